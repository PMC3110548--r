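# internal helpers: conditions, RNG scoping, small validators

ratvar_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ratvar_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`;
# seed = NULL leaves the global RNG stream untouched/consumed as usual
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# derive a child seed (< 2^31) from a parent seed and an index
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + i * 8191) %% 2147483647
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ratvar_error(sprintf("`%s` must be a single finite number", name),
                 "ratvar_invalid_spec")
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    ratvar_error(sprintf("`%s` = %g is out of range", name, x),
                 "ratvar_invalid_spec")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
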