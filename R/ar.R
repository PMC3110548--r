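# autoregressive modelling: Burg estimation, AIC order selection,
# pole-residue spectral decomposition

# Burg lattice recursion; returns coefficients and innovation variance at
# every order up to p_max (one pass). Coefficients are in predictor form
# x_t = a_1 x_{t-1} + ... + a_p x_{t-p} + e_t.
burg_recursion <- function(x, p_max) {
  x <- x - mean(x)
  n <- length(x)
  vars <- c(mean(x^2), numeric(p_max))
  coefs <- vector("list", p_max)
  f <- x
  b <- x
  a <- numeric(0)
  for (p in seq_len(p_max)) {
    ff <- f[-1]
    bb <- b[-length(b)]
    den <- sum(ff^2) + sum(bb^2)
    k <- if (den <= 0) 0 else 2 * sum(ff * bb) / den
    a <- if (p == 1L) k else c(a - k * rev(a), k)
    f <- ff - k * bb
    b <- bb - k * ff
    vars[p + 1L] <- vars[p] * (1 - k^2)
    coefs[[p]] <- a
  }
  list(coefs = coefs, vars = vars)
}

#' Fit an autoregressive model to a fragment by the Burg method
#'
#' Estimates AR coefficients by the Burg lattice recursion on the
#' mean-centred fragment. All reflection coefficients have modulus < 1, so
#' the fitted model is stable by construction; the innovation variance is
#' the final prediction-error power of the recursion.
#'
#' @param frag A [fragment()].
#' @param order AR model order `p` (>= 1); the fragment must be longer
#'   than `2 * order`.
#' @return An `ar_model`: `order`, `coefficients` (a_1..a_p, predictor
#'   form), `innovation_variance` (squared input units), `mean_interval`
#'   (s), `kind`, and `n` (fragment length).
#' @references Burg's maximum-entropy estimator is the standard choice for
#'   short cardiovascular fragments because of its resolution at low order.
#' @export
fit_ar <- function(frag, order) {
  if (!inherits(frag, "fragment")) {
    ratvar_error("`frag` must be a fragment", "ratvar_invalid_fragment")
  }
  check_number(order, "order", lower = 1)
  order <- as.integer(order)
  n <- frag$n_beats
  if (n <= 2L * order) {
    ratvar_error("fragment must be longer than 2 * order",
                 "ratvar_invalid_fragment")
  }
  if (var(frag$values) <= 0) {
    ratvar_error("fragment has zero variance", "ratvar_zero_variance")
  }
  fit <- burg_recursion(frag$values, order)
  new_ar_model(fit$coefs[[order]], fit$vars[order + 1L], frag, order)
}

new_ar_model <- function(coefficients, innovation_variance, frag, order) {
  structure(
    list(order = order,
         coefficients = coefficients,
         innovation_variance = innovation_variance,
         mean_interval = frag$mean_interval,
         kind = frag$kind,
         n = frag$n_beats),
    class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> %s, order %d, innovation variance %.4g\n",
              x$kind, x$order, x$innovation_variance))
  invisible(x)
}

#' Select the AR model order by AIC
#'
#' Runs the Burg recursion once up to `p_max` and returns the order in
#' `[p_min, p_max]` minimizing `AIC(p) = n log(innovation_variance_p) + 2p`,
#' ties broken toward the smaller order.
#'
#' @param frag A [fragment()].
#' @param p_min,p_max Order range (defaults 8 and 20); `p_max` must be
#'   below half the fragment length.
#' @return The selected order (integer) with the AIC values over the range
#'   attached as attribute `"aic"`.
#' @export
select_order <- function(frag, p_min = 8, p_max = 20) {
  if (!inherits(frag, "fragment")) {
    ratvar_error("`frag` must be a fragment", "ratvar_invalid_fragment")
  }
  check_number(p_min, "p_min", lower = 1)
  check_number(p_max, "p_max", lower = p_min)
  if (p_max >= frag$n_beats / 2) {
    ratvar_error("`p_max` must be below half the fragment length",
                 "ratvar_invalid_fragment")
  }
  if (var(frag$values) <= 0) {
    ratvar_error("fragment has zero variance", "ratvar_zero_variance")
  }
  fit <- burg_recursion(frag$values, as.integer(p_max))
  orders <- as.integer(p_min):as.integer(p_max)
  aic <- frag$n_beats * log(fit$vars[orders + 1L]) + 2 * orders
  best <- orders[which.min(aic)]  # which.min takes the first (smallest) tie
  structure(best, aic = setNames(aic, orders))
}

#' Decompose an AR spectrum into pole-resolved components
#'
#' Factors the AR characteristic polynomial and assigns each real root one
#' spectral component and each complex-conjugate pair one oscillatory
#' component. The component central frequency is the pole angle mapped to
#' Hz through the fragment's mean beat interval,
#' `f = |arg z| / (2 pi mean_interval)`, and component powers are the
#' residues of the AR spectral density at the poles (doubled for conjugate
#' pairs), so that the powers sum to the process variance.
#'
#' @param model An `ar_model` from [fit_ar()].
#' @return A data frame of class `spectral_components` with columns
#'   `central_freq` (Hz), `power` (squared input units), `is_complex_pair`,
#'   `modulus` (pole modulus), ordered by central frequency. Poles with
#'   modulus above 0.999 trigger a warning.
#' @details For the degenerate AR(0)-like case (all coefficients zero) the
#'   spectrum is flat and a single component at 0 Hz carrying the
#'   innovation variance is returned.
#' @export
decompose_spectrum <- function(model) {
  if (!inherits(model, "ar_model")) {
    ratvar_error("`model` must be an ar_model", "ratvar_invalid_model")
  }
  a <- model$coefficients
  s2 <- model$innovation_variance
  dt <- model$mean_interval
  p <- length(a)
  if (p == 0L || all(abs(a) < 1e-12)) {
    out <- data.frame(central_freq = 0, power = s2,
                      is_complex_pair = FALSE, modulus = 0)
    class(out) <- c("spectral_components", "data.frame")
    return(out)
  }
  z <- polyroot(c(-rev(a), 1))
  if (any(!is.finite(Re(z)) | !is.finite(Im(z)))) {
    ratvar_error("root finding failed for the AR characteristic polynomial",
                 "ratvar_root_failure")
  }
  if (any(Mod(z) >= 1)) {
    ratvar_error("AR model is not stable (root on/outside the unit circle)",
                 "ratvar_unstable_model")
  }
  if (any(Mod(z) > 0.999)) {
    warning("near-unit-circle pole(s); component powers may be ill-conditioned")
  }
  gam <- vapply(seq_len(p), function(j) {
    zj <- z[j]
    s2 * zj^(p - 1) / (prod(zj - z[-j]) * prod(1 - z * zj))
  }, complex(1))
  used <- rep(FALSE, p)
  rows <- list()
  for (j in seq_len(p)) {
    if (used[j]) next
    used[j] <- TRUE
    if (abs(Im(z[j])) < 1e-8 * (1 + abs(Re(z[j])))) {
      freq <- abs(Arg(z[j])) / (2 * pi * dt)
      rows[[length(rows) + 1L]] <- data.frame(
        central_freq = freq, power = Re(gam[j]),
        is_complex_pair = FALSE, modulus = Mod(z[j]))
    } else {
      mate <- which(!used & abs(z - Conj(z[j])) ==
                      min(abs(z[!used] - Conj(z[j]))))[1]
      used[mate] <- TRUE
      freq <- abs(Arg(z[j])) / (2 * pi * dt)
      rows[[length(rows) + 1L]] <- data.frame(
        central_freq = freq, power = 2 * Re(gam[j]),
        is_complex_pair = TRUE, modulus = Mod(z[j]))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$central_freq), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spectral_components", "data.frame")
  out
}

# AR power spectral density (two-sided, per Hz) at frequency f (Hz);
# integrates to the process variance over [-nyquist, nyquist]
ar_psd <- function(model, f) {
  a <- model$coefficients
  dt <- model$mean_interval
  vapply(f, function(fi) {
    w <- 2 * pi * fi * dt
    den <- if (length(a)) abs(1 - sum(a * exp(-1i * w * seq_along(a))))^2 else 1
    model$innovation_variance * dt / den
  }, numeric(1))
}
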