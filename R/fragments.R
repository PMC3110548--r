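# stationary-fragment selection on tachogram/systogram pairs

# a window passes the stationarity screen if, split into thirds, the
# sub-window means differ by less than k_mean * SD(window) and the
# sub-window variances differ by less than k_var * var(window)
window_is_stationary <- function(x, k_mean, k_var) {
  n <- length(x)
  cut <- c(0, round(n / 3), round(2 * n / 3), n)
  mu <- va <- numeric(3)
  for (j in 1:3) {
    sub <- x[(cut[j] + 1):cut[j + 1]]
    mu[j] <- mean(sub)
    va[j] <- var(sub)
  }
  s <- sd(x)
  v <- var(x)
  if (!is.finite(v) || v <= 0) return(FALSE)
  max(dist3(mu)) < k_mean * s && max(dist3(va)) < k_var * v
}

dist3 <- function(x) abs(c(x[1] - x[2], x[1] - x[3], x[2] - x[3]))

#' Select stationary fragments from a beat series
#'
#' Slides a window of `target_len` beats over the tachogram and systogram
#' and keeps windows in which both series pass a thirds-based stationarity
#' screen: the window is split into three equal sub-windows and qualifies
#' when sub-window means differ by less than `k_mean` x the window SD and
#' sub-window variances by less than `k_var` x the window variance.
#' Qualifying windows are accepted greedily from the start of the series,
#' so the returned fragments are non-overlapping and coincident between
#' tachogram and systogram (they share beat indices).
#'
#' @param beats A [beat_series()]; systogram value `k` is the systolic
#'   pressure at the peak opening pulse interval `k`, so both series have
#'   `length(pi_ms)` entries.
#' @param target_len Fragment length in beats (default 300).
#' @param k_mean,k_var Stationarity thresholds (defaults 0.5 and 1.0).
#' @return A list of fragments; each fragment is a list with `start`,
#'   `end` (beat indices), `tachogram` and `systogram` (objects of class
#'   `fragment` carrying `values`, `kind`, `n_beats`, `mean_interval` in s).
#' @section Errors:
#' A series shorter than `target_len` raises `"ratvar_short_input"`;
#' a long-enough series with no qualifying window raises
#' `"ratvar_no_stationary_fragment"`.
#' @export
select_stationary_fragments <- function(beats, target_len = 300,
                                        k_mean = 0.5, k_var = 1.0) {
  if (!inherits(beats, "beat_series")) {
    ratvar_error("`beats` must be a beat_series", "ratvar_invalid_beats")
  }
  target_len <- as.integer(target_len)
  tach <- beats$pi_ms
  syst <- beats$sap[-length(beats$sap)]
  n <- length(tach)
  if (n < target_len) {
    ratvar_error(sprintf("series has %d beats; %d required", n, target_len),
                 "ratvar_short_input")
  }
  out <- list()
  s <- 1L
  while (s + target_len - 1L <= n) {
    idx <- s:(s + target_len - 1L)
    if (window_is_stationary(tach[idx], k_mean, k_var) &&
        window_is_stationary(syst[idx], k_mean, k_var)) {
      mi <- mean(tach[idx]) / 1000
      out[[length(out) + 1L]] <- list(
        start = s, end = s + target_len - 1L,
        tachogram = new_fragment(tach[idx], "tachogram", mi),
        systogram = new_fragment(syst[idx], "systogram", mi))
      s <- s + target_len
    } else {
      s <- s + 1L
    }
  }
  if (!length(out)) {
    ratvar_error("no stationary fragment found", "ratvar_no_stationary_fragment")
  }
  out
}

new_fragment <- function(values, kind, mean_interval) {
  structure(list(values = as.numeric(values), kind = kind,
                 n_beats = length(values), mean_interval = mean_interval),
            class = "fragment")
}

#' Construct a spectral-analysis fragment
#'
#' @param values Beat-ordered values: pulse intervals (ms) for a tachogram,
#'   systolic pressures (mmHg) for a systogram.
#' @param kind `"tachogram"` or `"systogram"`.
#' @param mean_interval Mean pulse interval of the fragment (s); maps
#'   beat-domain frequencies to Hz. For a tachogram it defaults to
#'   `mean(values)/1000`.
#' @return An object of class `fragment`.
#' @export
fragment <- function(values, kind = c("tachogram", "systogram"),
                     mean_interval = NULL) {
  kind <- match.arg(kind)
  if (length(values) < 3L || !all(is.finite(values))) {
    ratvar_error("fragment values must be finite and number at least 3",
                 "ratvar_invalid_fragment")
  }
  if (is.null(mean_interval)) {
    if (kind != "tachogram") {
      ratvar_error("`mean_interval` is required for a systogram",
                   "ratvar_invalid_fragment")
    }
    mean_interval <- mean(values) / 1000
  }
  check_number(mean_interval, "mean_interval", lower = 0, strict_lower = TRUE)
  new_fragment(values, kind, mean_interval)
}
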