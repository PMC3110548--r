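#' Rat frequency-band edges
#'
#' The conventional spectral bands for beat-to-beat cardiovascular series
#' in the rat: VLF 0.0-0.2 Hz, LF 0.2-0.75 Hz, HF 0.75-3.0 Hz.
#'
#' @return Named numeric vector of band edges `c(vlf_lo, lf_lo, hf_lo, hf_hi)`.
#' @export
rat_bands <- function() c(vlf_lo = 0, lf_lo = 0.2, hf_lo = 0.75, hf_hi = 3.0)

#' Aggregate spectral components into band powers
#'
#' Assigns each spectral component's power to the band containing its
#' central frequency. Band intervals are half-open at the lower edge and
#' closed at the top edge (VLF `[0, 0.2)`, LF `[0.2, 0.75)`,
#' HF `[0.75, 3.0]` by default) so boundary components are assigned
#' deterministically; components above the HF edge are excluded from band
#' sums but counted in the total. Normalized units are percentages of the
#' LF + HF power, so `lf_nu + hf_nu = 100` whenever defined, and
#' LF/HF is the per-fragment ratio of absolute powers.
#'
#' @param components A `spectral_components` data frame from
#'   [decompose_spectrum()].
#' @param bands Band edges as in [rat_bands()], strictly increasing.
#' @param total Total power to report. Defaults to the sum of all
#'   component powers (the AR estimate of process variance); the analysis
#'   pipeline passes the fragment variance instead, which is the
#'   conventional definition of total HRV/SAPV.
#' @return A `band_powers` object: `vlf_abs`, `lf_abs`, `hf_abs`, `total`
#'   (input units squared), `lf_nu`, `hf_nu` (%), `lf_hf`, `lf_peak`,
#'   `hf_peak` (Hz; central frequency of the highest-power component in
#'   the band, `NA` when the band is empty). `lf_hf` is `NA` when the HF
#'   power is zero (never infinity).
#' @export
band_powers <- function(components, bands = rat_bands(), total = NULL) {
  if (!inherits(components, "spectral_components")) {
    ratvar_error("`components` must come from decompose_spectrum()",
                 "ratvar_invalid_components")
  }
  if (length(bands) != 4L || any(diff(bands) <= 0)) {
    ratvar_error("`bands` must be 4 strictly increasing edges",
                 "ratvar_invalid_bands")
  }
  f <- components$central_freq
  pw <- components$power
  in_band <- function(lo, hi, closed_top = FALSE) {
    if (closed_top) f >= lo & f <= hi else f >= lo & f < hi
  }
  sel_vlf <- in_band(bands[1], bands[2])
  sel_lf <- in_band(bands[2], bands[3])
  sel_hf <- in_band(bands[3], bands[4], closed_top = TRUE)
  peak <- function(sel) {
    if (!any(sel)) return(NA_real_)
    f[sel][which.max(pw[sel])]
  }
  vlf_abs <- sum(pw[sel_vlf])
  lf_abs <- sum(pw[sel_lf])
  hf_abs <- sum(pw[sel_hf])
  denom <- lf_abs + hf_abs
  structure(
    list(vlf_abs = vlf_abs, lf_abs = lf_abs, hf_abs = hf_abs,
         total = total %||% sum(pw),
         lf_nu = if (denom > 0) 100 * lf_abs / denom else NA_real_,
         hf_nu = if (denom > 0) 100 * hf_abs / denom else NA_real_,
         lf_hf = if (hf_abs > 0) lf_abs / hf_abs else NA_real_,
         lf_peak = peak(sel_lf), hf_peak = peak(sel_hf)),
    class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf(
    "<band_powers> total %.3g | VLF %.3g LF %.3g HF %.3g | LF %.1f nu HF %.1f nu | LF/HF %.3g\n",
    x$total, x$vlf_abs, x$lf_abs, x$hf_abs, x$lf_nu, x$hf_nu, x$lf_hf))
  invisible(x)
}
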