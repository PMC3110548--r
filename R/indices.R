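#' Spontaneous baroreflex alpha index
#'
#' `alpha_LF = sqrt(LF_HRV / LF_SAPV)`, the square root of the ratio
#' between the absolute LF powers of heart-rate variability (ms^2) and of
#' systolic-pressure variability (mmHg^2). It estimates spontaneous
#' baroreflex sensitivity in ms/mmHg.
#'
#' @param lf_hrv_abs Absolute LF power of the tachogram (ms^2), >= 0.
#' @param lf_sapv_abs Absolute LF power of the systogram (mmHg^2).
#' @return `sqrt(lf_hrv_abs / lf_sapv_abs)` (ms/mmHg); `NA` when the
#'   systogram LF power is not positive.
#' @examples
#' alpha_lf(4, 1)  # 2 ms/mmHg
#' @export
alpha_lf <- function(lf_hrv_abs, lf_sapv_abs) {
  if (any(lf_hrv_abs < 0, na.rm = TRUE)) {
    ratvar_error("LF powers must be non-negative", "ratvar_invalid_power")
  }
  out <- ifelse(is.na(lf_sapv_abs) | lf_sapv_abs <= 0, NA_real_,
                sqrt(lf_hrv_abs / lf_sapv_abs))
  as.numeric(out)
}

#' Sympathovagal balance (LF/HF index)
#'
#' Ratio of absolute LF to HF power of heart-rate variability, computed
#' per animal (never as a ratio of group-mean powers, which differs by a
#' Jensen gap).
#'
#' @param profile An `autonomic_profile` from [analyze_beats()], or a
#'   `band_powers` object for the tachogram.
#' @return `lf_abs / hf_abs`; `NA` when the HF power is zero.
#' @export
sympathovagal_balance <- function(profile) {
  bp <- if (inherits(profile, "autonomic_profile")) profile$hrv else profile
  if (!inherits(bp, "band_powers")) {
    ratvar_error("`profile` must be an autonomic_profile or band_powers",
                 "ratvar_invalid_profile")
  }
  if (is.na(bp$hf_abs) || bp$hf_abs <= 0) return(NA_real_)
  bp$lf_abs / bp$hf_abs
}

# spectral analysis of one fragment pair -> per-fragment outcome row
analyze_fragment <- function(frag_pair, bands = rat_bands(),
                             p_min = 8, p_max = 20) {
  one <- function(frag) {
    ord <- select_order(frag, p_min, p_max)
    model <- fit_ar(frag, ord)
    comp <- decompose_spectrum(model)
    bp <- band_powers(comp, bands, total = var(frag$values))
    list(bp = bp, order = as.integer(ord))
  }
  ta <- one(frag_pair$tachogram)
  sy <- one(frag_pair$systogram)
  data.frame(
    hrv_total = ta$bp$total, hrv_vlf = ta$bp$vlf_abs,
    hrv_lf = ta$bp$lf_abs, hrv_hf = ta$bp$hf_abs,
    hrv_lf_nu = ta$bp$lf_nu, hrv_hf_nu = ta$bp$hf_nu,
    lf_hf = ta$bp$lf_hf,
    hrv_lf_peak = ta$bp$lf_peak, hrv_hf_peak = ta$bp$hf_peak,
    sapv_total = sy$bp$total, sapv_vlf = sy$bp$vlf_abs,
    sapv_lf = sy$bp$lf_abs, sapv_hf = sy$bp$hf_abs,
    sapv_lf_peak = sy$bp$lf_peak, sapv_hf_peak = sy$bp$hf_peak,
    alpha_lf = alpha_lf(ta$bp$lf_abs, sy$bp$lf_abs),
    ar_order_tachogram = ta$order, ar_order_systogram = sy$order)
}

#' Full autonomic analysis of one beat series
#'
#' Chains stationary-fragment selection, AR order selection (AIC), Burg
#' fitting, pole-residue spectral decomposition and band aggregation for
#' the tachogram and the coincident systogram, computes the per-fragment
#' LF/HF and alpha indices, and averages all quantities across the
#' qualifying fragments of the recording. Total HRV and SAPV are reported
#' as the fragment variances.
#'
#' @param beats A [beat_series()].
#' @param bands Band edges, see [rat_bands()].
#' @param target_len Fragment length in beats.
#' @param p_min,p_max AR order range for AIC selection.
#' @param k_mean,k_var Stationarity thresholds, see
#'   [select_stationary_fragments()].
#' @return An `autonomic_profile`: `hrv` and `sapv` ([band_powers()]-like
#'   lists of fragment-averaged values), `alpha_lf`, `lf_hf`,
#'   `hemodynamics` ([summarize_hemodynamics()]), `n_fragments`, and the
#'   per-fragment table as element `fragments`.
#' @export
analyze_beats <- function(beats, bands = rat_bands(), target_len = 300,
                          p_min = 8, p_max = 20, k_mean = 0.5, k_var = 1.0) {
  frags <- select_stationary_fragments(beats, target_len, k_mean, k_var)
  per <- do.call(rbind, lapply(frags, analyze_fragment,
                               bands = bands, p_min = p_min, p_max = p_max))
  avg <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  hrv <- structure(list(
    vlf_abs = avg(per$hrv_vlf), lf_abs = avg(per$hrv_lf),
    hf_abs = avg(per$hrv_hf), total = avg(per$hrv_total),
    lf_nu = avg(per$hrv_lf_nu), hf_nu = avg(per$hrv_hf_nu),
    lf_hf = avg(per$lf_hf),
    lf_peak = avg(per$hrv_lf_peak), hf_peak = avg(per$hrv_hf_peak)),
    class = "band_powers")
  sapv <- structure(list(
    vlf_abs = avg(per$sapv_vlf), lf_abs = avg(per$sapv_lf),
    hf_abs = avg(per$sapv_hf), total = avg(per$sapv_total),
    lf_nu = NA_real_, hf_nu = NA_real_, lf_hf = NA_real_,
    lf_peak = avg(per$sapv_lf_peak), hf_peak = avg(per$sapv_hf_peak)),
    class = "band_powers")
  structure(
    list(hrv = hrv, sapv = sapv,
         alpha_lf = avg(per$alpha_lf), lf_hf = avg(per$lf_hf),
         hemodynamics = summarize_hemodynamics(beats),
         n_fragments = nrow(per), fragments = per),
    class = "autonomic_profile")
}

#' @export
print.autonomic_profile <- function(x, ...) {
  cat(sprintf(
    "<autonomic_profile> %d fragment(s); HRV %.3g ms^2 (LF %.3g, HF %.3g), SAPV %.3g mmHg^2, LF/HF %.3g, alpha_LF %.3g ms/mmHg\n",
    x$n_fragments, x$hrv$total, x$hrv$lf_abs, x$hrv$hf_abs,
    x$sapv$total, x$lf_hf, x$alpha_lf))
  invisible(x)
}

# flatten an autonomic_profile to one numeric row
profile_row <- function(p) {
  data.frame(
    hr_bpm = p$hemodynamics$hr, sap_mmhg = p$hemodynamics$sap_mean,
    dap_mmhg = p$hemodynamics$dap_mean, map_mmhg = p$hemodynamics$map_mean,
    hrv_total = p$hrv$total, hrv_lf_peak = p$hrv$lf_peak,
    hrv_lf = p$hrv$lf_abs, hrv_lf_nu = p$hrv$lf_nu,
    hrv_hf_peak = p$hrv$hf_peak, hrv_hf = p$hrv$hf_abs,
    hrv_hf_nu = p$hrv$hf_nu, lf_hf = p$lf_hf,
    sapv_total = p$sapv$total, sapv_vlf = p$sapv$vlf_abs,
    sapv_lf_peak = p$sapv$lf_peak, sapv_lf = p$sapv$lf_abs,
    sapv_hf_peak = p$sapv$hf_peak, sapv_hf = p$sapv$hf_abs,
    alpha_lf = p$alpha_lf, n_fragments = p$n_fragments)
}

#' Aggregate per-animal values to a group summary
#'
#' Per-field mean and SD over the animals of one group, excluding missing
#' values field-wise and reporting the count used per field. Aggregation
#' is permutation-invariant over animals.
#'
#' @param profiles A data frame of per-animal values (e.g. flattened
#'   autonomic profiles joined with cohort outcomes), one row per animal.
#' @param group A vector of group labels (length `nrow(profiles)`), or the
#'   name of a column of `profiles` holding them.
#' @return A data frame with one row per group x field: `group`, `field`,
#'   `mean`, `sd`, `n_used`.
#' @export
aggregate_group <- function(profiles, group) {
  if (length(group) == 1L && is.character(group) && group %in% names(profiles)) {
    glab <- profiles[[group]]
    profiles <- profiles[setdiff(names(profiles), group)]
  } else {
    glab <- group
  }
  if (length(glab) != nrow(profiles)) {
    ratvar_error("`group` must label every row", "ratvar_invalid_group")
  }
  num <- profiles[vapply(profiles, is.numeric, logical(1))]
  out <- list()
  for (g in unique(glab)) {
    sub <- num[glab == g, , drop = FALSE]
    if (nrow(sub) < 2L) {
      ratvar_error(sprintf("group '%s' has fewer than 2 animals", g),
                   "ratvar_invalid_group")
    }
    for (f in names(sub)) {
      v <- sub[[f]][!is.na(sub[[f]])]
      out[[length(out) + 1L]] <- data.frame(
        group = g, field = f,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) sd(v) else NA_real_,
        n_used = length(v))
    }
  }
  do.call(rbind, out)
}
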