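# derived-quantity arithmetic: densitometric normalization, percent
# differences, fold changes, pooled summaries

#' Normalize densitometric values to the control mean
#'
#' Every value in a batch (one blotting membrane) is multiplied by
#' `100 / mean(control values in that batch)`, so the batch's controls
#' average exactly 100 arbitrary units. Batches are normalized
#' independently; pooling per-batch-normalized controls across batches can
#' therefore average near, but not exactly, 100.
#'
#' @param values Numeric densitometric readings (AU).
#' @param control_flags Logical, `TRUE` for control (reference) samples.
#' @param batch Optional batch (membrane) labels; default: one batch.
#' @return Normalized values (AU).
#' @examples
#' normalize_densitometry(c(2, 4, 6), c(TRUE, TRUE, FALSE))
#' @export
normalize_densitometry <- function(values, control_flags, batch = NULL) {
  if (length(values) != length(control_flags)) {
    ratvar_error("`values` and `control_flags` must have equal length",
                 "ratvar_invalid_records")
  }
  batch <- batch %||% rep(1L, length(values))
  out <- numeric(length(values))
  for (b in unique(batch)) {
    sel <- batch == b
    ctl <- values[sel & control_flags]
    if (!length(ctl)) {
      ratvar_error(sprintf("batch '%s' has no control values", b),
                   "ratvar_no_controls")
    }
    if (mean(ctl) <= 0) {
      ratvar_error(sprintf("batch '%s' control mean is not positive", b),
                   "ratvar_no_controls")
    }
    out[sel] <- values[sel] * 100 / mean(ctl)
  }
  out
}

#' Percent difference of a comparison mean from a reference mean
#'
#' @param reference_mean Non-zero reference value.
#' @param comparison_mean Comparison value.
#' @param digits Rounding; `NULL` for none, `0` (default) for the
#'   nearest-integer convention of results prose ("~12% higher").
#' @return `100 * (comparison - reference) / reference`, rounded.
#' @export
percent_difference <- function(reference_mean, comparison_mean, digits = 0) {
  if (any(reference_mean == 0)) {
    ratvar_error("reference mean must be non-zero", "ratvar_invalid_records")
  }
  out <- 100 * (comparison_mean - reference_mean) / reference_mean
  if (is.null(digits)) out else round(out, digits)
}

#' Fold change between two positive means
#'
#' @param reference_mean,comparison_mean Positive values.
#' @param direction `"reduction"` (default) returns
#'   `reference / comparison` (a 4-fold *reduction* is reference four
#'   times the comparison); `"elevation"` returns
#'   `comparison / reference`.
#' @param digits Optional rounding (default `NULL`, none).
#' @return The fold change.
#' @export
fold_change <- function(reference_mean, comparison_mean,
                        direction = c("reduction", "elevation"),
                        digits = NULL) {
  direction <- match.arg(direction)
  if (any(c(reference_mean, comparison_mean) <= 0)) {
    ratvar_error("fold change requires positive inputs",
                 "ratvar_invalid_records")
  }
  out <- if (direction == "reduction") reference_mean / comparison_mean
         else comparison_mean / reference_mean
  if (is.null(digits)) out else round(out, digits)
}

#' Pool group summaries into a grand mean and pooled SD
#'
#' `grand mean = sum(n_i m_i) / sum(n_i)`;
#' `pooled SD = sqrt(sum((n_i - 1) s_i^2) / sum(n_i - 1))`.
#'
#' @param cells Data frame with columns `mean`, `sd`, `n` (>= 2 rows).
#' @return List with `grand_mean`, `pooled_sd`, `n_total`.
#' @export
pooled_summary <- function(cells) {
  if (!is.data.frame(cells) || nrow(cells) < 2L ||
      !all(c("mean", "sd", "n") %in% names(cells))) {
    ratvar_error("`cells` must be a data frame with mean, sd, n and >= 2 rows",
                 "ratvar_invalid_cells")
  }
  if (any(cells$n < 2) || any(cells$sd < 0)) {
    ratvar_error("cells need n >= 2 and sd >= 0", "ratvar_invalid_cells")
  }
  list(grand_mean = sum(cells$n * cells$mean) / sum(cells$n),
       pooled_sd = sqrt(sum((cells$n - 1) * cells$sd^2) / sum(cells$n - 1)),
       n_total = sum(cells$n))
}

#' Bundled reference group summaries
#'
#' Group-level summary statistics (mean, SD, n per outcome and group) for
#' the 2x2 diabetes x renal-denervation cohort of spontaneously
#' hypertensive rats that calibrates the default simulation, as printed in
#' the source study's summary tables. Metabolic outcomes carry their own
#' n's (9, 7, 9, 5), cardiovascular outcomes theirs (7, 6, 6, 5).
#'
#' @return A data frame: `outcome`, `group`, `diabetes`, `denervation`,
#'   `mean`, `sd`, `n`.
#' @export
reference_summaries <- function() {
  path <- system.file("extdata", "reference_summaries.csv",
                      package = "ratvar")
  df <- read.csv(path)
  df$diabetes <- factor(df$diabetes, levels = c("no", "yes"))
  df$denervation <- factor(df$denervation, levels = c("no", "yes"))
  df
}
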