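# 2x2 cohort simulation: diabetes x renal denervation

#' Build a cohort design
#'
#' A cohort design describes the four groups of the 2x2 factorial
#' (diabetes yes/no x renal denervation yes/no): per-group animal counts,
#' the Gaussian mean/SD of every scalar outcome, the log-normal albumin
#' parameters (given as median and a bracketed interval), and the
#' beat-series parameters used to attach a simulated recording to each
#' animal.
#'
#' @param groups A list of 4 group descriptions, each a list with
#'   `label`, `diabetes`, `denervation` (logicals), `n_animals` (>= 2),
#'   `outcomes` (named list of `list(mean=, sd=)`), `albumin`
#'   (`list(median=, lo=, hi=)`) and `beats` (named list of beat-series
#'   parameters; see the default config).
#' @param albumin_interval How to read the albumin brackets: `"range"`
#'   (observed min-max of a sample of `n_animals`; the SD on the log scale
#'   is the log-range divided by the expected range of a standard normal
#'   sample of that size) or `"iqr"` (interquartile range; divided by
#'   2 x 0.6745).
#' @param n_beats Beats simulated per animal.
#' @param seed Optional base seed; per-animal seeds are derived from it.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(groups, albumin_interval = c("range", "iqr"),
                          n_beats = 1200, seed = NULL) {
  albumin_interval <- match.arg(albumin_interval)
  if (length(groups) != 4L) {
    ratvar_error("a cohort design needs exactly 4 groups",
                 "ratvar_invalid_design")
  }
  grid <- t(vapply(groups, function(g) {
    c(isTRUE(g$diabetes), isTRUE(g$denervation))
  }, logical(2)))
  if (nrow(unique(grid)) != 4L) {
    ratvar_error("groups must span the 2x2 diabetes x denervation grid",
                 "ratvar_invalid_design")
  }
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n_animals) || g$n_animals < 2) {
      ratvar_error("each group needs a label and n_animals >= 2",
                   "ratvar_invalid_design")
    }
    for (o in g$outcomes) {
      if (!is.null(o$sd) && o$sd < 0) {
        ratvar_error("outcome SDs must be >= 0", "ratvar_invalid_design")
      }
    }
  }
  structure(list(groups = groups, albumin_interval = albumin_interval,
                 n_beats = n_beats, seed = seed),
            class = "cohort_design")
}

#' The default cohort design
#'
#' Reads the packaged configuration (see
#' `system.file("extdata", "default_config.yaml", package = "ratvar")`),
#' which calibrates the four groups to published group summaries for the
#' diabetic/renal-denervated spontaneously hypertensive rat model with
#' group sizes 7, 6, 6 and 5.
#'
#' @param seed Optional base seed.
#' @param config Optional configuration list (as returned by
#'   [pipeline_config()]) to build the design from.
#' @return A [cohort_design()].
#' @export
default_cohort_design <- function(seed = NULL, config = NULL) {
  cfg <- config %||% pipeline_config()
  cohort_design(cfg$groups, albumin_interval = cfg$albumin_interval,
                n_beats = cfg$n_beats, seed = seed)
}

# expected range (in SDs) of a standard normal sample of size n;
# Blom-type approximation of the expected extreme order statistics
expected_normal_range <- function(n) 2 * qnorm((n - 0.375) / (n + 0.25))

albumin_lognormal_params <- function(alb, n, interval) {
  meanlog <- log(alb$median)
  spread <- log(alb$hi) - log(alb$lo)
  sdlog <- if (interval == "iqr") spread / (2 * 0.6744898)
           else spread / expected_normal_range(n)
  c(meanlog = meanlog, sdlog = sdlog)
}

# truncated-above-threshold normal draw by inverse-CDF sampling (diabetic
# glycemia: the induction protocol only labels an animal diabetic above
# threshold); degenerate upper tails collapse to just above the threshold
rnorm_above <- function(n, mean, sd, lower) {
  p_lo <- pnorm(lower, mean, sd)
  if (p_lo < 1 - 1e-10) {
    u <- pmin(runif(n, p_lo, 1), 1 - 1e-12)
    qnorm(u, mean, sd)
  } else {
    lower + abs(rnorm(n, 0, sd * 1e-6)) + 1e-9
  }
}

#' Simulate a 2x2 cohort of animals
#'
#' Draws every scalar outcome per animal from its group's Gaussian
#' (log-normal for urinary albumin), and optionally attaches a simulated
#' beat series per animal whose mean pulse interval matches the animal's
#' drawn heart rate. For diabetic groups the *initial* glycemia is drawn
#' truncated above the inclusion threshold (300 mg/dL), mirroring the
#' induction protocol under which only animals above the threshold enter
#' the diabetic groups; the 45-day glycemia is drawn untruncated.
#' Urinary outcomes are truncated at zero. Per-animal systolic/diastolic
#' pairs are redrawn until pulse pressure is at least 10 mmHg.
#'
#' @param design A [cohort_design()].
#' @param with_beats Attach a simulated [beat_series()] per animal
#'   (default `TRUE`); disable for fast statistics-only cohorts.
#' @return A list of class `cohort`: `animals` (data frame, one row per
#'   animal: `id`, `group`, `diabetes`, `denervation`, scalar outcomes,
#'   `hr_bpm`, `sap_mmhg`, `dap_mmhg`) and `beats` (named list of
#'   beat series, or `NULL`).
#' @export
simulate_cohort <- function(design, with_beats = TRUE) {
  if (!inherits(design, "cohort_design")) {
    ratvar_error("`design` must be a cohort_design", "ratvar_invalid_design")
  }
  with_seed(design$seed, {
    rows <- list()
    beats <- list()
    aid <- 0L
    for (g in design$groups) {
      n <- g$n_animals
      draw <- function(o) rnorm(n, o$mean, o$sd)
      oc <- g$outcomes
      glyc_init <- if (isTRUE(g$diabetes)) {
        rnorm_above(n, oc$glycemia_initial$mean, oc$glycemia_initial$sd, 300)
      } else draw(oc$glycemia_initial)
      alb_par <- albumin_lognormal_params(g$albumin, n,
                                          design$albumin_interval)
      hr <- pmax(draw(g$beats$hr), 60)
      sap <- draw(g$beats$sap)
      dap <- draw(g$beats$dap)
      for (tries in 1:1000) {
        bad <- sap - dap < 10
        if (!any(bad)) break
        sap[bad] <- rnorm(sum(bad), g$beats$sap$mean, g$beats$sap$sd)
        dap[bad] <- rnorm(sum(bad), g$beats$dap$mean, g$beats$dap$sd)
      }
      df <- data.frame(
        id = sprintf("%s_%02d", g$label, seq_len(n)),
        group = g$label,
        diabetes = factor(ifelse(isTRUE(g$diabetes), "yes", "no"),
                          levels = c("no", "yes")),
        denervation = factor(ifelse(isTRUE(g$denervation), "yes", "no"),
                             levels = c("no", "yes")),
        weight_initial = draw(oc$weight_initial),
        weight_45d = draw(oc$weight_45d),
        glycemia_initial = glyc_init,
        glycemia_45d = draw(oc$glycemia_45d),
        diuresis = pmax(draw(oc$diuresis), 0),
        urinary_glucose = pmax(draw(oc$urinary_glucose), 0),
        urinary_sodium = pmax(draw(oc$urinary_sodium), 0),
        urinary_albumin = exp(rnorm(n, alb_par["meanlog"], alb_par["sdlog"])),
        densitometry = draw(oc$densitometry),
        hr_bpm = hr, sap_mmhg = sap, dap_mmhg = dap)
      rows[[length(rows) + 1L]] <- df
      if (with_beats) {
        for (i in seq_len(n)) {
          aid <- aid + 1L
          sp <- beat_spec(
            mean_pi = 60000 / hr[i],
            lf_freq = g$beats$lf_freq, lf_amp = g$beats$pi_lf_amp,
            hf_freq = g$beats$hf_freq, hf_amp = g$beats$pi_hf_amp,
            noise_sd = g$beats$pi_noise_sd,
            sap_mean = sap[i], dap_mean = dap[i],
            sap_lf_amp = g$beats$sap_lf_amp,
            sap_hf_amp = g$beats$sap_hf_amp,
            sap_noise_sd = g$beats$sap_noise_sd,
            n_beats = design$n_beats,
            seed = child_seed(design$seed, aid))
          beats[[df$id[i]]] <- simulate_beat_series(sp)
        }
      }
    }
    structure(list(animals = do.call(rbind, rows),
                   beats = if (with_beats) beats else NULL),
              class = "cohort")
  })
}

#' Apply the diabetes inclusion rule
#'
#' Animals in diabetic groups with initial glycemia at or below the
#' threshold (strict `>` required to stay) are excluded; non-diabetic
#' animals pass unconditionally. The rule is idempotent. The number of
#' exclusions is reported via `message()` and attached as attribute
#' `"n_excluded"`.
#'
#' @param records A cohort `animals` data frame (or a `cohort`).
#' @param threshold Glycemia threshold in mg/dL (default 300).
#' @return The filtered records (same type as the input).
#' @export
apply_inclusion <- function(records, threshold = 300) {
  is_cohort <- inherits(records, "cohort")
  df <- if (is_cohort) records$animals else records
  if (!all(c("diabetes", "glycemia_initial") %in% names(df))) {
    ratvar_error("records need `diabetes` and `glycemia_initial` columns",
                 "ratvar_invalid_records")
  }
  keep <- df$diabetes != "yes" | df$glycemia_initial > threshold
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message(sprintf("apply_inclusion: excluded %d animal(s) with glycemia <= %g mg/dL",
                    n_excl, threshold))
  }
  out <- df[keep, , drop = FALSE]
  if (is_cohort) {
    records$animals <- out
    if (!is.null(records$beats)) records$beats <- records$beats[out$id]
    attr(records, "n_excluded") <- n_excl
    return(records)
  }
  attr(out, "n_excluded") <- n_excl
  out
}

#' Write / read per-animal and per-beat CSV files
#'
#' `write_cohort_csv()` writes one row per animal; `write_beats_csv()`
#' writes one row per beat with columns `beat_time_s`, `pi_ms`,
#' `sap_mmHg`, `dap_mmHg` (interval `k` is described by peak time `k`,
#' the interval it opens, and the pressures around it).
#'
#' @param cohort A `cohort` or its `animals` data frame.
#' @param path Output file path.
#' @return `write_*` return the path invisibly; `read_*` return the
#'   parsed object.
#' @name cohort_io
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- if (inherits(cohort, "cohort")) cohort$animals else cohort
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path)
  for (f in c("diabetes", "denervation")) {
    if (f %in% names(df)) df[[f]] <- factor(df[[f]], levels = c("no", "yes"))
  }
  df
}

#' @rdname cohort_io
#' @param beats A [beat_series()].
#' @export
write_beats_csv <- function(beats, path) {
  m <- length(beats$beat_times)
  df <- data.frame(beat_time_s = beats$beat_times[-m],
                   pi_ms = beats$pi_ms,
                   sap_mmHg = beats$sap[-m],
                   dap_mmHg = beats$dap)
  df$last_sap_mmHg <- c(rep(NA, nrow(df) - 1L), beats$sap[m])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_beats_csv <- function(path) {
  df <- read.csv(path)
  m <- nrow(df) + 1L
  last_sap <- df$last_sap_mmHg[nrow(df)]
  if (is.null(last_sap) || is.na(last_sap)) last_sap <- df$sap_mmHg[nrow(df)]
  beat_series(
    beat_times = c(df$beat_time_s, df$beat_time_s[nrow(df)] +
                     df$pi_ms[nrow(df)] / 1000),
    sap = c(df$sap_mmHg, last_sap),
    dap = df$dap_mmHg)
}
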