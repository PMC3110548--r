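# end-to-end pipeline wiring: config, simulate -> analyze -> stats -> report

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration (defaulting to the packaged one) holding
#' band edges, AR order range, fragment length and stationarity
#' thresholds, sampling rate, significance level and the four group
#' parameter sets. Defaults reproduce the standard constants for rat
#' recordings: bands 0-0.2 / 0.2-0.75 / 0.75-3.0 Hz, ~300-beat fragments,
#' 2 kHz waveform sampling, alpha = 0.05.
#'
#' @param path Path to a YAML config; `NULL` for the packaged default.
#' @param seed Optional integer seed stored in the config.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, seed = NULL) {
  path <- path %||% system.file("extdata", "default_config.yaml",
                                package = "ratvar")
  cfg <- yaml::read_yaml(path)
  cfg$seed <- seed %||% cfg$seed
  b <- unlist(cfg$bands)
  if (length(b) != 4L || any(diff(b) <= 0)) {
    ratvar_error("config `bands` must hold 4 increasing edges",
                 "ratvar_invalid_config")
  }
  check_number(cfg$sampling_rate, "sampling_rate", lower = 100)
  check_number(cfg$alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(cfg$fragment$target_len, "fragment.target_len", lower = 10)
  check_number(cfg$ar$p_min, "ar.p_min", lower = 1)
  check_number(cfg$ar$p_max, "ar.p_max", lower = cfg$ar$p_min)
  if (length(cfg$groups) != 4L) {
    ratvar_error("config must define 4 groups", "ratvar_invalid_config")
  }
  cfg$dispersion_label <- cfg$dispersion_label %||% "sd"
  cfg$albumin_interval <- cfg$albumin_interval %||% "range"
  class(cfg) <- "pipeline_config"
  cfg
}

cfg_bands <- function(config) {
  b <- unlist(config$bands)
  names(b) <- c("vlf_lo", "lf_lo", "hf_lo", "hf_hi")
  b
}

#' Simulate a cohort and write it to disk
#'
#' Writes `cohort.csv` (one row per animal) and one `beats_<id>.csv` per
#' animal into `out_dir`. Identical config + seed give identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Existing output directory.
#' @param with_beats Also write per-beat CSVs (default `TRUE`).
#' @return Invisibly, the simulated `cohort`.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir,
                         with_beats = TRUE) {
  if (!dir.exists(out_dir)) {
    ratvar_error(sprintf("output directory '%s' does not exist", out_dir),
                 "ratvar_io_error")
  }
  design <- default_cohort_design(seed = config$seed, config = config)
  cohort <- simulate_cohort(design, with_beats = with_beats)
  cohort <- apply_inclusion(cohort,
                            config$inclusion$glycemia_threshold %||% 300)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  if (with_beats) {
    for (id in names(cohort$beats)) {
      write_beats_csv(cohort$beats[[id]],
                      file.path(out_dir, sprintf("beats_%s.csv", id)))
    }
  }
  invisible(cohort)
}

#' Spectral analysis of every animal of a cohort
#'
#' Runs [analyze_beats()] (fragment selection, AR fitting, band powers,
#' indices) per animal. Input is either a `cohort` with attached beat
#' series, or a directory of `beats_<id>.csv` files written by
#' [run_simulate()]; waveform input is supported by passing `waveforms`,
#' which are run through [detect_beats()] first. Per-animal failures
#' (e.g. no stationary fragment) are logged and the animal is skipped.
#'
#' @param config A [pipeline_config()].
#' @param cohort A `cohort`, or `NULL` to read `input_dir`.
#' @param input_dir Directory holding `cohort.csv` and `beats_*.csv`.
#' @param waveforms Optional named list of `waveform` objects (per animal
#'   id), used instead of stored beat series.
#' @return A data frame of per-animal profiles (one row per analyzed
#'   animal: id, group, factors, flattened [analyze_beats()] outputs),
#'   with skipped ids in attribute `"skipped"`.
#' @export
run_analyze <- function(config = pipeline_config(), cohort = NULL,
                        input_dir = NULL, waveforms = NULL) {
  if (is.null(cohort)) {
    if (is.null(input_dir)) {
      ratvar_error("supply `cohort` or `input_dir`", "ratvar_io_error")
    }
    animals <- read_cohort_csv(file.path(input_dir, "cohort.csv"))
    beats <- lapply(animals$id, function(id) {
      read_beats_csv(file.path(input_dir, sprintf("beats_%s.csv", id)))
    })
    names(beats) <- animals$id
    cohort <- structure(list(animals = animals, beats = beats),
                        class = "cohort")
  }
  if (!is.null(waveforms)) {
    cohort$beats <- lapply(waveforms, detect_beats)
  }
  if (is.null(cohort$beats) || !length(cohort$beats)) {
    ratvar_error("no beat series to analyze", "ratvar_io_error")
  }
  bands <- cfg_bands(config)
  rows <- list()
  skipped <- character(0)
  for (id in names(cohort$beats)) {
    pr <- tryCatch(
      analyze_beats(cohort$beats[[id]], bands = bands,
                    target_len = config$fragment$target_len,
                    p_min = config$ar$p_min, p_max = config$ar$p_max,
                    k_mean = config$fragment$k_mean,
                    k_var = config$fragment$k_var),
      ratvar_error = function(e) e)
    if (inherits(pr, "condition")) {
      message(sprintf("run_analyze: skipping %s (%s)", id,
                      conditionMessage(pr)))
      skipped <- c(skipped, id)
      next
    }
    meta <- cohort$animals[cohort$animals$id == id,
                           c("id", "group", "diabetes", "denervation")]
    rows[[length(rows) + 1L]] <- cbind(meta, profile_row(pr))
  }
  if (!length(rows)) {
    ratvar_error("no animal could be analyzed", "ratvar_io_error")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Factorial statistics for every outcome
#'
#' Two-way (diabetes x denervation) Type-III ANOVA per outcome, with
#' urinary albumin log-transformed first, plus SNK post-hoc comparisons
#' of the four groups.
#'
#' @param config A [pipeline_config()].
#' @param records Per-animal data frame (cohort outcomes, optionally
#'   joined with analysis profiles).
#' @param outcomes Outcome columns to test; default: all numeric columns.
#' @return Named list per outcome: `anova` (an `anova_table`) and `snk`
#'   (an `snk_result`).
#' @export
run_stats <- function(config = pipeline_config(), records,
                      outcomes = NULL) {
  if (inherits(records, "cohort")) records <- records$animals
  if (is.null(outcomes)) {
    outcomes <- names(records)[vapply(records, is.numeric, logical(1))]
    outcomes <- setdiff(outcomes, "n_fragments")
    outcomes <- outcomes[vapply(outcomes, function(oc) {
      any(!is.na(records[[oc]]))
    }, logical(1))]
  }
  out <- list()
  for (oc in outcomes) {
    df <- records
    if (oc == "urinary_albumin") df <- log_transform_outcome(df, oc)
    res <- tryCatch(
      list(anova = two_way_anova(df, oc),
           snk = snk_posthoc(df, oc, alpha = config$alpha,
                             group_name = if ("group" %in% names(df)) "group")),
      ratvar_error = function(e) e)
    if (inherits(res, "condition")) {
      message(sprintf("run_stats: skipping %s (%s)", oc,
                      conditionMessage(res)))
      next
    }
    out[[oc]] <- res
  }
  out
}

fmt_cell <- function(m, s) {
  ifelse(is.na(m), "NA", sprintf("%.2f ± %.2f", m, s))
}

#' Assemble group-comparison report tables
#'
#' Builds the two standard report tables: general characteristics
#' (metabolic outcomes; albumin displayed as median [range] from the raw
#' values, tested on the log scale) and cardiovascular parameters
#' (hemodynamics, HRV/SAPV band powers, LF/HF, alpha index). Each row
#' carries the four group columns as `mean +/- dispersion` plus the
#' denervation, diabetes and interaction p-values. A derived-quantity
#' appendix reports the pooled baseline weight, heart-rate percent
#' differences and the SAPV fold change, each tagged with its formula.
#'
#' @param config A [pipeline_config()].
#' @param profiles Per-animal analysis profiles from [run_analyze()], or
#'   `NULL` to report only cohort outcomes.
#' @param cohort A `cohort` or its `animals` data frame.
#' @param out_dir Optional directory; when given, writes
#'   `table_characteristics.tsv`, `table_cardiovascular.tsv` and
#'   `table_derived.tsv`.
#' @return List of data frames `characteristics`, `cardiovascular`,
#'   `derived`.
#' @export
run_report <- function(config = pipeline_config(), profiles = NULL,
                       cohort, out_dir = NULL) {
  animals <- if (inherits(cohort, "cohort")) cohort$animals else cohort
  labels <- vapply(config$groups, `[[`, "", "label")
  if (!setequal(unique(animals$group), labels)) {
    ratvar_error("cohort group labels do not match the config groups",
                 "ratvar_invalid_records")
  }
  groups_of <- function(df) factor(df$group, levels = labels)

  one_table <- function(df, rows) {
    st <- run_stats(config, df, outcomes = rows)
    out <- list()
    for (oc in rows) {
      if (is.null(st[[oc]])) next
      g <- groups_of(df)
      if (oc == "urinary_albumin") {
        cells <- vapply(levels(g), function(l) {
          v <- df[[oc]][g == l]
          sprintf("%.0f [%.0f-%.0f]", median(v), min(v), max(v))
        }, "")
      } else {
        m <- tapply(df[[oc]], g, mean, na.rm = TRUE)
        s <- tapply(df[[oc]], g, function(v) dispersion(v, config))
        cells <- fmt_cell(m, s)
      }
      p <- st[[oc]]$anova$table$p
      out[[length(out) + 1L]] <- data.frame(
        outcome = oc, t(cells),
        p_denervation = p[1], p_diabetes = p[2], p_interaction = p[3],
        check.names = FALSE)
    }
    out <- do.call(rbind, out)
    names(out)[2:5] <- labels
    out
  }

  metab <- c("weight_initial", "weight_45d", "glycemia_initial",
             "glycemia_45d", "diuresis", "urinary_glucose",
             "urinary_sodium", "urinary_albumin", "densitometry")
  characteristics <- one_table(animals, intersect(metab, names(animals)))

  cardio <- NULL
  if (!is.null(profiles)) {
    cvars <- c("hr_bpm", "sap_mmhg", "dap_mmhg", "map_mmhg",
               "hrv_total", "hrv_lf_peak", "hrv_lf", "hrv_lf_nu",
               "hrv_hf_peak", "hrv_hf", "hrv_hf_nu", "lf_hf",
               "sapv_total", "sapv_vlf", "sapv_lf_peak", "sapv_lf",
               "sapv_hf_peak", "sapv_hf", "alpha_lf")
    cardio <- one_table(profiles, intersect(cvars, names(profiles)))
  }

  src <- if (!is.null(profiles)) profiles else animals
  g <- groups_of(src)
  gm <- function(oc, l) mean(src[[oc]][g == l], na.rm = TRUE)
  wcells <- data.frame(
    mean = tapply(animals$weight_initial, groups_of(animals), mean),
    sd = tapply(animals$weight_initial, groups_of(animals), sd),
    n = as.integer(table(groups_of(animals))))
  pw <- pooled_summary(wcells)
  derived <- data.frame(
    quantity = c("baseline_weight_grand_mean_g", "baseline_weight_pooled_sd_g",
                 "hr_pct_rd_vs_ctl", "hr_pct_diab_vs_ctl",
                 "sapv_fold_reduction_diabetes"),
    value = c(pw$grand_mean, pw$pooled_sd,
              if (!is.null(profiles))
                c(percent_difference(gm("hr_bpm", labels[1]),
                                     gm("hr_bpm", labels[2]), digits = NULL),
                  percent_difference(gm("hr_bpm", labels[1]),
                                     gm("hr_bpm", labels[3]), digits = NULL),
                  fold_change(gm("sapv_total", labels[1]),
                              gm("sapv_total", labels[3])))
              else rep(NA_real_, 3)),
    formula = c("sum(n_i m_i)/sum(n_i)",
                "sqrt(sum((n_i-1)s_i^2)/sum(n_i-1))",
                "100*(m_RD - m_ctl)/m_ctl",
                "100*(m_diab - m_ctl)/m_ctl",
                "m_ctl/m_diab"))

  out <- list(characteristics = characteristics, cardiovascular = cardio,
              derived = derived)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ratvar_error(sprintf("output directory '%s' does not exist", out_dir),
                   "ratvar_io_error")
    }
    wt <- function(df, f) {
      if (!is.null(df)) {
        write.table(df, file.path(out_dir, f), sep = "\t",
                    row.names = FALSE, quote = FALSE)
      }
    }
    wt(characteristics, "table_characteristics.tsv")
    wt(cardio, "table_cardiovascular.tsv")
    wt(derived, "table_derived.tsv")
  }
  out
}

dispersion <- function(v, config) {
  s <- sd(v, na.rm = TRUE)
  if (identical(config$dispersion_label, "sem")) {
    s / sqrt(sum(!is.na(v)))
  } else s
}

#' Run the full pipeline: simulate, analyze, test, report
#'
#' @param config A [pipeline_config()].
#' @param out_dir Existing output directory for CSV/TSV artifacts.
#' @return List with `cohort`, `profiles`, `stats`, `report` (invisible).
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  cohort <- run_simulate(config, out_dir)
  profiles <- run_analyze(config, cohort = cohort)
  # analyzed hemodynamics supersede the cohort's generating draws
  merged <- merge(
    cohort$animals[setdiff(names(cohort$animals),
                           c("hr_bpm", "sap_mmhg", "dap_mmhg"))],
    profiles[, setdiff(names(profiles),
                       c("group", "diabetes", "denervation"))],
    by = "id")
  stats <- run_stats(config, merged)
  report <- run_report(config, profiles, cohort, out_dir = out_dir)
  invisible(list(cohort = cohort, profiles = profiles, stats = stats,
                 report = report))
}
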