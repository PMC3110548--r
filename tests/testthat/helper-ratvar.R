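# shared fixtures, all generated in code

# quiet, noise-free-ish beat series for round-trip work
rt_spec <- function(n_beats = 300, seed = 7, noise_sd = 0, sap_noise_sd = 0,
                    ...) {
  beat_spec(n_beats = n_beats, seed = seed, noise_sd = noise_sd,
            sap_noise_sd = sap_noise_sd, ...)
}

# beat series straight from a pulse-interval vector (constant pressures)
beats_from_pi <- function(pi_ms, sap = NULL, sap_mean = 178, dap_mean = 141) {
  m <- length(pi_ms) + 1L
  t <- c(0, cumsum(pi_ms / 1000))
  if (is.null(sap)) sap <- rep(sap_mean, m)
  beat_series(t, sap, rep(dap_mean, m - 1L))
}

# AR(2) sample of length n (innovation SD 1)
sim_ar2 <- function(n, a1 = 1.2, a2 = -0.8, seed = 1) {
  set.seed(seed)
  as.numeric(arima.sim(list(ar = c(a1, a2)), n = n))
}

# hand-built spectral component table
make_components <- function(freq, power, pair = TRUE) {
  out <- data.frame(central_freq = freq, power = power,
                    is_complex_pair = pair,
                    modulus = rep(0.9, length(freq)))
  class(out) <- c("spectral_components", "data.frame")
  out
}

# minimal band_powers object
make_bp <- function(lf, hf) {
  structure(list(vlf_abs = 0, lf_abs = lf, hf_abs = hf, total = lf + hf,
                 lf_nu = NA_real_, hf_nu = NA_real_, lf_hf = NA_real_,
                 lf_peak = NA_real_, hf_peak = NA_real_),
            class = "band_powers")
}

# cohort design from the default config with overridden group sizes;
# null = TRUE gives all four groups the first group's distributions
make_design <- function(n_per_group, seed = NULL, null = FALSE,
                        n_beats = 1200) {
  cfg <- pipeline_config()
  groups <- cfg$groups
  for (i in seq_along(groups)) {
    groups[[i]]$n_animals <- n_per_group
    if (null) {
      groups[[i]]$outcomes <- groups[[1]]$outcomes
      groups[[i]]$albumin <- groups[[1]]$albumin
      groups[[i]]$beats <- groups[[1]]$beats
    }
  }
  cohort_design(groups, albumin_interval = cfg$albumin_interval,
                n_beats = n_beats, seed = seed)
}

# raw 2x2 data frame with given cell means/sds/ns (exact sample moments)
cells_to_raw <- function(m, s, n) {
  # order: (no,no), (no,yes), (yes,no), (yes,yes) as (diabetes, denervation)
  lv <- list(c("no", "no"), c("no", "yes"), c("yes", "no"), c("yes", "yes"))
  out <- list()
  for (i in 1:4) {
    z <- seq_len(n[i])
    z <- (z - mean(z)) / sd(z)
    out[[i]] <- data.frame(diabetes = lv[[i]][1], denervation = lv[[i]][2],
                           y = m[i] + s[i] * z)
  }
  df <- do.call(rbind, out)
  df$diabetes <- factor(df$diabetes, levels = c("no", "yes"))
  df$denervation <- factor(df$denervation, levels = c("no", "yes"))
  df
}

cells_df <- function(m, s, n) {
  data.frame(diabetes = c("no", "no", "yes", "yes"),
             denervation = c("no", "yes", "no", "yes"),
             mean = m, sd = s, n = n)
}

# reference cell summaries for one outcome, as a 4-row cells data frame
ref_cells <- function(outcome) {
  df <- reference_summaries()
  df <- df[df$outcome == outcome, ]
  data.frame(diabetes = as.character(df$diabetes),
             denervation = as.character(df$denervation),
             mean = df$mean, sd = df$sd, n = df$n)
}

# default config shrunk for fast end-to-end runs
small_cfg <- function(seed = NULL) {
  cfg <- pipeline_config(seed = seed)
  cfg$n_beats <- 320
  for (i in 1:4) cfg$groups[[i]]$n_animals <- 3
  cfg
}

cfg_bands_test <- function(cfg) ratvar:::cfg_bands(cfg)

expect_anova_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$table$F, b$table$F, tolerance = tol)
  expect_equal(a$table$p, b$table$p, tolerance = tol)
  expect_equal(a$residual$MS, b$residual$MS, tolerance = tol)
  expect_identical(a$residual$df, b$residual$df)
}
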