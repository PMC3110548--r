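test_that("degenerate spec gives a constant pulse-interval series", {
  b <- simulate_beat_series(beat_spec(mean_pi = 200, lf_amp = 0, hf_amp = 0,
                                      noise_sd = 0, sap_lf_amp = 0,
                                      sap_hf_amp = 0, sap_noise_sd = 0,
                                      n_beats = 10, seed = 1))
  expect_equal(b$pi_ms, rep(200, 10))
  expect_equal(length(b$beat_times), 11L)
  expect_equal(diff(b$beat_times), rep(0.2, 10))
})

test_that("mean heart rate follows the configured mean pulse interval", {
  b <- simulate_beat_series(beat_spec(mean_pi = 155.92, lf_amp = 0,
                                      hf_amp = 0, noise_sd = 1,
                                      n_beats = 2000, seed = 3))
  hr <- summarize_hemodynamics(b)$hr
  expect_equal(hr, 60000 / 155.92, tolerance = 0.5 / 384)  # ~384.8 bpm
})

test_that("noise-free sinusoidal modulation carries analytic variance", {
  # a sinusoid of amplitude A contributes A^2/2 to the tachogram variance
  b <- simulate_beat_series(beat_spec(lf_amp = 4, hf_amp = 6, noise_sd = 0,
                                      n_beats = 3000, seed = 5))
  expect_equal(var(b$pi_ms), 4^2 / 2 + 6^2 / 2, tolerance = 0.05)
})

test_that("invalid beat specs are rejected", {
  expect_error(beat_spec(mean_pi = -1), class = "ratvar_invalid_spec")
  expect_error(beat_spec(lf_freq = 2, hf_freq = 0.4),
               class = "ratvar_invalid_spec")
  expect_error(beat_spec(lf_amp = -1), class = "ratvar_invalid_spec")
  expect_error(beat_spec(sap_mean = 100, dap_mean = 120),
               class = "ratvar_invalid_spec")
  expect_error(beat_spec(n_beats = 0), class = "ratvar_invalid_spec")
})

test_that("non-positive pulse-interval draws are clipped at 10 ms with a warning", {
  expect_warning(
    b <- simulate_beat_series(beat_spec(mean_pi = 20, noise_sd = 40,
                                        lf_amp = 0, hf_amp = 0,
                                        n_beats = 50, seed = 2)),
    "clipped")
  expect_true(all(b$pi_ms > 0))
  expect_true(any(abs(b$pi_ms - 10) < 1e-6))  # clipped draws sit at 10 ms
})

test_that("waveform extrema reproduce systolic and diastolic levels", {
  b <- simulate_beat_series(beat_spec(sap_mean = 178, dap_mean = 141,
                                      lf_amp = 0, hf_amp = 0, noise_sd = 0,
                                      sap_lf_amp = 0, sap_hf_amp = 0,
                                      sap_noise_sd = 0, n_beats = 1, seed = 1))
  w <- simulate_bp_waveform(b, 2000)
  expect_equal(max(w$samples), 178, tolerance = 0.05)
  expect_equal(min(w$samples), 141, tolerance = 0.05)
})

test_that("waveform synthesis rejects empty or non-monotone beat input", {
  expect_error(simulate_bp_waveform(list()), class = "ratvar_invalid_beats")
  expect_error(beat_series(numeric(0), numeric(0), numeric(0)),
               class = "ratvar_invalid_beats")
  expect_error(beat_series(c(0, 0.2, 0.1), rep(178, 3), rep(141, 2)),
               class = "ratvar_invalid_beats")
  b <- simulate_beat_series(rt_spec(n_beats = 5))
  expect_error(simulate_bp_waveform(b, sampling_rate = 50),
               class = "ratvar_invalid_spec")
})

test_that("cohort with zero SDs puts every animal exactly at the group mean", {
  d <- make_design(3, seed = 4, n_beats = 30)
  for (i in seq_along(d$groups)) {
    d$groups[[i]]$outcomes <- lapply(d$groups[[i]]$outcomes,
                                     function(o) list(mean = o$mean, sd = 0))
    alb <- d$groups[[i]]$albumin
    d$groups[[i]]$albumin <- list(median = alb$median, lo = alb$median,
                                  hi = alb$median)
  }
  co <- simulate_cohort(d, with_beats = FALSE)
  for (g in d$groups) {
    sub <- co$animals[co$animals$group == g$label, ]
    expect_equal(sub$weight_initial, rep(g$outcomes$weight_initial$mean, 3))
    expect_equal(sub$urinary_albumin, rep(g$albumin$median, 3))
  }
})

test_that("large-sample outcome means converge to design values", {
  d <- make_design(10000, seed = 9)
  co <- simulate_cohort(d, with_beats = FALSE)
  shr <- co$animals[co$animals$group == "SHR", ]
  expect_lt(abs(mean(shr$weight_initial) - 258), 0.5)
  stz <- co$animals[co$animals$group == "STZ-SHR", ]
  # 45-day glycemia is untruncated: population centred at the group mean
  expect_lt(abs(mean(stz$glycemia_45d) - 417.5), 4)
})

test_that("inclusion rule retains by strict glycemia threshold", {
  rec <- data.frame(
    id = c("a", "b", "c"),
    diabetes = factor(c("yes", "yes", "no"), levels = c("no", "yes")),
    glycemia_initial = c(414.1, 300, 92))
  expect_message(apply_inclusion(rec), "excluded 1")
  out <- suppressMessages(apply_inclusion(rec))
  expect_identical(out$id, c("a", "c"))
  expect_identical(attr(out, "n_excluded"), 1L)
  # idempotent
  out2 <- apply_inclusion(out)
  expect_identical(out2$id, out$id)
  expect_identical(attr(out2, "n_excluded"), 0L)
})

test_that("default cohorts pass inclusion unchanged (truncated induction draws)", {
  co <- simulate_cohort(default_cohort_design(seed = 21), with_beats = FALSE)
  out <- apply_inclusion(co$animals)
  expect_identical(nrow(out), nrow(co$animals))
})

test_that("identical design and seed give identical cohorts", {
  d <- make_design(3, seed = 123, n_beats = 40)
  c1 <- simulate_cohort(d)
  c2 <- simulate_cohort(d)
  expect_identical(c1$animals, c2$animals)
  expect_identical(lapply(c1$beats, `[[`, "pi_ms"),
                   lapply(c2$beats, `[[`, "pi_ms"))
})

test_that("cohort design validation enforces the 2x2 grid", {
  cfg <- pipeline_config()
  g <- cfg$groups
  g[[2]]$diabetes <- g[[1]]$diabetes
  g[[2]]$denervation <- g[[1]]$denervation
  expect_error(cohort_design(g), class = "ratvar_invalid_design")
  expect_error(cohort_design(cfg$groups[1:3]), class = "ratvar_invalid_design")
})

test_that("albumin interval interpretations give different log-scale spreads", {
  cfg <- pipeline_config()
  d_rng <- cohort_design(cfg$groups, albumin_interval = "range", seed = 1)
  d_iqr <- cohort_design(cfg$groups, albumin_interval = "iqr", seed = 1)
  c_rng <- simulate_cohort(d_rng, with_beats = FALSE)
  c_iqr <- simulate_cohort(d_iqr, with_beats = FALSE)
  v <- function(co) var(log(co$animals$urinary_albumin[co$animals$group == "SHR"]))
  # same brackets read as a min-max range imply a smaller SD than as an IQR
  expect_lt(v(c_rng), v(c_iqr))
})
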