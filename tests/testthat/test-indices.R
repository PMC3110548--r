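test_that("alpha index follows its closed form", {
  expect_equal(alpha_lf(4, 1), 2)
  expect_equal(alpha_lf(7.3, 7.3), 1)
  # group-mean LF powers of the hypertensive controls give ~0.53 ms/mmHg
  expect_equal(alpha_lf(5.17, 18.49), 0.5288, tolerance = 1e-3)
  expect_true(is.na(alpha_lf(4, 0)))
  expect_error(alpha_lf(-1, 2), class = "ratvar_invalid_power")
})

test_that("alpha index is scale-consistent through the spectral pipeline", {
  # scaling the tachogram by c scales LF power by c^2 and alpha by c
  x <- sim_ar2(300, 1.0, -0.5, seed = 9) + 5 * sin(2 * pi * 0.45 * (1:300) * 0.156)
  f1 <- fragment(x + 150, "tachogram")
  f2 <- fragment(2 * x + 150, "tachogram")
  f2$mean_interval <- f1$mean_interval
  lf_of <- function(f) band_powers(decompose_spectrum(fit_ar(f, 10)))$lf_abs
  a1 <- alpha_lf(lf_of(f1), 3.0)
  a2 <- alpha_lf(lf_of(f2), 3.0)
  expect_equal(a2, 2 * a1, tolerance = 1e-6)
})

test_that("sympathovagal balance is a per-animal ratio with closed forms", {
  expect_equal(sympathovagal_balance(make_bp(3, 3)), 1)
  expect_equal(sympathovagal_balance(make_bp(2, 6)), 1 / 3, tolerance = 1e-12)
  expect_true(is.na(sympathovagal_balance(make_bp(2, 0))))
})

test_that("mean of per-animal ratios differs from ratio of group means", {
  set.seed(4)
  lf <- rlnorm(50, 0, 0.8)
  hf <- rlnorm(50, 1, 0.8)
  per_animal <- mean(lf / hf)
  of_means <- mean(lf) / mean(hf)
  expect_gt(abs(per_animal - of_means) / of_means, 0.05)  # Jensen gap
})

test_that("group aggregation is permutation-invariant and validates size", {
  df <- data.frame(a = c(1, 2, 3, 4), b = c(10, 10, 20, NA))
  g <- c("x", "x", "y", "y")
  agg <- aggregate_group(df, g)
  expect_equal(agg$mean[agg$group == "x" & agg$field == "a"], 1.5)
  expect_equal(agg$n_used[agg$group == "y" & agg$field == "b"], 1L)
  perm <- c(3, 1, 4, 2)
  agg2 <- aggregate_group(df[perm, ], g[perm])
  o <- function(d) d[order(d$group, d$field), c("mean", "sd", "n_used")]
  expect_equal(o(agg2), o(agg), ignore_attr = TRUE)
  # two identical animals: SD 0, mean = value
  same <- data.frame(a = c(5, 5))
  agg3 <- aggregate_group(same, c("g", "g"))
  expect_equal(agg3$mean, 5)
  expect_equal(agg3$sd, 0)
  expect_error(aggregate_group(data.frame(a = 1), "g"),
               class = "ratvar_invalid_group")
})

test_that("analyze_beats averages per-fragment results and flags counts", {
  b <- simulate_beat_series(beat_spec(n_beats = 640, noise_sd = 4,
                                      lf_amp = 4, hf_amp = 5,
                                      sap_noise_sd = 3, sap_lf_amp = 4,
                                      sap_hf_amp = 2, seed = 14))
  pr <- suppressWarnings(analyze_beats(b, target_len = 300))
  expect_s3_class(pr, "autonomic_profile")
  expect_identical(pr$n_fragments, 2L)
  expect_identical(nrow(pr$fragments), 2L)
  expect_equal(pr$lf_hf, mean(pr$fragments$lf_hf))
  expect_equal(pr$alpha_lf, mean(pr$fragments$alpha_lf))
  # totals are fragment variances, not AR sums
  expect_equal(pr$hrv$total,
               mean(c(var(b$pi_ms[1:300]), var(b$pi_ms[301:600]))))
  # LF oscillation injected at 0.45 Hz is found inside the LF band
  expect_true(pr$hrv$lf_peak >= 0.2 && pr$hrv$lf_peak < 0.75)
})
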