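test_that("white noise yields near-zero AR coefficients", {
  set.seed(1)
  x <- rnorm(2000)
  f <- fragment(x + 200, "tachogram")
  m <- fit_ar(f, 5)
  expect_true(all(abs(m$coefficients) < 3 / sqrt(2000)))
  expect_equal(m$innovation_variance, var(x), tolerance = 0.02)
})

test_that("Burg recovers AR(2) parameters on simulated data", {
  x <- sim_ar2(3000, 1.2, -0.8, seed = 42)
  m <- fit_ar(fragment(x + 200, "tachogram"), 2)
  expect_equal(m$coefficients, c(1.2, -0.8), tolerance = 0.05)
})

test_that("long-series Burg agrees with the exact Yule-Walker solution", {
  # true autocorrelations of a stationary AR(2): rho1 = a1/(1-a2),
  # rho2 = a1 rho1 + a2; the Yule-Walker system solved with them returns
  # the generating coefficients exactly
  a1 <- 1.2; a2 <- -0.8
  rho1 <- a1 / (1 - a2)
  rho2 <- a1 * rho1 + a2
  yw <- solve(matrix(c(1, rho1, rho1, 1), 2), c(rho1, rho2))
  expect_equal(yw, c(a1, a2), tolerance = 1e-12)  # oracle self-check
  x <- sim_ar2(50000, a1, a2, seed = 99)
  m <- fit_ar(fragment(x + 200, "tachogram"), 2)
  expect_equal(m$coefficients, yw, tolerance = 0.01)
})

test_that("Burg matches the reference implementation coefficient-for-coefficient", {
  set.seed(12)
  x <- sim_ar2(500, 0.9, -0.5, seed = 12)
  for (ord in c(2, 6, 12)) {
    m <- fit_ar(fragment(x + 150, "tachogram"), ord)
    ref <- stats::ar.burg(x, aic = FALSE, order.max = ord, demean = TRUE)
    expect_equal(m$coefficients, unname(ref$ar), tolerance = 1e-8)
  }
})

test_that("fitted models are stable by construction", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- cumsum(rnorm(400))  # near-unit-root input
    m <- fit_ar(fragment(x - min(x) + 150, "tachogram"), 10)
    roots <- polyroot(c(-rev(m$coefficients), 1))
    expect_true(all(Mod(roots) < 1))
  }
})

test_that("fit_ar validates order, length and variance", {
  f <- fragment(rnorm(20) + 150, "tachogram")
  expect_error(fit_ar(f, 0), class = "ratvar_invalid_spec")
  expect_error(fit_ar(f, 10), class = "ratvar_invalid_fragment")
  flat <- fragment(rep(150, 50), "tachogram")
  expect_error(fit_ar(flat, 4), class = "ratvar_zero_variance")
})

test_that("AIC order selection penalizes structureless data to the boundary", {
  set.seed(3)
  f <- fragment(rnorm(300) + 150, "tachogram")
  expect_identical(as.integer(select_order(f, 8, 20)), 8L)
})

test_that("AIC never underfits a strong AR(2) signal and matches its formula", {
  x <- sim_ar2(300, 1.2, -0.8, seed = 6)
  f <- fragment(x + 150, "tachogram")
  ord <- select_order(f, 2, 20)
  expect_gte(as.integer(ord), 2L)
  # recompute AIC(p) = n log(sigma2_p) + 2p from the raw recursion
  fit <- ratvar:::burg_recursion(f$values, 20)
  aic <- vapply(2:20, function(p) 300 * log(fit$vars[p + 1]) + 2 * p,
                numeric(1))
  expect_equal(unname(attr(ord, "aic")), aic, tolerance = 1e-12)
  expect_identical(as.integer(ord), (2:20)[which.min(aic)])
})

test_that("an all-zero model decomposes to a single flat component", {
  f <- fragment(rnorm(100) + 150, "tachogram")
  m <- ratvar:::new_ar_model(c(0, 0), 2.5, f, 2L)
  comp <- decompose_spectrum(m)
  expect_identical(nrow(comp), 1L)
  expect_equal(comp$power, 2.5)
  expect_false(comp$is_complex_pair)
})

test_that("a complex pole pair maps to its oscillation frequency in Hz", {
  dt <- 0.156
  th <- 2 * pi * 0.5 * dt       # pole angle for a 0.5 Hz oscillation
  a <- c(2 * 0.9 * cos(th), -0.81)
  f <- fragment(rnorm(100) + 150, "tachogram")
  f$mean_interval <- dt
  m <- ratvar:::new_ar_model(a, 1, f, 2L)
  comp <- decompose_spectrum(m)
  expect_identical(nrow(comp), 1L)
  expect_true(comp$is_complex_pair)
  expect_equal(comp$central_freq, 0.5, tolerance = 0.01)
})

test_that("component powers sum to the quadrature integral of the density", {
  for (seed in c(4, 14, 24)) {
    x <- sim_ar2(400, 1.0, -0.6, seed = seed) + rnorm(400)
    f <- fragment(x + 150, "tachogram")
    m <- fit_ar(f, 8)
    comp <- decompose_spectrum(m)
    nyq <- 1 / (2 * m$mean_interval)
    iv <- integrate(function(fr) ratvar:::ar_psd(m, fr), -nyq, nyq,
                    rel.tol = 1e-9, subdivisions = 2000L)$value
    expect_equal(sum(comp$power), iv, tolerance = 0.005)
  }
})

test_that("doubling the mean interval halves every central frequency", {
  x <- sim_ar2(300, 1.1, -0.7, seed = 5)
  f1 <- fragment(x - min(x) + 10, "systogram", mean_interval = 0.15)
  f2 <- fragment(x - min(x) + 10, "systogram", mean_interval = 0.30)
  c1 <- decompose_spectrum(fit_ar(f1, 6))
  c2 <- decompose_spectrum(fit_ar(f2, 6))
  expect_equal(c2$central_freq, c1$central_freq / 2, tolerance = 1e-12)
  expect_equal(c2$power, c1$power, tolerance = 1e-12)
})

test_that("power decomposition is scale-equivariant", {
  x <- sim_ar2(300, 1.1, -0.7, seed = 16)
  f1 <- fragment(x + 150, "tachogram")
  f2 <- fragment(3 * x + 150, "tachogram")
  f2$mean_interval <- f1$mean_interval
  c1 <- decompose_spectrum(fit_ar(f1, 6))
  c2 <- decompose_spectrum(fit_ar(f2, 6))
  expect_equal(c2$power, 9 * c1$power, tolerance = 1e-8)
})
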