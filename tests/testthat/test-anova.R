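test_that("four identical cells give F = 0 and p = 1 for every effect", {
  df <- cells_to_raw(m = rep(5, 4), s = rep(1, 4), n = rep(4, 4))
  tb <- two_way_anova(df, "y")
  expect_equal(tb$table$F, rep(0, 3), tolerance = 1e-12)
  expect_equal(tb$table$p, rep(1, 3), tolerance = 1e-12)
})

test_that("balanced designs match the classical cell-means decomposition", {
  set.seed(7)
  n <- 6
  df <- cells_to_raw(m = c(10, 12, 15, 20), s = c(2, 2.5, 1.5, 2), n = rep(n, 4))
  tb <- two_way_anova(df, "y")
  # classical balanced two-way oracle from cell means
  cm <- tapply(df$y, list(df$diabetes, df$denervation), mean)
  grand <- mean(df$y)
  SS_dia <- 2 * n * sum((rowMeans(cm) - grand)^2)
  SS_den <- 2 * n * sum((colMeans(cm) - grand)^2)
  SS_int <- n * sum((cm - outer(rowMeans(cm), colMeans(cm), `+`) + grand)^2)
  SS_res <- sum(tapply(df$y, list(df$diabetes, df$denervation),
                       function(v) sum((v - mean(v))^2)))
  df_res <- 4 * (n - 1)
  F_oracle <- c(SS_den, SS_dia, SS_int) / (SS_res / df_res)
  expect_equal(tb$table$F, F_oracle, tolerance = 1e-9)
  expect_equal(tb$residual$df, df_res)
})

test_that("summary-based ANOVA equals the raw-data ANOVA exactly", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(3:9, 4, replace = TRUE)
    m <- rnorm(4, 100, 20)
    s <- runif(4, 1, 10)
    df <- cells_to_raw(m, s, n)
    raw <- two_way_anova(df, "y")
    summ <- anova_from_summary(cells_df(m, s, n))
    expect_anova_equal(raw, summ, tol = 1e-9)
  }
})

test_that("reference weight summaries reproduce the published factorial p-values", {
  tb <- anova_from_summary(ref_cells("weight_initial"))
  p <- setNames(tb$table$p, tb$table$effect)
  expect_lt(abs(p["interaction"] - 0.729), 0.05)
  expect_lt(abs(p["denervation"] - 0.452), 0.05)
  expect_lt(abs(p["diabetes"] - 0.278), 0.05)
  tb45 <- anova_from_summary(ref_cells("weight_45d"))
  expect_lt(tb45$table$p[tb45$table$effect == "diabetes"], 0.001)
})

test_that("ANOVA validates cells and degenerate variance", {
  df <- cells_to_raw(rep(5, 4), rep(0, 4), rep(3, 4))
  expect_error(two_way_anova(df, "y"), class = "ratvar_zero_variance")
  expect_error(anova_from_summary(cells_df(rep(5, 4), rep(0, 4), rep(3, 4))),
               class = "ratvar_zero_variance")
  expect_error(anova_from_summary(cells_df(1:4, rep(1, 4), c(1, 3, 3, 3))),
               class = "ratvar_invalid_cells")
  small <- cells_to_raw(1:4, rep(1, 4), c(2, 2, 2, 2))
  expect_error(two_way_anova(small[-1, ], "y"), class = "ratvar_empty_cell")
})

test_that("two-group SNK coincides with the pooled t-test", {
  set.seed(20)
  for (i in 1:40) {
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    shift <- runif(1, 0, 2)
    g1 <- rnorm(n1)
    g2 <- rnorm(n2, shift)
    df <- data.frame(y = c(g1, g2), g = rep(c("a", "b"), c(n1, n2)))
    snk <- snk_posthoc(df, "y", alpha = 0.05, group_name = "g")
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_identical(snk$pairs$significant, tt$p.value < 0.05)
  }
})

test_that("extreme separation flags all pairs; identical groups flag none", {
  set.seed(5)
  wide <- data.frame(
    y = c(rnorm(5, 0), rnorm(5, 10), rnorm(5, 20), rnorm(5, 30)),
    g = rep(letters[1:4], each = 5))
  snk <- snk_posthoc(wide, "y", group_name = "g")
  expect_true(all(snk$pairs$significant))
  same <- data.frame(y = rep(rnorm(5), 4), g = rep(letters[1:4], each = 5))
  snk2 <- snk_posthoc(same, "y", group_name = "g")
  expect_false(any(snk2$pairs$significant))
})

test_that("no significant pair is nested inside a non-significant span", {
  set.seed(33)
  for (i in 1:30) {
    df <- data.frame(y = rnorm(24, rep(runif(4, 0, 2), each = 6)),
                     g = rep(letters[1:4], each = 6))
    snk <- snk_posthoc(df, "y", group_name = "g")
    pr <- snk$pairs
    ord <- snk$means$group
    pos <- function(g) match(g, ord)
    for (r in which(!pr$significant)) {
      i1 <- pos(pr$group1[r]); j1 <- pos(pr$group2[r])
      inside <- pos(pr$group1) >= min(i1, j1) & pos(pr$group2) <= max(i1, j1)
      expect_false(any(pr$significant[inside]))
    }
  }
})

test_that("log transform maps known values and rejects non-positive data", {
  df <- data.frame(id = c("r1", "r2", "r3"),
                   urinary_albumin = c(1, exp(1), exp(2)))
  out <- log_transform_outcome(df, "urinary_albumin")
  expect_equal(out$urinary_albumin, c(0, 1, 2))
  expect_true("urinary_albumin" %in% attr(out, "log_transformed"))
  bad <- data.frame(id = c("r1", "r2"), urinary_albumin = c(5, -1))
  err <- expect_error(log_transform_outcome(bad, "urinary_albumin"),
                      class = "ratvar_nonpositive_value")
  expect_match(conditionMessage(err), "r2")
})

test_that("log transform normalizes simulated albumin more often than not", {
  set.seed(44)
  better <- 0L
  for (i in 1:100) {
    x <- rlnorm(30, meanlog = 5, sdlog = 1)
    p_raw <- shapiro.test(x)$p.value
    p_log <- shapiro.test(log(x))$p.value
    if (p_log > p_raw) better <- better + 1L
  }
  expect_gt(better, 80)
})
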