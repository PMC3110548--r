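# 2x2 factorial statistics: unbalanced two-way ANOVA (raw and from cell
# summaries), Student-Newman-Keuls post-hoc, log transform

new_anova_table <- function(F, p, SS, MSE, df_res) {
  eff <- c("denervation", "diabetes", "interaction")
  structure(
    list(table = data.frame(effect = eff, SS = SS, df = 1L, F = F, p = p),
         residual = list(MS = MSE, df = df_res)),
    class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Two-way ANOVA (Type III, sum-to-zero contrasts)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Residual: MS = %.4g on %d df\n", x$residual$MS, x$residual$df))
  invisible(x)
}

#' Unbalanced two-way ANOVA on raw records
#'
#' Fits `outcome ~ denervation * diabetes` by least squares under
#' sum-to-zero contrasts and reports Type-III F tests for the two main
#' effects and the interaction. In the 2x2 design every effect has one
#' degree of freedom, so the Type-III F is the squared t of the
#' corresponding coefficient.
#'
#' @param records Data frame with factors `diabetes`, `denervation`
#'   (levels no/yes) and the outcome column.
#' @param outcome_name Name of a numeric outcome column.
#' @return An `anova_table`: per-effect sum of squares, df, F and p, plus
#'   the residual mean square and df.
#' @section Errors:
#' Raises `"ratvar_empty_cell"` unless all four cells have >= 2
#' observations, and `"ratvar_zero_variance"` when the residual variance
#' is zero.
#' @export
two_way_anova <- function(records, outcome_name) {
  df <- check_records(records, outcome_name)
  y <- df[[outcome_name]]
  cell_var <- tapply(y, interaction(df$diabetes, df$denervation), var)
  if (all(cell_var == 0)) {
    ratvar_error("zero residual variance", "ratvar_zero_variance")
  }
  fit <- lm(y ~ denervation * diabetes, data = df,
            contrasts = list(denervation = contr.sum, diabetes = contr.sum))
  sm <- summary(fit)$coefficients
  if (!all(is.finite(sm[, "t value"]))) {
    ratvar_error("zero residual variance", "ratvar_zero_variance")
  }
  df_res <- fit$df.residual
  MSE <- sum(fit$residuals^2) / df_res
  Fv <- sm[2:4, "t value"]^2
  pv <- pf(Fv, 1, df_res, lower.tail = FALSE)
  new_anova_table(unname(Fv), unname(pv), unname(Fv * MSE), MSE, df_res)
}

check_records <- function(records, outcome_name) {
  if (inherits(records, "cohort")) records <- records$animals
  for (f in c("diabetes", "denervation")) {
    if (!f %in% names(records)) {
      ratvar_error(sprintf("records need a `%s` column", f),
                   "ratvar_invalid_records")
    }
    records[[f]] <- factor(records[[f]], levels = c("no", "yes"))
  }
  if (!outcome_name %in% names(records) ||
      !is.numeric(records[[outcome_name]])) {
    ratvar_error(sprintf("`%s` must be a numeric column", outcome_name),
                 "ratvar_invalid_records")
  }
  records <- records[!is.na(records[[outcome_name]]), , drop = FALSE]
  cellsize <- table(records$diabetes, records$denervation)
  if (any(cellsize < 2)) {
    ratvar_error("every cell of the 2x2 design needs >= 2 observations",
                 "ratvar_empty_cell")
  }
  records
}

#' Two-way ANOVA from printed cell summaries
#'
#' In the factorial model the cell means, SDs and sizes are sufficient
#' statistics, so the ANOVA table of any raw data with those summaries can
#' be reconstructed exactly. Type-III sums of squares for the 2x2 design
#' are the unweighted cell-mean contrasts
#' `SS = L^2 / sum(c_ij^2 / n_ij)` with contrast coefficients +-1/2 for
#' the main effects and +-1 for the interaction; the residual sum of
#' squares is `sum((n_ij - 1) s_ij^2)`.
#'
#' @param cells A data frame with one row per cell and columns
#'   `diabetes`, `denervation` (`"no"`/`"yes"`), `mean`, `sd`, `n`
#'   (all four cells present, `n >= 2`, `sd >= 0`).
#' @return An `anova_table`, identical (to machine precision) to
#'   [two_way_anova()] on any raw data with these cell summaries.
#' @export
anova_from_summary <- function(cells) {
  need <- c("diabetes", "denervation", "mean", "sd", "n")
  if (!is.data.frame(cells) || !all(need %in% names(cells)) ||
      nrow(cells) != 4L) {
    ratvar_error("`cells` must be a 4-row data frame with diabetes, denervation, mean, sd, n",
                 "ratvar_invalid_cells")
  }
  if (any(cells$n < 2) || any(cells$sd < 0)) {
    ratvar_error("cells need n >= 2 and sd >= 0", "ratvar_invalid_cells")
  }
  key <- paste(cells$diabetes, cells$denervation)
  want <- c("no no", "no yes", "yes no", "yes yes")
  if (!setequal(key, want)) {
    ratvar_error("cells must span the 2x2 no/yes grid", "ratvar_invalid_cells")
  }
  o <- match(want, key)  # m1=(ctl,sham) m2=(ctl,RD) m3=(diab,sham) m4=(diab,RD)
  m <- cells$mean[o]; s <- cells$sd[o]; n <- cells$n[o]
  L_den <- (m[1] - m[2] + m[3] - m[4]) / 2   # sham - denervated
  L_dia <- (m[1] + m[2] - m[3] - m[4]) / 2   # control - diabetic
  L_int <- m[1] - m[2] - m[3] + m[4]
  SS_den <- L_den^2 / sum(0.25 / n)
  SS_dia <- L_dia^2 / sum(0.25 / n)
  SS_int <- L_int^2 / sum(1 / n)
  df_res <- as.integer(sum(n)) - 4L
  SS_res <- sum((n - 1) * s^2)
  if (SS_res <= 0) {
    ratvar_error("zero residual variance", "ratvar_zero_variance")
  }
  MSE <- SS_res / df_res
  Fv <- c(SS_den, SS_dia, SS_int) / MSE
  pv <- pf(Fv, 1, df_res, lower.tail = FALSE)
  new_anova_table(Fv, pv, c(SS_den, SS_dia, SS_int), MSE, df_res)
}

#' Student-Newman-Keuls post-hoc comparisons
#'
#' Ranks the group means and performs the stepwise studentized-range
#' procedure: the span of `r` ordered means is tested against
#' `qtukey(1 - alpha, r, df)`; a non-significant span is homogenized (all
#' pairs inside it are declared non-significant and not tested further),
#' a significant span is split and its sub-spans tested recursively. With
#' unequal group sizes each comparison uses the harmonic mean of the two
#' group sizes, so for two groups the decision coincides with a two-sided
#' pooled t-test at `alpha`.
#'
#' @param records Data frame with a grouping column and a numeric outcome,
#'   or a `cohort`. With `group_name = NULL` and `diabetes`/`denervation`
#'   columns present, the four factorial cells are compared.
#' @param outcome_name Numeric outcome column name.
#' @param alpha Significance level (default 0.05).
#' @param group_name Optional name of the grouping column.
#' @return A `snk_result`: data frame `pairs` (`group1`, `group2`, `diff`,
#'   `q`, `q_crit`, `span`, `significant`) and `means` (sorted group
#'   means and sizes). The pooled error term is the one-way MSE over the
#'   compared groups.
#' @export
snk_posthoc <- function(records, outcome_name, alpha = 0.05,
                        group_name = NULL) {
  if (inherits(records, "cohort")) records <- records$animals
  if (is.null(group_name)) {
    if (all(c("diabetes", "denervation") %in% names(records))) {
      records$.group <- interaction(records$denervation, records$diabetes,
                                    drop = TRUE, sep = "/")
      levels(records$.group) <- c("sham/ctl", "RD/ctl", "sham/diab",
                                  "RD/diab")[seq_along(levels(records$.group))]
      group_name <- ".group"
    } else {
      ratvar_error("supply `group_name` or diabetes/denervation columns",
                   "ratvar_invalid_records")
    }
  }
  g <- factor(records[[group_name]])
  y <- records[[outcome_name]]
  ok <- !is.na(y) & !is.na(g)
  g <- droplevels(g[ok]); y <- y[ok]
  k <- nlevels(g)
  if (k < 2L) {
    ratvar_error("need at least 2 groups", "ratvar_invalid_records")
  }
  ns <- tapply(y, g, length)
  if (any(ns < 2)) {
    ratvar_error("every group needs >= 2 observations", "ratvar_empty_cell")
  }
  ms <- tapply(y, g, mean)
  df_res <- length(y) - k
  MSE <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_res
  ord <- order(ms)
  ms <- ms[ord]; ns <- ns[ord]
  sig <- matrix(NA, k, k)  # upper triangle over sorted means
  test_span <- function(i, j) {
    if (!is.na(sig[i, j])) return()
    r <- j - i + 1L
    nh <- 2 / (1 / ns[i] + 1 / ns[j])
    q <- (ms[j] - ms[i]) / sqrt(MSE / nh)
    crit <- qtukey(1 - alpha, r, df_res)
    if (q < crit || MSE == 0 && ms[j] == ms[i]) {
      for (a in i:(j - 1L)) for (b in (a + 1L):j) {
        if (is.na(sig[a, b])) sig[a, b] <<- FALSE
      }
    } else {
      sig[i, j] <<- TRUE
      if (r > 2L) {
        test_span(i, j - 1L)
        test_span(i + 1L, j)
      }
    }
  }
  if (MSE <= 0) {
    # all residuals zero: spans of unequal means are trivially separated
    for (a in 1:(k - 1L)) for (b in (a + 1L):k) sig[a, b] <- ms[b] > ms[a]
  } else {
    test_span(1L, k)
  }
  pairs <- list()
  for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
    nh <- 2 / (1 / ns[a] + 1 / ns[b])
    r <- b - a + 1L
    pairs[[length(pairs) + 1L]] <- data.frame(
      group1 = names(ms)[a], group2 = names(ms)[b],
      diff = unname(ms[b] - ms[a]),
      q = if (MSE > 0) unname((ms[b] - ms[a]) / sqrt(MSE / nh)) else Inf,
      q_crit = qtukey(1 - alpha, r, df_res),
      span = r, significant = sig[a, b])
  }
  structure(list(pairs = do.call(rbind, pairs),
                 means = data.frame(group = names(ms), mean = unname(ms),
                                    n = unname(as.integer(ns))),
                 MSE = MSE, df = df_res, alpha = alpha),
            class = "snk_result")
}

#' @export
print.snk_result <- function(x, ...) {
  cat(sprintf("Student-Newman-Keuls (alpha = %g, MSE = %.4g, df = %d)\n",
              x$alpha, x$MSE, x$df))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Natural-log transform an outcome before analysis
#'
#' Replaces the outcome column with its natural logarithm (the standard
#' pre-treatment for right-skewed urinary albumin); the report layer
#' back-transforms for display. The transform is recorded in attribute
#' `"log_transformed"`.
#'
#' @param records Data frame (or `cohort`) with the outcome column.
#' @param outcome_name Strictly positive numeric column.
#' @return The records with the column replaced by its log.
#' @export
log_transform_outcome <- function(records, outcome_name) {
  is_cohort <- inherits(records, "cohort")
  df <- if (is_cohort) records$animals else records
  v <- df[[outcome_name]]
  if (is.null(v)) {
    ratvar_error(sprintf("no column `%s`", outcome_name),
                 "ratvar_invalid_records")
  }
  bad <- which(!is.na(v) & v <= 0)
  if (length(bad)) {
    who <- if ("id" %in% names(df)) paste(df$id[bad], collapse = ", ")
           else paste("row", paste(bad, collapse = ", "))
    ratvar_error(sprintf("non-positive `%s` for: %s", outcome_name, who),
                 "ratvar_nonpositive_value")
  }
  df[[outcome_name]] <- log(v)
  attr(df, "log_transformed") <-
    unique(c(attr(df, "log_transformed"), outcome_name))
  if (is_cohort) {
    records$animals <- df
    return(records)
  }
  df
}
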