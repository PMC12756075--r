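# Group-comparison and correlation statistics: one-way ANOVA across diagnosis
# groups, pairwise Welch t-tests, and simple linear regression with R^2 and a
# 95% confidence band. No multiple-testing correction is applied; pairwise
# comparisons are exploratory follow-ups to the ANOVA.

#' One-way analysis of variance
#'
#' Classical equal-variance between/within decomposition.
#'
#' @param values numeric outcome vector.
#' @param groups group labels (same length).
#' @return list with `F`, `dof_between`, `dof_within`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_input("need at least two groups")
  if (any(table(groups) < 2)) stop_input("every group needs at least two values")
  fit <- oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(fit$statistic), dof_between = unname(fit$parameter[1]),
       dof_within = unname(fit$parameter[2]), p = fit$p.value)
}

#' Welch two-sample t-test
#'
#' Unpaired t-test with Welch's correction (Welch-Satterthwaite degrees of
#' freedom), two-sided.
#'
#' @param a,b numeric samples (>= 2 values each; at least one with nonzero
#'   variance).
#' @return list with `t`, `dof`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_input("each sample needs >= 2 values")
  if (var(a) == 0 && var(b) == 0)
    stop_input("degenerate input: both samples have zero variance")
  fit <- t.test(a, b, var.equal = FALSE)
  list(t = unname(fit$statistic), dof = unname(fit$parameter), p = fit$p.value)
}

#' Simple linear regression with confidence band
#'
#' Least-squares fit of `y ~ x` with the squared Pearson correlation,
#' the two-sided slope test, and the pointwise 95% confidence band for the
#' mean regression line.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @param band_points number of grid points for the confidence band.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, and `band`
#'   (`data.frame` of `x`, `fit`, `lower`, `upper`).
#' @export
simple_linear_regression <- function(x, y, band_points = 50) {
  if (length(x) < 3) stop_input("need at least 3 observations")
  if (sd(x) == 0) stop_input("x must not be constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  grid <- data.frame(x = seq(min(x), max(x), length.out = band_points))
  ci <- predict(fit, newdata = grid, interval = "confidence", level = 0.95)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       band = data.frame(x = grid$x, fit = ci[, "fit"],
                         lower = ci[, "lwr"], upper = ci[, "upr"]))
}

#' Group summaries as mean and standard error of the mean
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return `data.frame` with `group`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values, groups) {
  groups <- factor(groups,
                   levels = sort(unique(as.character(groups)), method = "radix"))
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g & !is.na(values)]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Group comparisons for a set of cohort variables
#'
#' For each variable: one-way ANOVA across all groups, then all pairwise
#' Welch t-tests (flagged, not filtered; which pairs to interpret after a
#' non-significant ANOVA is left to the analyst).
#'
#' @param table cohort `data.frame`.
#' @param variables columns to compare.
#' @param group_col grouping column name.
#' @return tidy `data.frame` with one row per test.
#' @export
cohort_group_comparisons <- function(table, variables, group_col = "group") {
  lev <- sort(unique(as.character(table[[group_col]])), method = "radix")
  groups <- factor(table[[group_col]], levels = lev)  # locale-independent order
  rows <- list()
  for (v in variables) {
    vals <- table[[v]]
    ok <- !is.na(vals)
    an <- one_way_anova(vals[ok], droplevels(groups[ok]))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, comparison = "ANOVA", statistic = an$F,
      dof = an$dof_within, p = an$p, stringsAsFactors = FALSE)
    lv <- levels(droplevels(groups[ok]))
    for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
      wt <- welch_t_test(vals[ok & groups == lv[i]], vals[ok & groups == lv[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, comparison = paste(lv[i], "vs", lv[j]),
        statistic = wt$t, dof = wt$dof, p = wt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
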