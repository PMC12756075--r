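# L1-penalized linear regression used inside the stability-selection
# procedure. The path solver is cyclic coordinate descent with covariance
# updates and warm starts (compiled; see src/), written in-package because the
# selection loop calls it tens of thousands of times per analysis.
#
# Objective: (1/(2n)) * ||y - b0 - X b||^2 + lambda * ||b||_1, so the whole
# coefficient vector is exactly zero for lambda >= lambda_max =
# max_j |x_j' (y - mean(y))| / n. The intercept is unpenalized and handled by
# exact centering inside the solver.

#' Standardize predictor columns
#'
#' Centers and scales each column by its mean and population standard
#' deviation (the statistics of the supplied sample only, never of held-out
#' data). Constant columns cannot be scaled and are dropped.
#'
#' @param X numeric predictor matrix.
#' @param warn warn when constant columns are dropped.
#' @return list with `X` (standardized, kept columns), `center`, `scale`,
#'   `kept` (logical per input column).
#' @export
standardize_predictors <- function(X, warn = TRUE) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colMeans(Xc^2))
  kept <- scl > 1e-12
  if (!all(kept) && warn)
    warning(sprintf("dropping constant predictor column(s): %s",
                    paste(colnames(X)[!kept], collapse = ", ")), call. = FALSE)
  Xs <- sweep(Xc[, kept, drop = FALSE], 2, scl[kept], "/")
  list(X = Xs, center = ctr, scale = scl, kept = kept)
}

#' Log-spaced penalty grid
#'
#' `n_lambda` values from `lambda_max` (smallest penalty with an all-zero
#' solution) down to `min_ratio * lambda_max`.
#'
#' @param X standardized predictor matrix.
#' @param y outcome (centering handled internally).
#' @param n_lambda grid length.
#' @param min_ratio ratio of smallest to largest penalty.
#' @return decreasing numeric vector of penalties.
#' @export
lasso_lambda_grid <- function(X, y, n_lambda = 100, min_ratio = 1e-4) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / n
  if (lmax <= 0) lmax <- 1e-3  # outcome orthogonal to all predictors
  exp(seq(log(lmax), log(min_ratio * lmax), length.out = n_lambda))
}

#' Fit the LASSO coefficient path
#'
#' Cyclic coordinate descent over a decreasing penalty grid with warm starts.
#' Soft-thresholding produces exact zeros, so `lambda >= lambda_max` returns
#' an exactly zero coefficient vector.
#'
#' @param X predictor matrix (standardize beforehand, e.g. with
#'   [standardize_predictors()], if comparable penalization across columns is
#'   wanted).
#' @param y outcome vector.
#' @param lambda decreasing penalty vector.
#' @param tol convergence tolerance on the largest scaled coefficient change
#'   per sweep.
#' @param maxit maximum coordinate-descent sweeps per penalty.
#' @return list with `beta` (p x length(lambda) matrix, rows named by
#'   column), `a0` (intercepts) and `lambda`.
#' @export
fit_lasso_path <- function(X, y, lambda, tol = 1e-9, maxit = 100000L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  fit <- .cpp_lasso_path(X, as.double(y), as.double(lambda), tol, as.integer(maxit))
  rownames(fit$beta) <- colnames(X)
  fit
}

#' Select the penalty by inner cross-validation
#'
#' K-fold cross-validation over a fixed penalty grid; the minimum-CV-error
#' rule picks the penalty (on ties, the first and therefore largest penalty,
#' i.e. the sparser model).
#'
#' @param X predictor matrix.
#' @param y outcome vector.
#' @param n_inner number of folds.
#' @param lambda decreasing penalty grid.
#' @param seed integer seed for the fold assignment.
#' @param tol solver convergence tolerance.
#' @param fold_id optional explicit fold assignment (e.g. folds drawn over
#'   source observations of a bootstrap sample, so duplicated rows never
#'   straddle train and test); overrides `seed`.
#' @param rule `"min"` picks the penalty with the smallest CV error; `"1se"`
#'   picks the largest penalty whose CV error is within one standard error
#'   (of per-fold mean errors) of the minimum — the conventional conservative
#'   choice when selection, not prediction, is the goal.
#' @return list with `lambda` (selected penalty), `index`, and `cv_mse`
#'   (mean squared prediction error per grid point).
#' @export
inner_cv_select_lambda <- function(X, y, n_inner, lambda, seed, tol = 1e-7,
                                   fold_id = NULL, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  n <- nrow(X)
  if (n < n_inner)
    stop_input("too few observations (%d) for %d inner folds", n, n_inner)
  fold <- fold_id %||% make_outer_folds(n, n_inner, seed)
  sse <- numeric(length(lambda))
  fold_means <- matrix(NA_real_, n_inner, length(lambda))
  for (k in seq_len(n_inner)) {
    tr <- fold != k
    if (all(tr) || !any(tr)) next  # fold received no (or all) rows
    fit <- fit_lasso_path(X[tr, , drop = FALSE], y[tr], lambda, tol = tol)
    pred <- sweep(X[!tr, , drop = FALSE] %*% fit$beta, 2, fit$a0, "+")
    err <- (pred - y[!tr])^2
    sse <- sse + colSums(err)
    fold_means[k, ] <- colMeans(err)
  }
  cv_mse <- sse / n
  idx <- which.min(cv_mse)
  if (rule == "1se") {
    fm <- fold_means[stats::complete.cases(fold_means), , drop = FALSE]
    se <- sd(fm[, idx]) / sqrt(nrow(fm))
    idx <- which(cv_mse <= cv_mse[idx] + se)[1]
  }
  list(lambda = lambda[idx], index = idx, cv_mse = cv_mse)
}
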