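# Bootstrap LASSO stability selection inside nested cross-validation:
# outer folds for honest error estimation, B bootstrap replicates per outer
# training fold for selection stability, an inner CV per replicate for the
# penalty, selection frequencies f = C / (n_outer * B), a frequency-threshold
# reduced model, and a paired full-vs-reduced cross-validated MSE comparison
# on identical outer folds.

#' Selection procedure configuration
#'
#' @param n_outer number of outer cross-validation folds.
#' @param n_bootstrap bootstrap replicates B per outer training fold.
#' @param n_inner inner cross-validation folds for penalty tuning.
#' @param freq_threshold selection-frequency threshold; variables with
#'   `f > freq_threshold` (strict) enter the reduced model.
#' @param n_lambda,lambda_min_ratio penalty grid specification (see
#'   [lasso_lambda_grid()]); the grid is recomputed on every fitting sample.
#' @param lambda_rule inner-CV penalty choice: `"1se"` (default, the
#'   conservative one-standard-error rule, appropriate when the goal is
#'   stable variable selection) or `"min"` (minimum CV error).
#' @param freq_denominator `"outer_times_B"` divides selection counts by
#'   `n_outer * B` so frequencies live in `[0, 1]`; `"B"` uses the literal
#'   per-replicate denominator.
#' @param seed top-level integer seed; all folds and bootstrap draws derive
#'   deterministic child streams from it.
#' @param thresh solver convergence threshold used inside the bootstrap loop.
#' @return a `selection_config` list.
#' @export
selection_config <- function(n_outer = 10, n_bootstrap = 500, n_inner = 10,
                             freq_threshold = 0.5, n_lambda = 100,
                             lambda_min_ratio = 1e-4,
                             lambda_rule = c("1se", "min"),
                             freq_denominator = c("outer_times_B", "B"),
                             seed = 1, thresh = 1e-7) {
  if (n_outer < 2 || n_inner < 2) stop_input("fold counts must be >= 2")
  if (n_bootstrap < 1) stop_input("need at least one bootstrap replicate")
  if (freq_threshold <= 0 || freq_threshold >= 1)
    stop_input("freq_threshold must lie strictly between 0 and 1")
  structure(list(n_outer = n_outer, n_bootstrap = n_bootstrap,
                 n_inner = n_inner, freq_threshold = freq_threshold,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 lambda_rule = match.arg(lambda_rule),
                 freq_denominator = match.arg(freq_denominator),
                 seed = as.integer(seed), thresh = thresh),
            class = "selection_config")
}

#' Assign observations to folds of near-equal size
#'
#' Every observation lands in exactly one fold and fold sizes differ by at
#' most one; deterministic given the seed.
#'
#' @param n number of observations (>= `k`).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per observation.
#' @export
make_outer_folds <- function(n, k, seed) {
  if (n < k) stop_input("cannot split %d observations into %d folds", n, k)
  with_seed(seed, {
    fold <- integer(n)
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
    fold
  })
}

#' Bootstrap resample of a training index set
#'
#' @param train_indices non-empty integer vector.
#' @param seed integer seed.
#' @return indices of equal length, drawn with replacement.
#' @export
bootstrap_sample <- function(train_indices, seed) {
  if (length(train_indices) == 0L) stop_input("empty training index set")
  with_seed(seed, train_indices[sample.int(length(train_indices),
                                           length(train_indices),
                                           replace = TRUE)])
}

#' Selection frequencies across all folds and bootstrap replicates
#'
#' `f(v) = C(v) / (n_outer * B)` where `C(v)` counts how often variable `v`
#' had a nonzero LASSO coefficient across all outer training folds and
#' bootstrap replicates.
#'
#' @param selected_sets list of character vectors (one per replicate).
#' @param n_outer,B accounting dimensions; `length(selected_sets)` must equal
#'   `n_outer * B`.
#' @param predictors full predictor roster (frequencies are defined, possibly
#'   zero, for every predictor).
#' @param denominator `"outer_times_B"` or `"B"`.
#' @return named numeric vector of frequencies.
#' @export
selection_frequencies <- function(selected_sets, n_outer, B, predictors,
                                  denominator = "outer_times_B") {
  if (length(selected_sets) != n_outer * B)
    stop_input("expected %d selection sets, got %d", n_outer * B,
               length(selected_sets))
  counts <- setNames(numeric(length(predictors)), predictors)
  tab <- table(unlist(selected_sets, use.names = FALSE))
  counts[names(tab)] <- as.numeric(tab)
  denom <- if (identical(denominator, "B")) B else n_outer * B
  counts / denom
}

#' Threshold selection frequencies into a retained variable set
#'
#' Strict inequality: a variable at exactly the threshold is excluded.
#'
#' @param frequencies named frequency vector.
#' @param threshold frequency cutoff.
#' @return character vector of retained variable names (original order).
#' @export
reduce_variables <- function(frequencies, threshold = 0.5) {
  names(frequencies)[frequencies > threshold]
}

# OLS with intercept; falls back to a pseudo-inverse fit when the design is
# rank deficient. Returns a coefficient vector aligned with cbind(1, X).
ols_coefficients <- function(X, y) {
  A <- cbind(`(Intercept)` = 1, X)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    warning("rank-deficient design in OLS refit; using pseudo-inverse",
            call. = FALSE)
    return(drop(MASS::ginv(A) %*% y))
  }
  drop(qr.coef(qrA, y))
}

#' Cross-validated MSE of an OLS model over fixed folds
#'
#' Fits ordinary least squares (raw predictor scale) on each outer training
#' fold using only `variables`, computes the squared prediction error for
#' every outer-test observation, and averages globally. An empty variable set
#' gives the intercept-only model. Using one fixed fold assignment for both a
#' full and a reduced model makes their MSE difference a paired comparison of
#' the variable sets alone.
#'
#' @param X full predictor matrix (columns named).
#' @param y outcome vector.
#' @param variables character vector of columns to use (possibly empty).
#' @param fold_id integer fold assignment per observation.
#' @return list with `mse` and `per_observation_errors` (squared errors in
#'   observation order).
#' @export
evaluate_cv_mse <- function(X, y, variables, fold_id) {
  if (length(variables) && !all(variables %in% colnames(X)))
    stop_input("variables not found in predictor matrix: %s",
               paste(setdiff(variables, colnames(X)), collapse = ", "))
  errs <- numeric(length(y))
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    Xtr <- X[tr, variables, drop = FALSE]
    bhat <- ols_coefficients(Xtr, y[tr])
    Xte <- cbind(1, X[!tr, variables, drop = FALSE])
    errs[!tr] <- (y[!tr] - drop(Xte %*% bhat))^2
  }
  list(mse = mean(errs), per_observation_errors = errs)
}

#' Run bootstrap LASSO stability selection with nested cross-validation
#'
#' The full procedure: split complete cases into `n_outer` folds; within each
#' outer training fold draw `n_bootstrap` bootstrap samples; per sample,
#' standardize predictors on that sample, build the penalty grid, select the
#' penalty by inner `n_inner`-fold CV (`lambda_rule`) and record the nonzero
#' coefficient set; convert counts into selection frequencies; retain
#' variables with `f > freq_threshold`; finally compare full and reduced
#' models by cross-validated MSE on the same outer folds (OLS refits on the
#' raw scale). Deterministic given `config$seed`.
#'
#' @param table `data.frame` holding the outcome and all predictors.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param config a [selection_config()].
#' @return an object of class `stability_selection` with elements
#'   `frequencies`, `retained`, `reduced_formula`, `mse_full`, `mse_reduced`,
#'   `per_observation_errors`, `fold_id`, `n_used`, `outcome`, `predictors`,
#'   `config`.
#' @export
run_stability_selection <- function(table, outcome, predictors,
                                    config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  miss <- setdiff(c(outcome, predictors), names(table))
  if (length(miss))
    stop_input("columns missing from table: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(predictors)) stop_input("predictor names must be unique")
  dat <- table[, c(outcome, predictors), drop = FALSE]
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  n <- nrow(dat)
  if (n < config$n_outer)
    stop_input("only %d complete cases for %d outer folds", n, config$n_outer)
  y <- as.numeric(dat[[outcome]])
  X <- as.matrix(dat[, predictors, drop = FALSE])
  storage.mode(X) <- "double"

  seed <- config$seed
  fold_id <- make_outer_folds(n, config$n_outer, derive_seed(seed, 101))
  B <- config$n_bootstrap
  sets <- vector("list", config$n_outer * B)
  for (i in seq_len(config$n_outer)) {
    tr_idx <- which(fold_id != i)
    Xtr <- X[tr_idx, , drop = FALSE]
    ytr <- y[tr_idx]
    for (b in seq_len(B)) {
      bs <- bootstrap_sample(seq_along(tr_idx), derive_seed(seed, 202, i, b))
      Xb <- Xtr[bs, , drop = FALSE]
      yb <- ytr[bs]
      std <- standardize_predictors(Xb, warn = FALSE)  # constants: dropped, counted unselected
      yc <- yb - mean(yb)
      lam <- lasso_lambda_grid(std$X, yc, config$n_lambda, config$lambda_min_ratio)
      # inner folds over *source* rows: duplicates of one observation must
      # never straddle an inner train/test split
      src_fold <- make_outer_folds(length(tr_idx), config$n_inner,
                                   derive_seed(seed, 303, i, b))
      sel <- inner_cv_select_lambda(std$X, yc, config$n_inner, lam,
                                    derive_seed(seed, 303, i, b),
                                    tol = config$thresh,
                                    fold_id = src_fold[bs],
                                    rule = config$lambda_rule)
      path <- fit_lasso_path(std$X, yc, lam, tol = config$thresh)
      nz <- path$beta[, sel$index]
      sets[[(i - 1) * B + b]] <- rownames(path$beta)[nz != 0]
    }
  }
  freqs <- selection_frequencies(sets, config$n_outer, B, predictors,
                                 config$freq_denominator)
  retained <- reduce_variables(freqs, config$freq_threshold)
  full_eval <- evaluate_cv_mse(X, y, predictors, fold_id)
  red_eval <- evaluate_cv_mse(X, y, retained, fold_id)
  structure(list(
    frequencies = freqs,
    retained = retained,
    reduced_formula = format_reduced_formula(outcome, retained, freqs),
    mse_full = full_eval$mse,
    mse_reduced = red_eval$mse,
    per_observation_errors = list(full = full_eval$per_observation_errors,
                                  reduced = red_eval$per_observation_errors),
    fold_id = fold_id,
    n_used = n,
    outcome = outcome,
    predictors = predictors,
    config = config
  ), class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf("<stability_selection> n = %d, %d predictors, B = %d\n",
              x$n_used, length(x$predictors), x$config$n_bootstrap))
  cat("  ", x$reduced_formula, "\n", sep = "")
  cat(sprintf("  CV-MSE full = %.4g, reduced = %.4g\n", x$mse_full, x$mse_reduced))
  invisible(x)
}

#' Format a reduced model the way selection tables report it
#'
#' `"outcome ~ var1 [0.615] + var2 [0.784]"`, bracket values being the
#' selection frequencies; an empty retained set formats as the intercept-only
#' model `"outcome ~ 1"`.
#'
#' @param outcome outcome name.
#' @param retained retained variable names.
#' @param frequencies named selection-frequency vector.
#' @return a single string.
#' @export
format_reduced_formula <- function(outcome, retained, frequencies) {
  if (length(retained) == 0L) return(paste(outcome, "~ 1"))
  terms <- sprintf("%s [%.3f]", retained, frequencies[retained])
  paste(outcome, "~", paste(terms, collapse = " + "))
}
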