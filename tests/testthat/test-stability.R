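test_that("fold assignment is balanced, exhaustive and deterministic", {
  f40 <- make_outer_folds(40, 10, seed = 7)
  expect_true(all(table(f40) == 4))
  expect_length(f40, 40)
  f37 <- make_outer_folds(37, 10, seed = 7)
  expect_equal(sort(as.integer(table(f37))), c(rep(3L, 3), rep(4L, 7)))
  expect_identical(make_outer_folds(37, 10, seed = 7), f37)
  expect_false(identical(make_outer_folds(37, 10, seed = 8), f37))
  expect_error(make_outer_folds(5, 10, seed = 1), "folds")
})

test_that("bootstrap resampling preserves size and the 1 - 1/e unique fraction", {
  expect_length(bootstrap_sample(3:30, seed = 1), 28)
  expect_identical(bootstrap_sample(7L, seed = 1), rep(7L, 1))
  expect_identical(bootstrap_sample(1:10, seed = 3), bootstrap_sample(1:10, seed = 3))
  expect_error(bootstrap_sample(integer(0), seed = 1), "empty")
  uf <- vapply(1:1000, function(s) length(unique(bootstrap_sample(1:100, s))) / 100,
               numeric(1))
  expect_lt(abs(mean(uf) - (1 - exp(-1))), 0.02)
})

test_that("selection frequencies are counts over n_outer x B with full support", {
  sets <- c(rep(list(c("a", "b")), 3), rep(list("a"), 2), list(character(0)))
  f <- selection_frequencies(sets, n_outer = 2, B = 3, predictors = c("a", "b", "c"))
  expect_equal(f, c(a = 5 / 6, b = 0.5, c = 0))
  expect_error(selection_frequencies(sets, 2, 5, c("a")), "accounting|expected")
  fB <- selection_frequencies(sets, 2, 3, c("a", "b", "c"), denominator = "B")
  expect_equal(fB[["a"]], 5 / 3)  # the literal per-replicate denominator can exceed 1
})

test_that("thresholding is strict and monotone", {
  f <- c(a = 0.62, b = 0.50, c = 0.77)
  expect_identical(reduce_variables(f, 0.5), c("a", "c"))
  expect_identical(reduce_variables(c(a = 0.2, b = 0.4), 0.5), character(0))
  expect_identical(reduce_variables(f, 0), c("a", "b", "c"))
  thresholds <- seq(0, 0.9, by = 0.1)
  sizes <- vapply(thresholds, function(t) length(reduce_variables(f, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cross-validated OLS error is exact for a perfect linear fit", {
  set.seed(1)
  x <- rnorm(30)
  X <- cbind(x = x, z = rnorm(30))
  y <- 2 * x
  ev <- evaluate_cv_mse(X, y, "x", make_outer_folds(30, 10, 1))
  expect_lt(ev$mse, 1e-20 * var(y))
})

test_that("the intercept-only model reproduces per-fold means in closed form", {
  set.seed(2)
  y <- rnorm(25, 10, 2)
  X <- cbind(x = rnorm(25))
  fid <- make_outer_folds(25, 5, seed = 3)
  ev <- evaluate_cv_mse(X, y, character(0), fid)
  manual <- numeric(25)
  for (k in 1:5) manual[fid == k] <- (y[fid == k] - mean(y[fid != k]))^2
  expect_equal(ev$per_observation_errors, manual)
  expect_equal(ev$mse, mean(manual))
})

test_that("adding a pure-noise variable does not systematically lower CV error", {
  d <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 60
    x <- rnorm(n); z <- rnorm(n)
    y <- 2 * x + rnorm(n, 0, 0.5)
    X <- cbind(x = x, z = z)
    fid <- make_outer_folds(n, 10, s)
    evaluate_cv_mse(X, y, c("x", "z"), fid)$mse -
      evaluate_cv_mse(X, y, "x", fid)$mse
  }, numeric(1))
  expect_gt(mean(d), -1e-3)
  expect_gte(mean(d >= 0), 0.7)
})

test_that("rank-deficient OLS refits fall back to a pseudo-inverse with warning", {
  set.seed(3)
  x <- rnorm(30)
  X <- cbind(a = x, b = x)  # perfectly collinear
  y <- x + rnorm(30, 0, 0.1)
  expect_warning(ev <- evaluate_cv_mse(X, y, c("a", "b"), make_outer_folds(30, 5, 1)),
                 "pseudo-inverse")
  expect_lt(ev$mse, var(y))
})

test_that("the full procedure is deterministic and respects its contracts", {
  sc <- generate_sparse_cohort(n = 60, p = 8, active = 1:2, beta = 2,
                               noise_sd = 0.5, seed = 4)
  cfg <- selection_config(n_outer = 5, n_bootstrap = 8, n_inner = 5, seed = 42)
  r1 <- run_stability_selection(sc$table, "y", paste0("v", 1:8), cfg)
  r2 <- run_stability_selection(sc$table, "y", paste0("v", 1:8), cfg)
  expect_identical(r1, r2)  # bit-identical under one seed
  expect_true(all(r1$frequencies >= 0 & r1$frequencies <= 1))
  expect_true(all(r1$retained %in% paste0("v", 1:8)))
  expect_setequal(names(r1$frequencies), paste0("v", 1:8))
  expect_identical(r1$retained,
                   reduce_variables(r1$frequencies, cfg$freq_threshold))
  expect_gte(r1$mse_full, 0)
  expect_gte(r1$mse_reduced, 0)
  # full and reduced errors are paired on identical folds
  expect_length(r1$per_observation_errors$full, r1$n_used)
  expect_length(r1$per_observation_errors$reduced, r1$n_used)
  r3 <- run_stability_selection(sc$table, "y", paste0("v", 1:8),
                                selection_config(n_outer = 5, n_bootstrap = 8,
                                                 n_inner = 5, seed = 43))
  expect_false(identical(r1$frequencies, r3$frequencies))
})

test_that("listwise deletion and configuration errors are explicit", {
  sc <- generate_sparse_cohort(n = 30, p = 4, active = 1, beta = 1,
                               noise_sd = 0.5, seed = 5)
  tab <- sc$table
  tab$v1[1:3] <- NA
  cfg <- selection_config(n_outer = 5, n_bootstrap = 4, n_inner = 5, seed = 1)
  r <- run_stability_selection(tab, "y", paste0("v", 1:4), cfg)
  expect_equal(r$n_used, 27)
  tab$v1[1:28] <- NA
  expect_error(run_stability_selection(tab, "y", paste0("v", 1:4), cfg),
               "complete cases")
  expect_error(run_stability_selection(sc$table, "y", c("v1", "nope"), cfg),
               "missing from table")
  expect_error(selection_config(freq_threshold = 1), "strictly between")
  expect_error(selection_config(n_outer = 1), "fold counts")
})

test_that("reduced formulas format like selection tables", {
  f <- c("SUVR-1" = 0.6154, age = 0.7841, Volume = 0.2)
  s <- format_reduced_formula("AIRarg", c("SUVR-1", "age"), f)
  expect_identical(s, "AIRarg ~ SUVR-1 [0.615] + age [0.784]")
  expect_identical(format_reduced_formula("AIRarg", character(0), f), "AIRarg ~ 1")
})
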