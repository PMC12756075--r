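test_that("generated pancreas masks have three connected, contiguous labels", {
  mk <- generate_pancreas_mask(seed = 2)
  counts <- table(factor(mk$labels[mk$labels > 0], levels = 1:3))
  expect_true(all(counts > 0))
  # slices along the sweep axis are contiguous, and consecutive occupied
  # slices overlap in (y, z) -- which implies 6-connectivity of the organ
  occ <- which(apply(mk$labels > 0, 1, any))
  expect_identical(occ, seq(min(occ), max(occ)))
  for (i in seq_len(length(occ) - 1)) {
    expect_true(any(mk$labels[occ[i], , ] > 0 & mk$labels[occ[i + 1], , ] > 0))
  }
  # labels are contiguous thirds along the sweep
  lab_per_slice <- apply(mk$labels, 1, function(s) unique(s[s > 0]))
  lab_seq <- unlist(lab_per_slice[occ])
  expect_true(all(diff(lab_seq) >= 0))
})

test_that("mask generation is deterministic and fails on undersized grids", {
  m1 <- generate_pancreas_mask(seed = 5)
  m2 <- generate_pancreas_mask(seed = 5)
  expect_identical(m1$labels, m2$labels)
  expect_error(generate_pancreas_mask(dim = c(20, 16, 10), seed = 1),
               "grid|organ")
  expect_error(generate_pancreas_mask(body_scale = 0, seed = 1), "body_scale")
})

test_that("shrinking the body short axis shrinks the body's smallest PAL", {
  full <- generate_pancreas_mask(seed = 5, body_scale = 1)
  thin <- generate_pancreas_mask(seed = 5, body_scale = 0.7)
  pal_full <- compute_principal_axis_lengths(full$masks$body)
  pal_thin <- compute_principal_axis_lengths(thin$masks$body)
  expect_lt(pal_thin[3], pal_full[3])
})

test_that("synthetic cohorts match the target design and are deterministic", {
  gen <- generate_cohort(seed = 1)
  expect_equal(nrow(gen$cohort), 40)
  expect_equal(as.vector(table(factor(gen$cohort$group,
                                      c("HOV", "prediabetes", "T2D")))),
               c(16, 5, 19))
  expect_true(all(c("AIRarg", "AIRargMAX", "acute:MAX") %in% names(gen$cohort)))
  expect_true(all(gen$cohort$years.of.diabetes[gen$cohort$group != "T2D"] == 0))
  gen2 <- generate_cohort(seed = 1)
  expect_identical(gen$cohort, gen2$cohort)
  expect_identical(gen$morph, gen2$morph)
  expect_false(identical(generate_cohort(seed = 2)$cohort$AIRarg,
                         gen$cohort$AIRarg))
})

test_that("parametric morphology satisfies every metric invariant", {
  gen <- generate_cohort(seed = 6)
  m <- gen$morph
  expect_true(all(m$PrincipalAxisLength1 >= m$PrincipalAxisLength2))
  expect_true(all(m$PrincipalAxisLength2 >= m$PrincipalAxisLength3))
  expect_true(all(m$PrincipalAxisLength3 > 0))
  expect_true(all(m$Volume <= m$ConvexVolume + 1e-9))
  expect_true(all(m$ConvexVolume <= m$BoundingBoxVolume + 1e-9))
  expect_true(all(m$Extent > 0 & m$Extent <= 1))
  expect_true(all(m$Solidity > 0 & m$Solidity <= 1))
  expect_equal(m$BoundingBoxVolume,
               m$BoundingBox1 * m$BoundingBox2 * m$BoundingBox3)
  expect_equal(m$EquivDiameter, (6 * m$Volume / pi)^(1 / 3))
})

test_that("a noiseless single-cause outcome correlates perfectly with its driver", {
  truth <- cohort_truth(
    outcome_models = list(
      "AIRargMAX" = list(intercept = 5, coefficients = c("SUVR-1" = 2),
                         noise_sd = 0),
      "AIRarg" = list(intercept = 2, coefficients = c("age" = -1),
                      noise_sd = 0.3),
      "acute:MAX" = list(intercept = 0.3, coefficients = c("HbA1c" = 0.05),
                         noise_sd = 0.02)),
    region = "body")
  gen <- generate_cohort(truth = truth, seed = 3)
  tab <- assemble_model_table(gen$cohort, gen$morph, gen$pet, region = "body")
  fit <- simple_linear_regression(tab[["SUVR-1"]], tab$AIRargMAX)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(
    generate_cohort(truth = cohort_truth(list(
      "AIRarg" = list(intercept = 0, coefficients = c(bogus = 1), noise_sd = 1),
      "AIRargMAX" = list(intercept = 0, coefficients = c(age = 1), noise_sd = 1),
      "acute:MAX" = list(intercept = 0, coefficients = c(age = 1), noise_sd = 1))),
      seed = 1),
    "unknown predictors")
})

test_that("group shifts act in the documented qualitative direction", {
  gen <- generate_cohort(seed = 11)
  pet_body <- gen$pet[gen$pet$region == "body", ]
  suvr <- merge(pet_body, gen$cohort[, c("subject", "group")])
  expect_gt(mean(suvr$suvr_minus1[suvr$group == "HOV"]),
            mean(suvr$suvr_minus1[suvr$group == "T2D"]))
  body <- merge(gen$morph[gen$morph$region == "body", ],
                gen$cohort[, c("subject", "group")])
  expect_gt(mean(body$PrincipalAxisLength3[body$group == "HOV"]),
            mean(body$PrincipalAxisLength3[body$group == "T2D"]))
})

test_that("sparse-regression cohorts expose an honest ground truth", {
  sc <- generate_sparse_cohort(n = 50, p = 6, active = c(2, 5), beta = c(1, -2),
                               noise_sd = 0, seed = 9)
  expect_identical(sc$truth$active_set, c("v2", "v5"))
  expect_equal(sc$table$y, sc$table$v2 - 2 * sc$table$v5)
  expect_identical(generate_sparse_cohort(seed = 3)$table,
                   generate_sparse_cohort(seed = 3)$table)
})

test_that("missingness injection is seeded, rate-faithful and MCAR", {
  gen <- generate_cohort(seed = 4)
  tab <- gen$cohort
  expect_identical(inject_missingness(tab, 0, seed = 1), tab)
  miss <- inject_missingness(tab, 0.1, seed = 1)
  expect_identical(inject_missingness(tab, 0.1, seed = 1), miss)
  eligible <- setdiff(names(tab), c("subject", "group"))
  n_na <- sum(is.na(miss[, eligible]))
  n_cells <- nrow(tab) * length(eligible)
  expect_gt(n_na, 0)
  # within 4 sd of the binomial expectation
  expect_lt(abs(n_na - 0.1 * n_cells), 4 * sqrt(n_cells * 0.1 * 0.9))
  # listwise deletion count downstream matches the injected pattern
  cc <- sum(stats::complete.cases(miss[, c("AIRarg", eligible[1:5])]))
  cfg <- selection_config(n_outer = 2, n_bootstrap = 2, n_inner = 2, seed = 1)
  expect_error(inject_missingness(tab, 1, seed = 1), "rate")
  expect_equal(cc, sum(rowSums(is.na(miss[, c("AIRarg", eligible[1:5])])) == 0))
})
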