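# Synthetic study generator. Emulates the statistical structure the analysis
# assumes -- a three-group cohort (healthy obese volunteers, prediabetes,
# type 2 diabetes) with group-shifted pancreas morphology and PET binding,
# and functional outcomes generated from a known sparse linear model over the
# predictor roster -- with the ground truth exposed so every stage of the
# pipeline is testable without clinical data.

#' Ground truth for a synthetic cohort
#'
#' Each outcome is linear in standardized predictors
#' (`y = b0 + sum(beta * x_std) + eps`), so effect sizes are comparable
#' across heterogeneously scaled predictors and recoverable by LASSO on
#' standardized inputs. Default group shifts follow the qualitative direction
#' seen in type 2 diabetes (lower SUVR-1, smaller pancreas-body short axis,
#' lower maximum insulin response) without asserting magnitudes.
#'
#' @param outcome_models named list; per outcome a list with `intercept`,
#'   `coefficients` (named numeric; names are predictor columns), `noise_sd`.
#' @param region which region's morphology metrics the outcome models read.
#' @param group_effects named list of multiplicative/additive group shifts.
#' @return a `cohort_truth` object.
#' @export
cohort_truth <- function(outcome_models, region = "body",
                         group_effects = default_group_effects()) {
  for (nm in names(outcome_models)) {
    m <- outcome_models[[nm]]
    if (!all(c("intercept", "coefficients", "noise_sd") %in% names(m)))
      stop_input("outcome model '%s' needs intercept, coefficients, noise_sd", nm)
  }
  structure(list(outcome_models = outcome_models, region = region,
                 group_effects = group_effects,
                 active_set = lapply(outcome_models, function(m)
                   names(m$coefficients)[m$coefficients != 0])),
            class = "cohort_truth")
}

#' @rdname cohort_truth
#' @export
default_group_effects <- function() {
  list(suvr_shift = c(HOV = 0, prediabetes = -0.07, T2D = -0.17),
       body_short_axis_scale = c(HOV = 1, prediabetes = 0.95, T2D = 0.85),
       body_bb1_scale = c(HOV = 1, prediabetes = 0.96, T2D = 0.88),
       centroid1_shift = c(HOV = 0, prediabetes = -2, T2D = -4))
}

#' @rdname cohort_truth
#' @export
default_cohort_truth <- function() {
  cohort_truth(
    outcome_models = list(
      "AIRarg" = list(intercept = 2.3,
                      coefficients = c("SUVR-1" = 0.6, "age" = -0.35,
                                       "years.of.diabetes" = -0.55),
                      noise_sd = 0.5),
      "AIRargMAX" = list(intercept = 7.5,
                         coefficients = c("SUVR-1" = 2.0,
                                          "PrincipalAxisLength3" = 1.3,
                                          "HbA1c" = -1.6,
                                          "years.of.diabetes" = -1.0),
                         noise_sd = 1.1),
      "acute:MAX" = list(intercept = 0.35,
                         coefficients = c("SUVR-1" = -0.05, "HbA1c" = 0.06,
                                          "age" = 0.02),
                         noise_sd = 0.05)),
    region = "body")
}

#' Generate a labeled synthetic pancreas mask
#'
#' A tube of elliptical cross-section swept slice-wise along a seeded smooth
#' 3D curve: the head is the widest third, the tail tapers, and a
#' group-dependent `body_scale` shrinks the body's shortest cross-sectional
#' axis (mimicking short-axis atrophy of the pancreas body). Labels are
#' contiguous thirds along the sweep (1 head, 2 body, 3 tail). Deterministic
#' given the seed.
#'
#' @param dim grid dimensions (voxels).
#' @param spacing voxel edge lengths in mm.
#' @param body_scale multiplier (0, 1] on the body's short cross-sectional
#'   axis.
#' @param head_radius,tail_radius cross-section radii (voxels) at the two
#'   ends.
#' @param seed integer seed.
#' @return list with `labels` (3D integer array), `spacing`, and `masks`
#'   (named list of [volume_mask()]: whole/head/body/tail).
#' @export
generate_pancreas_mask <- function(dim = c(72, 64, 36), spacing = c(1.5, 1.5, 2),
                                   body_scale = 1, head_radius = 9,
                                   tail_radius = 4, seed = 1) {
  if (body_scale <= 0 || body_scale > 1) stop_input("body_scale must be in (0, 1]")
  margin <- 4
  xs_full <- (margin + head_radius):(dim[1] - margin - tail_radius)
  if (length(xs_full) < 12) stop_input("grid too small for the requested organ scale")
  with_seed(derive_seed(seed, 9), {
    # subject-specific organ length and position along the sweep axis
    n_keep <- max(12L, round(length(xs_full) * runif(1, 0.82, 1)))
    start <- sample.int(length(xs_full) - n_keep + 1L, 1)
    xs <- xs_full[start + seq_len(n_keep) - 1L]
  })
  t <- seq(0, 1, length.out = length(xs))
  with_seed(seed, {
    # smooth random centerline in (y, z)
    ay <- runif(2, 2, 5) * dim[2] / 64
    az <- runif(2, 1, 2.5) * dim[3] / 36
    ph <- runif(4, 0, 2 * pi)
    cy <- dim[2] / 2 + ay[1] * sin(pi * t + ph[1]) + ay[2] * sin(2 * pi * t + ph[2])
    cz <- dim[3] / 2 + az[1] * sin(pi * t + ph[3]) + az[2] * sin(1.5 * pi * t + ph[4])
    # tapering radii with mild seeded modulation
    mod <- 1 + 0.08 * sin(3 * pi * t + runif(1, 0, 2 * pi))
    ry <- (head_radius + (tail_radius - head_radius) * t) * mod
    rz <- 0.7 * ry
  })
  third <- cut(t, breaks = c(-Inf, 1 / 3, 2 / 3, Inf), labels = FALSE)
  rz[third == 2] <- rz[third == 2] * body_scale
  if (any(cy - ry < 2) || any(cy + ry > dim[2] - 1) ||
      any(cz - rz < 2) || any(cz + rz > dim[3] - 1))
    stop_input("organ exceeds grid: enlarge dim or reduce radii")
  labels <- array(0L, dim)
  yy <- matrix(seq_len(dim[2]), dim[2], dim[3])
  zz <- matrix(seq_len(dim[3]), dim[2], dim[3], byrow = TRUE)
  for (i in seq_along(xs)) {
    inside <- ((yy - cy[i]) / ry[i])^2 + ((zz - cz[i]) / rz[i])^2 <= 1
    slice <- labels[xs[i], , ]
    slice[inside] <- third[i]
    labels[xs[i], , ] <- slice
  }
  list(labels = labels, spacing = spacing, masks = labels_to_masks(labels, spacing))
}

#' Split a labeled array into per-region binary masks
#'
#' @param labels 3D integer array with labels 1 (head), 2 (body), 3 (tail).
#' @param spacing voxel edge lengths in mm.
#' @return named list of [volume_mask()]: whole/head/body/tail.
#' @export
labels_to_masks <- function(labels, spacing) {
  list(whole = volume_mask(labels >= 1 & labels <= 3, spacing, "whole"),
       head  = volume_mask(labels == 1, spacing, "head"),
       body  = volume_mask(labels == 2, spacing, "body"),
       tail  = volume_mask(labels == 3, spacing, "tail"))
}

# Per-region parameters for the parametric morphology draw (voxel units;
# roughly pancreas-like under 1.5 x 1.5 x 2 mm spacing).
region_morph_params <- function() {
  list(
    whole = list(bb = c(95, 85, 18), bb_sd = c(7, 7, 2), extent = 0.10, solidity = 0.72,
                 centroid = c(140, 60, 12), pal_frac = c(0.95, 0.80, 0.55)),
    head  = list(bb = c(45, 42, 16), bb_sd = c(4, 4, 2), extent = 0.16, solidity = 0.82,
                 centroid = c(170, 65, 12), pal_frac = c(0.90, 0.80, 0.60)),
    body  = list(bb = c(40, 28, 11), bb_sd = c(3.5, 3, 1.2), extent = 0.50, solidity = 0.90,
                 centroid = c(130, 55, 13), pal_frac = c(0.95, 0.85, 0.70)),
    tail  = list(bb = c(48, 38, 12), bb_sd = c(4, 4, 1.5), extent = 0.22, solidity = 0.80,
                 centroid = c(100, 50, 14), pal_frac = c(0.92, 0.80, 0.60)))
}

#' Generate a synthetic three-group cohort
#'
#' Clinical covariates come from plausible seeded distributions (years of
#' diabetes is zero outside the T2D group), per-region morphology metrics are
#' drawn parametrically (constructed so every metric invariant holds
#' exactly), PET binding is drawn with a group shift, and the functional
#' outcomes are computed from the supplied sparse linear ground truth over
#' cohort-standardized predictors.
#'
#' @param n_per_group named integer vector, subjects per group (each >= 2);
#'   default matches a 16/5/19 HOV/prediabetes/T2D cohort of 40.
#' @param truth a [cohort_truth()].
#' @param seed integer seed.
#' @param spacing voxel spacing assumed for mL conversions.
#' @return list with `cohort` (subject, group, clinical covariates,
#'   outcomes), `morph` (long per subject x region), `pet` (long), and
#'   `truth`.
#' @export
generate_cohort <- function(n_per_group = c(HOV = 16, prediabetes = 5, T2D = 19),
                            truth = default_cohort_truth(), seed = 1,
                            spacing = c(1.5, 1.5, 2)) {
  if (any(n_per_group < 2)) stop_input("need n >= 2 per group")
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  subjects <- sprintf("S%03d", seq_len(n))
  ge <- truth$group_effects
  voxvol <- prod(spacing) / 1000

  with_seed(derive_seed(seed, 1), {
    clinical <- data.frame(
      subject = subjects, group = groups,
      age = round(rnorm(n, 52, 9)),
      gender = rbinom(n, 1, 0.5),
      weight = round(rnorm(n, 95, 15), 1),
      BMI = round(rnorm(n, 32, 4), 1),
      HbA1c = round(rnorm(n, c(HOV = 5.4, prediabetes = 6.0, T2D = 7.8)[groups],
                          c(HOV = 0.2, prediabetes = 0.25, T2D = 1.1)[groups]), 1),
      years.of.diabetes = ifelse(groups == "T2D",
                                 round(stats::rgamma(n, shape = 2, scale = 4), 1), 0),
      stringsAsFactors = FALSE, check.names = FALSE)
  })

  morph <- with_seed(derive_seed(seed, 2), {
    params <- region_morph_params()
    size_factor <- exp(rnorm(n, 0, 0.08))  # shared subject size
    rows <- list()
    for (region in names(params)) {
      p <- params[[region]]
      bb <- sapply(1:3, function(a) pmax(4, rnorm(n, p$bb[a], p$bb_sd[a]) * size_factor))
      if (region == "body") {
        bb[, 1] <- bb[, 1] * ge$body_bb1_scale[groups]
        bb[, 3] <- bb[, 3] * ge$body_short_axis_scale[groups]
      }
      bbvol <- bb[, 1] * bb[, 2] * bb[, 3]
      extent <- pmin(0.95, pmax(0.02, rnorm(n, p$extent, p$extent * 0.12)))
      vol <- extent * bbvol
      solidity <- pmin(0.99, pmax(0.3, rnorm(n, p$solidity, 0.04)))
      cvx <- pmin(bbvol, vol / solidity)
      pal_raw <- bb * matrix(p$pal_frac, n, 3, byrow = TRUE) *
        matrix(exp(rnorm(3 * n, 0, 0.04)), n, 3)
      pal <- t(apply(pal_raw, 1, sort, decreasing = TRUE))
      centroid1 <- rnorm(n, p$centroid[1], 2) + ge$centroid1_shift[groups]
      surf <- 0.9 * (vol * voxvol)^(2 / 3) * exp(rnorm(n, 0, 0.1)) * 4.8
      rows[[region]] <- data.frame(
        subject = subjects, region = region,
        Volume = vol, Volume_mL = vol * voxvol, SurfaceArea = surf,
        Centroid1 = centroid1,
        Centroid2 = rnorm(n, p$centroid[2], 2),
        Centroid3 = rnorm(n, p$centroid[3], 1),
        BoundingBox1 = bb[, 1], BoundingBox2 = bb[, 2], BoundingBox3 = bb[, 3],
        BoundingBoxVolume = bbvol,
        EquivDiameter = (6 * vol / pi)^(1 / 3),
        Extent = vol / bbvol,
        PrincipalAxisLength1 = pal[, 1], PrincipalAxisLength2 = pal[, 2],
        PrincipalAxisLength3 = pal[, 3],
        ConvexVolume = cvx, ConvexVolume_mL = cvx * voxvol,
        Solidity = vol / cvx,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  pet <- with_seed(derive_seed(seed, 3), {
    subj_level <- rnorm(n, 0, 0.12)
    rows <- lapply(c("whole", "head", "body", "tail"), function(region) {
      suvr <- pmax(0.05, 1.35 * (1 + ge$suvr_shift[groups]) +
                     subj_level + rnorm(n, 0, 0.15))
      data.frame(subject = subjects, region = region,
                 suvr_minus1 = suvr,
                 bp_nd = pmax(0.05, 1.1 * suvr + rnorm(n, 0, 0.1)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  # outcomes: sparse linear model over the cohort-standardized predictor set
  # of the truth's region
  base <- assemble_model_table(clinical, morph, pet, region = truth$region,
                               pet_variable = "SUVR-1")
  preds <- attr(base, "predictors")
  Z <- scale(as.matrix(base[, preds]))
  with_seed(derive_seed(seed, 4), {
    for (oc in names(truth$outcome_models)) {
      m <- truth$outcome_models[[oc]]
      bad <- setdiff(names(m$coefficients), preds)
      if (length(bad))
        stop_input("truth for '%s' names unknown predictors: %s", oc,
                   paste(bad, collapse = ", "))
      eta <- m$intercept + drop(Z[, names(m$coefficients), drop = FALSE] %*%
                                  m$coefficients)
      clinical[[oc]] <- eta + rnorm(n, 0, m$noise_sd)
    }
  })
  list(cohort = clinical, morph = morph, pet = pet, truth = truth)
}

#' Generate a generic sparse-regression cohort
#'
#' Plain design for solver-level experiments: `p` standard-normal predictors
#' `v1..vp`, an outcome linear in a small active subset, Gaussian noise.
#'
#' @param n observations.
#' @param p predictors.
#' @param active indices or names of active predictors.
#' @param beta coefficient (scalar or per active predictor).
#' @param noise_sd outcome noise standard deviation.
#' @param seed integer seed.
#' @return list with `table` (columns `y`, `v1..vp`) and `truth`.
#' @export
generate_sparse_cohort <- function(n = 300, p = 15, active = 1:3, beta = 2,
                                   noise_sd = 0.5, seed = 1) {
  vars <- paste0("v", seq_len(p))
  if (is.numeric(active)) active <- vars[active]
  if (!all(active %in% vars)) stop_input("active set outside v1..v%d", p)
  beta <- rep_len(beta, length(active))
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, vars))
    y <- drop(X[, active, drop = FALSE] %*% beta) + rnorm(n, 0, noise_sd)
  })
  list(table = data.frame(y = y, X, check.names = FALSE),
       truth = list(active_set = active,
                    coefficients = setNames(beta, active),
                    noise_sd = noise_sd))
}

#' Set table cells missing completely at random
#'
#' @param table `data.frame`.
#' @param rate missingness probability per eligible cell, in `[0, 1)`.
#' @param seed integer seed.
#' @param cols columns eligible for missingness; defaults to everything
#'   except identifier/group columns.
#' @return the table with `NA`s injected.
#' @export
inject_missingness <- function(table, rate, seed,
                               cols = setdiff(names(table), c("subject", "group", "region"))) {
  if (rate < 0 || rate >= 1) stop_input("rate must be in [0, 1)")
  if (rate == 0) return(table)
  with_seed(seed, {
    for (cl in cols) {
      hit <- runif(nrow(table)) < rate
      table[[cl]][hit] <- NA
    }
  })
  table
}
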