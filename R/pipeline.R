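# Pipeline orchestration: assembling modeling tables from the cohort, the
# morphology table and the PET table; running the model grid; simulating a
# complete synthetic study; reproducibility manifests.

CLINICAL_PREDICTORS <- c("age", "gender", "weight", "BMI", "HbA1c",
                         "years.of.diabetes", "diagnosis.prediabetes",
                         "diagnosis.T2D")
MORPH_PREDICTORS <- c("Volume", "SurfaceArea", "Centroid1", "Centroid2",
                      "Centroid3", "BoundingBox1", "BoundingBox2",
                      "BoundingBox3", "BoundingBoxVolume", "EquivDiameter",
                      "Extent", "PrincipalAxisLength1", "PrincipalAxisLength2",
                      "PrincipalAxisLength3", "ConvexVolume", "Solidity")
OUTCOME_NAMES <- c("AIRarg", "AIRargMAX", "acute:MAX")
PET_VARIABLES <- c("SUVR-1", "BP_ND", "SUVR-1xVolume", "BP_NDxVolume")

#' Model specification: one PET variable, one region, one outcome
#'
#' Mirrors the model composition of the predictive analysis: each model
#' combines exactly one PET variable with all morphology metrics of one
#' pancreas region and all clinical covariates.
#'
#' @param outcome one of `AIRarg`, `AIRargMAX`, `acute:MAX`.
#' @param pet_variable one of `SUVR-1`, `BP_ND`, `SUVR-1xVolume`,
#'   `BP_NDxVolume`.
#' @param region one of `whole`, `head`, `body`, `tail`.
#' @return a `model_spec` list with the ordered predictor roster.
#' @export
model_spec <- function(outcome, pet_variable = "SUVR-1", region = "whole") {
  outcome <- match.arg(outcome, OUTCOME_NAMES)
  pet_variable <- match.arg(pet_variable, PET_VARIABLES)
  region <- match.arg(region, c("whole", "head", "body", "tail"))
  structure(list(outcome = outcome, pet_variable = pet_variable,
                 region = region,
                 predictors = c(pet_variable, MORPH_PREDICTORS,
                                CLINICAL_PREDICTORS)),
            class = "model_spec")
}

#' Assemble the modeling table for one region and PET variable
#'
#' Joins the cohort (clinical covariates and outcomes), the long morphology
#' table and the long PET table by subject; expands gender and diagnosis to
#' numeric indicators; computes aggregate binding (`metric x Volume_mL`) when
#' an aggregate PET variable is requested.
#'
#' @param cohort `data.frame` with `subject`, `group`, clinical covariates
#'   and (optionally) outcomes.
#' @param morph long morphology table (`subject`, `region`, metrics).
#' @param pet long PET table (`subject`, `region`, `suvr_minus1`, optionally
#'   `bp_nd`).
#' @param region pancreas region.
#' @param pet_variable PET predictor to construct.
#' @return `data.frame` with attribute `"predictors"` (ordered roster).
#' @export
assemble_model_table <- function(cohort, morph, pet, region = "whole",
                                 pet_variable = "SUVR-1") {
  pet_variable <- match.arg(pet_variable, PET_VARIABLES)
  m <- morph[morph$region == region, c("subject", MORPH_PREDICTORS, "Volume_mL")]
  p <- pet[pet$region == region, , drop = FALSE]
  out <- merge(cohort, m, by = "subject", sort = FALSE)
  out <- merge(out, p[, setdiff(names(p), "region")], by = "subject", sort = FALSE)
  base <- if (grepl("^SUVR-1", pet_variable)) out$suvr_minus1 else {
    if (is.null(out$bp_nd)) stop_input("PET table has no bp_nd column")
    out$bp_nd
  }
  out[[pet_variable]] <- if (grepl("xVolume$", pet_variable))
    aggregate_binding(base, out$Volume_mL) else base
  if (!is.numeric(out$gender)) out$gender <- as.numeric(factor(out$gender)) - 1
  grp <- out$group %||% rep("HOV", nrow(out))
  out[["diagnosis.prediabetes"]] <- as.numeric(grp == "prediabetes")
  out[["diagnosis.T2D"]] <- as.numeric(grp == "T2D")
  out$suvr_minus1 <- NULL
  out$bp_nd <- NULL
  attr(out, "predictors") <- c(pet_variable, MORPH_PREDICTORS, CLINICAL_PREDICTORS)
  out
}

#' Run the stability-selection model grid
#'
#' One stability-selection run per outcome x region x PET variable (the
#' primary grid is the 12 SUVR-1 models: 3 outcomes x 4 regions). Listwise
#' deletion per model is handled inside [run_stability_selection()]; the
#' per-model complete-case `n` is reported.
#'
#' @param cohort,morph,pet tables as in [assemble_model_table()].
#' @param config a [selection_config()].
#' @param outcomes,regions,pet_variables grid axes.
#' @param out_dir optional; when given, a JSON report per model, a tidy CSV
#'   across models and a reproducibility manifest are written there.
#' @return list with `models` (named list of `stability_selection` objects)
#'   and `summary` (tidy `data.frame`).
#' @export
run_selection_grid <- function(cohort, morph, pet, config = selection_config(),
                               outcomes = OUTCOME_NAMES,
                               regions = c("whole", "head", "body", "tail"),
                               pet_variables = "SUVR-1", out_dir = NULL) {
  models <- list()
  rows <- list()
  for (pv in pet_variables) for (rg in regions) for (oc in outcomes) {
    tab <- assemble_model_table(cohort, morph, pet, region = rg, pet_variable = pv)
    if (!oc %in% names(tab)) stop_input("outcome column '%s' missing", oc)
    res <- run_stability_selection(tab, oc, attr(tab, "predictors"), config)
    key <- paste(oc, rg, pv, sep = "|")
    models[[key]] <- res
    rows[[key]] <- data.frame(
      outcome = oc, region = rg, pet_variable = pv, n = res$n_used,
      n_retained = length(res$retained),
      mse_full = res$mse_full, mse_reduced = res$mse_reduced,
      reduced_formula = res$reduced_formula,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(models))

      write_selection_report(models[[key]],
                             file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", key), ".json")))
    write.csv(summary, file.path(out_dir, "selection_summary.csv"), row.names = FALSE)
    write_manifest(file.path(out_dir, "manifest.json"), config,
                   extra = list(models = names(models)))
  }
  list(models = models, summary = summary)
}

#' Write one stability-selection result as JSON
#'
#' Frequencies are reported to 4 decimals; the reduced model is formatted as
#' `"outcome ~ var [freq] + ..."`.
#'
#' @param result a `stability_selection` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(result, path) {
  report <- list(
    outcome = result$outcome,
    n = result$n_used,
    frequencies = as.list(round(result$frequencies, 4)),
    retained = as.list(result$retained),
    reduced_formula = result$reduced_formula,
    mse_full = result$mse_full,
    mse_reduced = result$mse_reduced,
    config = unclass(result$config))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Reproducibility manifest: config hash, seed and package version suffice to
# re-create every output bit-identically.
write_manifest <- function(path, config, extra = list()) {
  manifest <- c(list(
    package = "pancmorph",
    version = as.character(utils::packageVersion("pancmorph")),
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(unclass(config))), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a complete synthetic study on disk
#'
#' Writes everything the downstream commands consume: one labeled NIfTI mask
#' per subject (group-dependent body short-axis scale), `cohort.csv`
#' (clinical covariates and outcomes), `pet.csv`, `morph_parametric.csv` (the
#' parametric morphology table the outcomes were generated from),
#' `truth.json`, and a run manifest.
#'
#' @param out_dir output directory (created).
#' @param n_per_group subjects per group; masks are generated for
#'   `n_masks` subjects only when smaller (mask morphometrics is the slow
#'   path).
#' @param n_masks how many subjects get a voxel mask written (default all).
#' @param truth a [cohort_truth()].
#' @param seed integer seed.
#' @param mask_dim,spacing mask grid geometry.
#' @return list with the generated tables, `truth`, and `paths`.
#' @export
simulate_study <- function(out_dir,
                           n_per_group = c(HOV = 16, prediabetes = 5, T2D = 19),
                           n_masks = NULL, truth = default_cohort_truth(),
                           seed = 1, mask_dim = c(72, 64, 36),
                           spacing = c(1.5, 1.5, 2)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  masks_dir <- file.path(out_dir, "masks")
  dir.create(masks_dir, showWarnings = FALSE)
  gen <- generate_cohort(n_per_group, truth, seed = seed, spacing = spacing)
  subjects <- gen$cohort$subject
  n_masks <- min(n_masks %||% length(subjects), length(subjects))
  scale_by_group <- truth$group_effects$body_short_axis_scale
  for (i in seq_len(n_masks)) {
    g <- gen$cohort$group[i]
    mk <- generate_pancreas_mask(dim = mask_dim, spacing = spacing,
                                 body_scale = unname(scale_by_group[g]),
                                 seed = derive_seed(seed, 77, i))
    write_pancreas_mask(mk$labels, spacing,
                        file.path(masks_dir, paste0(subjects[i], ".nii.gz")))
  }
  paths <- list(
    masks_dir = masks_dir,
    cohort = file.path(out_dir, "cohort.csv"),
    pet = file.path(out_dir, "pet.csv"),
    morph = file.path(out_dir, "morph_parametric.csv"),
    truth = file.path(out_dir, "truth.json"),
    manifest = file.path(out_dir, "manifest.json"))
  write.csv(gen$cohort, paths$cohort, row.names = FALSE)
  write.csv(gen$pet, paths$pet, row.names = FALSE)
  write.csv(gen$morph, paths$morph, row.names = FALSE)
  jsonlite::write_json(
    list(active_set = gen$truth$active_set,
         outcome_models = gen$truth$outcome_models,
         region = gen$truth$region),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- list(seed = seed, n_per_group = as.list(n_per_group),
              n_masks = n_masks, mask_dim = mask_dim, spacing = spacing)
  write_manifest(paths$manifest, list(seed = seed), extra = list(simulate = cfg))
  c(gen, list(paths = paths))
}

#' Read a cohort CSV preserving the modeling column names
#'
#' @param path CSV path.
#' @return `data.frame` with `check.names = FALSE` (keeps `SUVR-1`,
#'   `acute:MAX`, ...).
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
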