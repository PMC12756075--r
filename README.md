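# pancmorph

Pancreas morphometrics and multimodal prediction of beta-cell function.

In type 2 diabetes (T2D), beta-cell mass and function decline alongside
structural remodeling of the whole pancreas. PET with a VMAT2-binding
radioligand measures beta-cell density as the spleen-referenced uptake ratio
**SUVR-1**; structural MRI measures organ morphology. `pancmorph` implements
the analysis that combines the two with clinical covariates to predict
functional beta-cell outcomes — the acute and maximum C-peptide responses to
arginine stimulation (**AIRarg**, **AIRargMAX**) and their ratio
(**acute:MAX**) — and to identify which variables carry the signal.

The package provides, as tested components:

* **3D morphometrics** from labeled binary masks (NIfTI; labels head/body/
  tail): volume, surface area, centroid, bounding box, equivalent diameter,
  extent, principal axis lengths, convex volume and solidity, per region.
  Convex volumes use an exact lattice-point-in-hull count (compiled
  quickhull); surface areas use a triangulated 0.5-level isosurface with
  Gaussian pre-smoothing and trilinear refinement.
* **PET quantification**: SUV, duration-weighted late-window means
  (180–240 min), spleen-referenced SUVR-1, and aggregate (volume-weighted)
  binding.
* **Bootstrap LASSO stability selection** inside nested cross-validation:
  10 outer folds × B bootstrap replicates × inner 10-fold penalty tuning,
  selection frequencies `f = C/(n_outer·B)`, retention at `f > 0.5`, and a
  paired full-vs-reduced cross-validated MSE comparison. The coordinate-
  descent LASSO path solver is compiled and deterministic under one seed.
* **Cohort statistics**: one-way ANOVA, pairwise Welch t-tests, simple
  linear regression with 95% confidence bands, mean ± SEM summaries.
* **A synthetic study generator** (masks, PET, covariates, outcomes from a
  known sparse linear truth) so the full pipeline runs and is testable
  without any clinical data.

The model at the core: for one outcome `y`, one pancreas region and one PET
variable, the predictor roster is `x = (PET, 16 morphology metrics, 8
clinical covariates)`. On every bootstrap replicate of every outer training
fold the LASSO

    min_b  (1/2n) ||y − b0 − X b||² + λ ||b||₁

is tuned by inner cross-validation and the nonzero set recorded; variables
with selection frequency `f > 0.5` form the reduced model

    y ~ x_(1) [f₁] + x_(2) [f₂] + …

whose cross-validated MSE is compared against the all-predictor model on
identical folds.

## Worked example

```r
library(pancmorph)

# a 40-subject synthetic cohort (16 HOV / 5 prediabetes / 19 T2D) with a
# known sparse ground truth for each outcome
gen <- generate_cohort(seed = 42)

one_way_anova(gen$cohort$AIRargMAX, gen$cohort$group)
#> F = 31.5 on 2 and 37 df, p = 1e-08      (T2D group strongly reduced)

# one primary model: AIRargMAX ~ SUVR-1 + body morphology + clinical
tab <- assemble_model_table(gen$cohort, gen$morph, gen$pet,
                            region = "body", pet_variable = "SUVR-1")
res <- run_stability_selection(tab, "AIRargMAX", attr(tab, "predictors"),
                               selection_config(n_bootstrap = 100, seed = 42))
res
#> <stability_selection> n = 40, 25 predictors, B = 100
#>   AIRargMAX ~ SUVR-1 [1.000] + PrincipalAxisLength3 [0.983] + HbA1c [0.999]
#>               + years.of.diabetes [0.581] + diagnosis.T2D [0.858]
#>   CV-MSE full = 4.068, reduced = 0.7405

gen$truth$active_set$AIRargMAX
#> "SUVR-1"  "PrincipalAxisLength3"  "HbA1c"  "years.of.diabetes"
```

The procedure retained every true driver (bracketed numbers are selection
frequencies), added the T2D indicator as a correlated proxy, and the
5-variable reduced model predicts about 5× better than the 25-predictor full
model in cross-validation — the overfitting the selection step removes.

Morphometrics work on any binary mask:

```r
m <- compute_all_metrics(ball)   # digital ball, radius 20 voxels, 1 mm spacing
#> <morphology_metrics 'whole'>
#>   volume: 33401 vox (33.40 mL), surface 52.36 cm^2
#>   pal: 39.98/39.98/39.98, extent 0.485, solidity 1.000
```

(Analytic values: volume 33 510 mm³, surface 50.27 cm², axis lengths 40;
the extent of a digital ball is `π/6 · (2r/(2r+1))³ ≈ 0.486`, not π/6 — a
consequence of the whole-voxel bounding-box convention.)

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data and
write their tables under `results/`:

| script | what it does | main outputs |
|---|---|---|
| `01_simulate.R` | 40-subject cohort + one labeled mask per subject | `results/study/` |
| `02_morphometrics.R` | 16 metrics × 4 regions per subject, group tests | `results/morphology.csv` |
| `03_cohort_stats.R` | ANOVA/Welch on outcomes, single-metric correlations | `results/cohort_stats.csv`, `results/correlations.csv` |
| `04_stability_selection.R` | the 12 primary models (3 outcomes × 4 regions) | `results/selection/` |
| `05_report.R` | reduced formulas, full-vs-reduced MSE table | `results/final_report.csv` |

On the default simulation the reduced model beats the full model in 12 of 12
models, and the body-region models recover the simulated drivers.

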