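#!/usr/bin/env Rscript
# Stage 3: group statistics and exploratory correlations.
#
# One-way ANOVA across HOV / prediabetes / T2D for each functional outcome,
# pairwise Welch t-tests, group mean +/- SEM summaries, and simple linear
# regressions of outcomes on single imaging metrics (SUVR-1 per region and
# the pancreas-body short axis).

suppressPackageStartupMessages(library(pancmorph))

cohort <- read_cohort_csv("results/study/cohort.csv")
pet <- read_cohort_csv("results/study/pet.csv")
morph <- read_cohort_csv("results/morphology.csv")

outcomes <- c("AIRarg", "AIRargMAX", "acute:MAX")
stats <- cohort_group_comparisons(cohort, outcomes)
write.csv(stats, "results/cohort_stats.csv", row.names = FALSE)
cat("Group comparisons -> results/cohort_stats.csv\n")
print(stats[stats$comparison == "ANOVA", ], row.names = FALSE, digits = 3)

summaries <- do.call(rbind, lapply(outcomes, function(oc)
  cbind(outcome = oc, group_summary(cohort[[oc]], cohort$group))))
write.csv(summaries, "results/outcome_summaries.csv", row.names = FALSE)

# exploratory single-metric correlations
rows <- list()
for (region in c("whole", "head", "body", "tail")) {
  tab <- assemble_model_table(cohort, morph, pet, region = region)
  for (oc in outcomes) {
    for (metric in c("SUVR-1", "PrincipalAxisLength3")) {
      fit <- simple_linear_regression(tab[[metric]], tab[[oc]])
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, region = region, metric = metric,
        slope = fit$slope, r_squared = fit$r_squared, p = fit$p)
    }
  }
}
cors <- do.call(rbind, rows)
write.csv(cors, "results/correlations.csv", row.names = FALSE)
cat("\nStrongest single-metric correlations (top 5 by R^2):\n")
print(head(cors[order(-cors$r_squared), ], 5), row.names = FALSE, digits = 3)
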