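#!/usr/bin/env Rscript
# Association statistics: demographic/clinical group comparisons recomputed
# from the bundled summary table, and bivariate correlation of the averaged
# paired-state probabilities with the behavioral covariates, overall and per
# group.

library(elscape)
dir.create("results", showWarnings = FALSE)

dem <- demographic_tests(read.csv(system.file(
  "extdata", "cohort_demographics.csv", package = "elscape")))
write.csv(dem, "results/demographic_tests.csv", row.names = FALSE)
cat("demographic comparisons (statistic, p):\n")
print(dem, row.names = FALSE, digits = 3)

cohort <- generate_cohort(default_cohort_config(seed = 20240901))
profiles <- fit_cohort(cohort)
affected <- sort(planted_affected_states(cohort, n_states = 2))
pf <- paired_state_frequencies(profiles, matrix(affected, ncol = 2))

spec <- behavior_spec(
  scores = list(
    perceptual_scale = list(target_states = affected, coefficient = -40,
                            noise_sd = 1, intercept = 5),
    unrelated_score = list(target_states = affected, coefficient = 0,
                           noise_sd = 1)),
  group_shift = c(perceptual_scale = 1.5, unrelated_score = 0))
behavior <- generate_behavior(cohort, spec, seed = 20240902)

cors <- correlate_pairs_with_covariates(pf, behavior, by_group = TRUE)
write.csv(cors, "results/pair_behavior_correlations.csv", row.names = FALSE)
cat("\npaired-state frequency vs behavior (Pearson r, two-sided p):\n")
print(cors, row.names = FALSE, digits = 3)
cat("wrote results/demographic_tests.csv, results/pair_behavior_correlations.csv\n")
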