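#!/usr/bin/env Rscript
# Characterize the energy landscapes implied by the group-average fitted
# parameters: per-state energies and probabilities, local minima, basin
# membership and basin depth, for controls and patients separately.

library(elscape)
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(default_cohort_config(seed = 20240901))
profiles <- fit_cohort(cohort)
grp <- vapply(profiles, `[[`, character(1), "group")

group_mean_params <- function(g) {
  ps <- profiles[grp == g]
  h <- Reduce(`+`, lapply(ps, function(p) p$params$h)) / length(ps)
  J <- Reduce(`+`, lapply(ps, function(p) p$params$J)) / length(ps)
  mem_params(h, J)
}

for (g in c("control", "patient")) {
  params <- group_mean_params(g)
  rep_ <- landscape_report(params)
  write.csv(rep_, sprintf("results/landscape_%s.csv", g), row.names = FALSE)
  mins <- rep_[rep_$state %in% local_minima(energy_table(params)), ]
  cat(sprintf("\n%s group: %d local minima\n", g, nrow(mins)))
  print(mins[, c("state", "label", "energy", "probability", "basin_depth")],
        row.names = FALSE)
}
cat("\nwrote results/landscape_control.csv, results/landscape_patient.csv\n")
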