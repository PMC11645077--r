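# elscape

Energy-landscape analysis of binarized brain states with pairwise maximum
entropy models, plus the group statistics that turn it into a case–control
pipeline: per-state energy tests, complementary paired-state biomarkers,
ROI-to-ROI Fisher-z connectivity contrasts with SPC permutation
cluster-mass inference, and behavioral correlation. It is aimed at
researchers comparing resting-state fMRI dynamics between a patient group
and controls (the bundled study conditions emulate a schizophrenia-spectrum
cohort of 55 patients vs 63 healthy controls over 8 ROIs), and at
methodologists who want every stage of such a pipeline testable without
access to raw imaging data.

## The model

Each ROI's signal is binarized (active/inactive at its own mean), so N ROIs
yield a time series over 2^N joint activation states. The pairwise maximum
entropy model — the Ising model with spins σᵢ ∈ {−1, +1} — is the
least-structured distribution matching the empirical activation and
co-activation rates:

    P(V_k) = exp(−E(V_k)) / Z,
    E(V_k) = − Σᵢ hᵢ σᵢ⁽ᵏ⁾ − ½ Σ_{i≠j} J_ij σᵢ⁽ᵏ⁾ σⱼ⁽ᵏ⁾.

Low-energy states are frequently visited, stable states. The energies over
the hypercube of states form a landscape whose local minima (under
single-spin flips), basins, and basin depths characterize attractor
structure. Group comparisons run per state on the subjects' model energies
(Welch t, Bonferroni-corrected), complementary state pairs are averaged into
per-subject frequencies, and connectivity contrasts are clustered with
permutation cluster-mass inference on the hierarchically ordered edge
matrix.

Because no raw cohort is distributed, the package includes a first-class
synthetic generator: two-group Ising cohorts with planted coupling
differences, subject-level parameter jitter, continuous BOLD-like
surrogates, coupled behavioral scores, and a toy 4D image fixture for the
ROI-extraction step.

## Worked example

```r
library(elscape)

# study-scale synthetic cohort: 63 controls, 55 patients, 8 ROIs, T = 888,
# patients carry a -0.6 deficit on the coupling between ROIs 1 and 2
cohort   <- generate_cohort(default_cohort_config(seed = 20240901))
profiles <- fit_cohort(cohort)          # per-subject MEM fits

tests <- energy_ttest_per_state(profiles)
adj   <- bonferroni(tests$p, m = sum(!is.na(tests$p)))
sum(adj$significant)                    # 256: every state's energy shifts by +/-0.6

affected <- planted_affected_states(cohort)      # ground truth: states 0 and 255
pf <- paired_state_frequencies(profiles, matrix(sort(affected), ncol = 2))
tapply(pf$pair_0_255, pf$group, mean)
#>   control   patient
#> 0.1299...  0.0808...
```

The control group keeps the higher mean paired-state frequency — the
planted coupling deficit flattens the patients' two complementary attractors
(all-inactive "−" and all-active "12345678"). The landscape of the
group-mean fitted parameters makes the same point:

```r
landscape_report(fit_mem(empirical_distribution(
  cohort$subjects[[1]]$patterns))$params)  # per-state energy/probability/basin
```

Running the numbered drivers under `analysis/` reproduces the whole
workflow on this cohort; for example `analysis/03_landscape.R` prints

```
control group: 2 local minima
 state    label    energy probability basin_depth
     0        - -4.217819   0.1409387    4.679892
   255 12345678 -4.117155   0.1274419    4.579228

patient group: 2 local minima
 state    label    energy probability basin_depth
     0        - -3.647055  0.08384985    3.550251
   255 12345678 -3.661115  0.08503711    3.564311
```

(shallower, less probable attractors in the patient group), and
`analysis/05_connectivity_spc.R` finds one suprathreshold SPC cluster
(mass 224.02, p_FWE = 0.0002 at 5000 permutations) whose Bonferroni
reduction returns all 8 ROIs. `analysis/06_behavior_correlation.R`
recovers the planted behavior loading (r = −0.87 overall) and recomputes
the demographic contrasts from the bundled summary table.

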