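---
title: "Energy-landscape analysis of binarized brain states: models, choices, and guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape analysis of binarized brain states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elscape)
```

## The model

`elscape` analyzes joint activation patterns of a small set of brain regions
(ROIs). Each ROI's time series is binarized into active/inactive at every
time point, so a recording of N ROIs becomes a sequence of joint activation
states — one of \(2^N\) possibilities per time point. The package fits the
pairwise maximum entropy model (MEM), the least-structured distribution that
matches the empirical activation rates and pairwise co-activation rates.
With spins \(\sigma_i \in \{-1, +1\}\) it is the Ising model:

\[
P(V_k) = \frac{e^{-E(V_k)}}{\sum_l e^{-E(V_l)}}, \qquad
E(V_k) = -\sum_i h_i \sigma_i^{(k)} - \tfrac12 \sum_{i \ne j} J_{ij}
  \sigma_i^{(k)} \sigma_j^{(k)},
\]

where \(h_i\) is ROI *i*'s tendency to be active and \(J_{ij}\) the pairwise
coupling. Energy and probability are inversely related by construction:
low-energy states are the frequently visited, dynamically stable ones. The
energy values over all \(2^N\) states form a landscape on the N-dimensional
hypercube; its local minima (states below all N single-flip neighbors) are
attractors, and basins and basin depths quantify their stability.

The assumptions worth stating plainly: (i) binarization preserves the signal
of interest — the model sees only threshold crossings, not amplitudes;
(ii) time points are treated as exchangeable draws from a stationary
distribution — temporal order enters nowhere in the likelihood; (iii) second
moments suffice — higher-order interactions are attributed to pairwise
structure. These are the standard commitments of pairwise-MEM analyses of
resting-state data, and they restrict N to small values (8 here) where the
\(2^N\) state space is both enumerable and reasonably sampled by sessions of
several hundred volumes.

## Fitting

`fit_mem()` maximizes the log-likelihood by gradient ascent on the moment
residuals, with exact model moments by enumeration:
\(\Delta h_i \propto \langle\sigma_i\rangle_{data} -
\langle\sigma_i\rangle_{model}\), and likewise for pairs. The likelihood is
concave, so with zero initialization the fit is deterministic. Defaults:
learning rate 0.1, tolerance \(10^{-8}\) on the maximum absolute moment
residual, at most \(5 \times 10^5\) iterations. Non-convergence is returned
as a flag, never silently. No regularization is applied by default (the
maximum-likelihood fixed point is the maximum-entropy solution); an optional
L2 penalty on J is exposed for very short series. States never observed in a
subject get empirical probability zero with no pseudocounts — the model
still assigns them positive probability.

The model is fitted per subject, so each subject contributes a full set of
\(2^N\) energies to the group comparison; a pooled fit can be obtained by
concatenating series before binarization. The cohort-level helper
`fit_cohort()` uses a slightly larger step (0.2) and a \(10^{-6}\) tolerance:
with 888 time points the empirical moments themselves carry sampling noise
of order \(1/\sqrt{T} \approx 0.03\), so iterating below \(10^{-6}\) buys
nothing statistically and keeps the hundreds of per-subject fits fast.

## Landscape characterization

A state is a local minimum iff its energy is strictly below all N single-flip
neighbors. Basins are found by steepest single-flip descent; exact energy
ties among neighbors are broken toward the lower state index — ties have
measure zero for continuous parameters, but the rule makes results
reproducible bit-for-bit. Basin depth is the lowest saddle connecting a
minimum to any other minimum (threshold percolation over the hypercube,
equivalent to a minimax path search) minus the minimum's energy; a landscape
with a single minimum gets depth = energy range, a convention we state
because depth is otherwise undefined there. All three computations are
verified against exhaustive brute-force search on random instances with
N ≤ 4 in the test suite.

## Group comparison and paired states

Per-subject state usage rates (mean empirical probabilities) are partitioned
around the 5% threshold, with a ±0.5 percentage-point band defining
"approximately 5%". A state "appears" in a group when any subject of the
group visits it at least once (a visit-count floor is available). Group
differences are tested per state with Welch's two-sample t on the subjects'
model energies — Welch rather than pooled because between-subject energy
variances need not match across clinical groups — followed by Bonferroni
correction with m defaulting to the number of tested states.

Complementary paired states are then averaged:
\((\hat p(a) + \hat p(b))/2\) per subject. Because "complementary" has no
unique formal definition, pairing is a configurable rule: the default greedy
minimum-Hamming-distance pairing (ties broken toward the lexicographically
smaller index pair, leftovers reported) captures "states differing in few
ROIs", and an explicit user-supplied pairing is always accepted for pairings
motivated by the empirical distributions themselves. The analysis scripts
use the explicit route with the generator's ground-truth pair.

## Connectivity contrast and SPC inference

Subject connectivity is the Fisher-transformed Pearson correlation of ROI
series (`atanh(r)`, r clipped to \(\pm(1-10^{-7})\)). For a single resting
condition this correlation is exactly what a weighted GLM of the rectified
design reduces to, so the package computes it directly. Edges are contrasted
between groups with pooled-variance t (df = \(n_1+n_2-2\); 116 at the
default 63/55 cohort), signed by the (control = −1, patient = +1) contrast.

SPC (spatial pairwise clustering) inference orders ROIs by complete-linkage
clustering on 1 − correlation of edge profiles (each ROI's profile excludes
the two self-entries, which would otherwise anticorrelate strongly coupled
pairs), with exact optimal leaf ordering by dynamic programming on the
dendrogram. Suprathreshold edges (two-sided height threshold, default
p < 0.05) are grouped by 4-connectivity in the ordered upper-triangular
matrix — a stated, testable stand-in for proprietary clustering rules —
and scored by mass (sum of |T|). Group labels are permuted at the subject
level: the per-permutation maximum mass gives FWE p-values, the pooled null
mass distribution gives uncorrected p-values, Benjamini–Hochberg across
clusters gives FDR. The Bonferroni ROI reduction divides alpha by the number
of candidate dendrogram blocks (all unordered pairs of dendrogram nodes,
including self-pairs; 120 at N = 8), a denominator reported with every
result so the correction is explicit. Note the resolution constraint this
implies: with B permutations the smallest attainable uncorrected p is about
1/B, so clearing a threshold of alpha/120 needs several thousand
permutations; the connectivity analysis script uses 5000.

## The synthetic cohort generator

No raw imaging data accompany the study design this package implements, so
the generator is the source of all cohort-scale inputs and is itself tested
code. Its defaults are the study conditions: N = 8 ROIs, 63 controls and 55
patients, T = 888 time points per subject. (The acquisition arithmetic of a
four-run protocol would suggest roughly twice that many volumes; T is a free
parameter precisely because the two numbers cannot both hold.) The
generating model uses zero local fields and uniform ferromagnetic couplings
J = 0.15 — weak collective alignment producing two complementary attractors
(all-active / all-inactive), the structure the paired-state analysis is
built to detect — with patients receiving a −0.6 shift on the (1,2)
coupling, emulating reduced patient connectivity, and every subject
receiving Gaussian parameter jitter of sd 0.05 (between-subject
heterogeneity of realistic magnitude: subject energies vary by a few tenths,
comparable to the group effect). Each subject's state sequence is drawn
i.i.d. from their exact Boltzmann distribution by enumeration; a Gibbs
sampler (burn-in 1000 sweeps, thinning 5) covers N beyond enumeration.
All substreams derive from one seed; generation is bit-reproducible.

Continuous mode maps spins to amplitudes ±1 plus Gaussian noise (sd 0.4,
optional AR(1) smoothing), so mean-thresholding recovers the planted states
when noise is small. What the generator does *not* emulate: hemodynamic
convolution, temporal autocorrelation of real BOLD, motion and physiological
artifacts, or spatial structure beyond the toy label-image fixture. Passing
tests therefore certify the statistical machinery — moment matching, error
control, power against planted effects — not robustness to fMRI
preprocessing choices, which are out of scope (a zero-phase Butterworth
band-pass utility is provided, with the series demeaned first so the DC
component is removed exactly).

Behavioral covariates are linear in the subject's averaged probability of a
target state set, plus group shift and Gaussian noise, giving closed-form
population correlations for calibration tests.

A note on "affected states": a shift on a single coupling changes every
state's energy by exactly ±δ, so no energy-difference criterion singles out
specific states. Ground truth is therefore defined through the model: the
affected states are those whose Boltzmann probability changes most between
the two groups' generating parameters (the complementary pair 0 and 255
under the default configuration).

## Numerical choices and conventions

- Spin encoding {−1, +1}; "active" = +1 = binary 1; ROI 1 is the least
  significant bit of the state index. States can be labeled by their active
  ROI positions (state 6 of 8 ROIs = "23").
- Binarization threshold: per-ROI time-series mean (median available). Mean
  thresholding is the common choice in this literature; the tests verify
  invariance under positive affine rescaling, which is the property that
  matters.
- Boltzmann probabilities use a max-shifted softmax; normalization is exact
  to 1e−12.
- The energy includes the 1/2 double-counting factor on J, stated explicitly
  since conventions differ across papers.
- Demographic tests from printed summaries: Welch or pooled t as declared
  per variable, chi-square without continuity correction (the uncorrected
  statistic is what the reference summaries reproduce), all two-sided.

## Problem sizes used by the test and acceptance runs

Simulation scales are chosen so the guarantees are informative yet the whole
suite runs in minutes on one core: family-wise error of the corrected
per-state tests on 200 null cohorts at N = 4, 20 + 20 subjects, T = 200
(error control is a property of the procedure, not of the cohort size, so a
reduced scale tests it equally well); SPC null calibration on 100 datasets
at 20 + 20 subjects, T = 120, 500 permutations each; planted-effect power at
the full study scale (63 + 55 subjects, T = 888, N = 8, coupling deficit
0.6) over 50 replicates; MEM recovery at N = 8 from 50,000 samples; and 100
random landscape instances at N ≤ 4 against exhaustive search.

## Known limitations

- Exact enumeration bounds N at ~20 for energies and ~15 for fitting in
  practice; this is by design — the method itself presumes small N.
- The SPC connectedness rule (4-connectivity in the leaf-ordered matrix) is
  one defensible definition among several; cluster shapes, though not error
  control, depend on it.
- Basin depth is reported per minimum without transition-rate modeling;
  depths are comparative, not kinetic, quantities.
- Permutation p-values are granular at 1/(number of permutations); budget
  permutations to the threshold you need to clear.
- The behavioral generator's linear link is a calibration device, not a
  cognitive model.
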