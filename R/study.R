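#' States most affected by the planted group difference
#'
#' From the cohort's ground-truth group parameters, enumerates both
#' Boltzmann distributions and returns the states whose model probabilities
#' change the most between groups. (A pure coupling shift moves every
#' state's energy by the same magnitude, so probability change — not energy
#' change — is what singles out affected states.)
#'
#' @param cohort a `cohort` (uses its `truth` parameter sets).
#' @param n_states how many top states to return (default 2).
#' @return Integer state indices, ordered by decreasing |probability change|.
#' @export
planted_affected_states <- function(cohort, n_states = 2L) {
  pc <- boltzmann_distribution(cohort$truth$control)$probs
  pp <- boltzmann_distribution(cohort$truth$patient)$probs
  order(abs(pc - pp), decreasing = TRUE)[seq_len(n_states)] - 1L
}

#' Family-wise error rate of Bonferroni-corrected per-state energy tests
#'
#' Simulates null cohorts (no planted group difference), runs the
#' per-subject MEM fits and per-state Welch tests with Bonferroni correction
#' over all states, and reports the fraction of replicates with any
#' significant state — the family-wise error rate, which a valid procedure
#' keeps at or below alpha.
#'
#' @param n_reps number of null cohorts.
#' @param n_rois,n_per_group,n_timepoints cohort scale per replicate.
#' @param base_J uniform coupling strength of the shared model.
#' @param jitter_sd between-subject parameter jitter.
#' @param alpha family-wise level.
#' @param seed integer seed.
#' @param tol MEM fit tolerance used in the simulation.
#' @return List with `fwer`, `n_reps`, and the per-replicate rejection flags.
#' @export
simulate_state_fwer <- function(n_reps = 200L, n_rois = 4L, n_per_group = 20L,
                                n_timepoints = 200L, base_J = 0.15,
                                jitter_sd = 0.05, alpha = 0.05, seed = 1L,
                                tol = 1e-6) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  J <- matrix(base_J, n_rois, n_rois); diag(J) <- 0
  any_rej <- logical(n_reps)
  for (b in seq_len(n_reps)) {
    cfg <- cohort_config(n_rois = n_rois, n_controls = n_per_group,
                         n_patients = n_per_group,
                         n_timepoints = n_timepoints,
                         base_J = J, subject_jitter_sd = jitter_sd,
                         seed = rep_seeds[b])
    profiles <- fit_cohort(generate_cohort(cfg), tol = tol)
    tests <- energy_ttest_per_state(profiles)
    ok <- !is.na(tests$p)
    adj <- bonferroni(tests$p[ok], alpha = alpha)
    any_rej[b] <- any(adj$significant)
  }
  list(fwer = mean(any_rej), n_reps = n_reps, rejections = any_rej)
}

#' SPC false-positive calibration on null connectivity datasets
#'
#' Simulates datasets of independent-noise ROI series for two groups (no
#' group difference), runs the full SPC permutation inference, and records
#' each dataset's minimum cluster FWE p-value (1 when no suprathreshold
#' cluster forms). Under the null the rejection rate at `alpha` should not
#' exceed `alpha` up to Monte-Carlo error, and the p-values should
#' stochastically dominate the uniform distribution.
#'
#' @param n_reps number of null datasets.
#' @param n_rois,n_per_group,n_timepoints dataset scale.
#' @param n_perm permutations per dataset.
#' @param seed integer seed.
#' @return List with `min_p_fwe` (per dataset), `reject_rate_05`, `n_reps`.
#' @export
simulate_spc_null <- function(n_reps = 100L, n_rois = 8L, n_per_group = 20L,
                              n_timepoints = 120L, n_perm = 500L, seed = 1L) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  groups <- rep(c("control", "patient"), each = n_per_group)
  min_p <- numeric(n_reps)
  for (b in seq_len(n_reps)) {
    set.seed(rep_seeds[b])
    mats <- lapply(seq_along(groups), function(s) {
      connectivity_matrix(roi_timeseries(
        matrix(stats::rnorm(n_timepoints * n_rois), n_timepoints, n_rois),
        subject_id = sprintf("S%03d", s)))
    })
    res <- spc_cluster_inference(mats, groups, n_perm = n_perm,
                                 seed = rep_seeds[b])
    pf <- vapply(res$clusters, `[[`, numeric(1), "p_FWE")
    min_p[b] <- if (length(pf)) min(pf) else 1
  }
  list(min_p_fwe = min_p, reject_rate_05 = mean(min_p < 0.05), n_reps = n_reps)
}

#' Power of the paired-state analysis on planted-coupling cohorts
#'
#' Replicates the study-scale cohort (one perturbed coupling in the patient
#' group), runs per-subject MEM fits, Bonferroni-corrected per-state energy
#' tests, and checks (a) whether the ground-truth affected states are
#' flagged and (b) whether the control group's mean frequency of the
#' affected complementary state pair exceeds the patient group's.
#'
#' @param n_reps number of replicate cohorts.
#' @param delta coupling shift for the patient group (edge 1-2).
#' @param seed integer seed.
#' @param tol MEM fit tolerance.
#' @param config_fn function(seed, delta) -> `cohort_config`; defaults to
#'   [default_cohort_config()].
#' @return List with `flag_rate` (fraction of replicates flagging all
#'   affected states), `control_higher_rate` (fraction with higher control
#'   pair frequency), and per-replicate detail.
#' @export
simulate_planted_power <- function(n_reps = 50L, delta = -0.6, seed = 1L,
                                   tol = 1e-6,
                                   config_fn = default_cohort_config) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  flagged <- logical(n_reps)
  control_higher <- logical(n_reps)
  for (b in seq_len(n_reps)) {
    cohort <- generate_cohort(config_fn(seed = rep_seeds[b], delta = delta))
    affected <- planted_affected_states(cohort, n_states = 2L)
    profiles <- fit_cohort(cohort, tol = tol)
    tests <- energy_ttest_per_state(profiles)
    adj <- bonferroni(tests$p, m = sum(!is.na(tests$p)))
    sig <- tests$state[which(adj$significant)]
    flagged[b] <- all(affected %in% sig)
    pf <- paired_state_frequencies(profiles, matrix(sort(affected), ncol = 2))
    m <- tapply(pf[[3]], pf$group, mean)
    control_higher[b] <- m[["control"]] > m[["patient"]]
  }
  list(flag_rate = mean(flagged), control_higher_rate = mean(control_higher),
       flagged = flagged, control_higher = control_higher, n_reps = n_reps)
}

#' Parameter recovery of the MEM fit on simulated data
#'
#' Samples a long state series from known parameters, fits the MEM to the
#' empirical distribution, and reports the Pearson correlation between the
#' true and fitted concatenated (h, J) vectors.
#'
#' @param n_rois system size N.
#' @param n_samples series length.
#' @param seed integer seed (controls both the true parameters and the draw).
#' @param tol fit tolerance.
#' @return List with `correlation`, `true`, `fitted` (concatenated vectors).
#' @export
simulate_mem_recovery <- function(n_rois = 8L, n_samples = 50000L, seed = 1L,
                                  tol = 1e-6) {
  set.seed(seed)
  idx <- pair_index(n_rois)
  h <- stats::rnorm(n_rois, sd = 0.3)
  J <- matrix(0, n_rois, n_rois)
  J[idx] <- stats::rnorm(nrow(idx), sd = 0.25)
  J <- J + t(J)
  truth <- mem_params(h, J)
  bps <- sample_ising(truth, n_samples, method = "exact")
  fit <- fit_mem(empirical_distribution(bps), tol = tol, lr = 0.2,
                 max_iter = 1e5)
  tv <- c(truth$h, truth$J[idx])
  fv <- c(fit$params$h, fit$params$J[idx])
  list(correlation = stats::cor(tv, fv), true = tv, fitted = fv,
       converged = fit$diagnostics$converged)
}
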