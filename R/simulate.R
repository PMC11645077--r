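#' Sample binary activation states from a pairwise MEM
#'
#' `method = "exact"` enumerates all `2^N` states, computes the Boltzmann
#' distribution and draws i.i.d. states by inverse-CDF sampling (N <= 20).
#' `method = "gibbs"` runs a single-site-sweep Gibbs chain with burn-in and
#' thinning, usable for larger N.
#'
#' @param params a `mem_params`.
#' @param n_samples number of states to draw (>= 1).
#' @param seed optional integer seed.
#' @param method `"exact"` or `"gibbs"`.
#' @param burn_in,thin Gibbs chain burn-in sweeps and thinning interval.
#' @return A `binary_patterns` with `n_samples` rows.
#' @export
sample_ising <- function(params, n_samples, seed = NULL,
                         method = c("exact", "gibbs"),
                         burn_in = 1000L, thin = 5L) {
  stopifnot(inherits(params, "mem_params"), n_samples >= 1)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n <- length(params$h)
  if (method == "exact") {
    if (n > 20L) stop("exact enumeration limited to N <= 20; use method = 'gibbs'")
    dist <- boltzmann_distribution(params)
    idx <- sample.int(2^n, n_samples, replace = TRUE, prob = dist$probs) - 1L
    spins <- state_spins(n)[idx + 1L, , drop = FALSE]
  } else {
    spins <- gibbs_sample_cpp(params$h, params$J, as.integer(n_samples),
                              as.integer(burn_in), as.integer(thin))
  }
  binary_patterns(spins, roi_names = params$roi_names)
}

#' Configuration of a synthetic two-group cohort
#'
#' Describes a cohort of control and patient subjects whose joint ROI
#' activations follow subject-specific pairwise MEMs: patients get
#' `base + patient_delta` parameters, and every subject receives independent
#' Gaussian jitter of sd `subject_jitter_sd` on each field and coupling.
#'
#' @param n_rois number of ROIs N (>= 2).
#' @param n_controls,n_patients group sizes.
#' @param n_timepoints time points T per subject (>= 1).
#' @param base_h length-N local fields.
#' @param base_J symmetric N x N couplings, zero diagonal.
#' @param patient_delta_h,patient_delta_J additive parameter shifts applied to
#'   the patient group (same shapes; default zero).
#' @param subject_jitter_sd nonnegative sd of per-subject parameter jitter.
#' @param mode `"binary"` (spin series only) or `"continuous"` (BOLD-like
#'   surrogate: spin amplitude `amplitude` plus Gaussian noise `noise_sd`,
#'   optional AR(1) smoothing `ar_coef`).
#' @param amplitude,noise_sd,ar_coef continuous-mode surrogate parameters.
#' @param seed integer seed; all substreams derive from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_rois, n_controls, n_patients, n_timepoints,
                          base_h = rep(0, n_rois),
                          base_J = matrix(0, n_rois, n_rois),
                          patient_delta_h = rep(0, n_rois),
                          patient_delta_J = matrix(0, n_rois, n_rois),
                          subject_jitter_sd = 0,
                          mode = c("binary", "continuous"),
                          amplitude = 1, noise_sd = 0.4, ar_coef = 0,
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_rois >= 2, n_timepoints >= 1, subject_jitter_sd >= 0,
            length(base_h) == n_rois, length(patient_delta_h) == n_rois)
  for (m in list(base_J, patient_delta_J)) {
    if (!identical(dim(as.matrix(m)), c(as.integer(n_rois), as.integer(n_rois))))
      stop("coupling matrices must be N x N")
    if (max(abs(m - t(m))) > 1e-10 || any(diag(as.matrix(m)) != 0))
      stop("coupling matrices must be symmetric with zero diagonal")
  }
  structure(list(n_rois = as.integer(n_rois),
                 n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 n_timepoints = as.integer(n_timepoints),
                 base_h = base_h, base_J = as.matrix(base_J),
                 patient_delta_h = patient_delta_h,
                 patient_delta_J = as.matrix(patient_delta_J),
                 subject_jitter_sd = subject_jitter_sd,
                 mode = mode, amplitude = amplitude, noise_sd = noise_sd,
                 ar_coef = ar_coef, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default study-scale cohort configuration
#'
#' The conditions the rest of the package simulates by default: 8 ROIs,
#' 63 controls and 55 patients, 888 time points per subject, zero local
#' fields with uniform ferromagnetic couplings (J = 0.15), a planted deficit
#' of -0.6 on the coupling between ROIs 1 and 2 in the patient group, and
#' between-subject parameter jitter of sd 0.05.
#'
#' @param seed integer seed.
#' @param delta coupling shift applied to the patient group on edge (1, 2).
#' @param mode `"binary"` or `"continuous"`.
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L, delta = -0.6,
                                  mode = c("binary", "continuous")) {
  n <- 8L
  J <- matrix(0.15, n, n); diag(J) <- 0
  dJ <- matrix(0, n, n); dJ[1, 2] <- dJ[2, 1] <- delta
  cohort_config(n_rois = n, n_controls = 63L, n_patients = 55L,
                n_timepoints = 888L, base_h = rep(0, n), base_J = J,
                patient_delta_J = dJ, subject_jitter_sd = 0.05,
                mode = match.arg(mode), seed = seed)
}

ar1_smooth <- function(x, phi) {
  if (phi == 0) return(x)
  as.numeric(stats::filter(x, phi, method = "recursive")) * sqrt(1 - phi^2)
}

#' Generate a synthetic two-group cohort
#'
#' Draws subject-specific MEM parameters (base + group delta + jitter), then
#' samples each subject's activation-state series exactly from its Boltzmann
#' distribution. In continuous mode a BOLD-like surrogate is added whose
#' per-ROI mean-threshold binarization recovers the sampled spins when the
#' noise is small. Generation is bit-reproducible given the config (which
#' carries the seed); all per-subject substreams derive from that seed.
#'
#' @param config a `cohort_config`.
#' @return A `cohort`: list with `subjects` (each holding `subject_id`,
#'   `group`, `params`, `patterns`, and `series` in continuous mode) and
#'   `config`; ground-truth group parameters are in `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_rois
  n_sub <- config$n_controls + config$n_patients
  sub_seeds <- sample.int(.Machine$integer.max, n_sub)
  groups <- rep(c("control", "patient"), c(config$n_controls, config$n_patients))
  ids <- sprintf("S%03d", seq_len(n_sub))
  truth <- list(
    control = mem_params(config$base_h, config$base_J),
    patient = mem_params(config$base_h + config$patient_delta_h,
                         config$base_J + config$patient_delta_J))
  idx <- pair_index(n)
  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    set.seed(sub_seeds[s])
    p0 <- truth[[groups[s]]]
    h <- p0$h
    J <- p0$J
    if (config$subject_jitter_sd > 0) {
      h <- h + stats::rnorm(n, sd = config$subject_jitter_sd)
      jit <- stats::rnorm(nrow(idx), sd = config$subject_jitter_sd)
      Jj <- matrix(0, n, n); Jj[idx] <- jit
      J <- J + Jj + t(Jj)
    }
    params <- mem_params(h, J)
    patterns <- sample_ising(params, config$n_timepoints, method = "exact")
    series <- NULL
    if (config$mode == "continuous") {
      noise <- matrix(stats::rnorm(config$n_timepoints * n, sd = config$noise_sd),
                      config$n_timepoints, n)
      if (config$ar_coef != 0) noise <- apply(noise, 2L, ar1_smooth, phi = config$ar_coef)
      series <- roi_timeseries(config$amplitude * patterns$spins + noise,
                               roi_names = patterns$roi_names, subject_id = ids[s])
    }
    subjects[[s]] <- list(subject_id = ids[s], group = groups[s],
                          params = params, patterns = patterns, series = series)
  }
  structure(list(subjects = subjects, config = config, truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("Synthetic cohort: %d controls + %d patients, %d ROIs, T = %d (%s mode)\n",
              sum(g == "control"), sum(g == "patient"),
              x$config$n_rois, x$config$n_timepoints, x$config$mode))
  invisible(x)
}

#' Behavioral covariate specification
#'
#' Each score is a linear function of the subject's mean empirical
#' probability over a target set of states, plus a group shift and Gaussian
#' noise: `score = intercept + coefficient * mean(p_hat[targets]) +
#' group_shift[group] + noise`.
#'
#' @param scores named list; each element a list with `target_states`
#'   (state indices), `coefficient`, `noise_sd` (> 0), and optional
#'   `intercept` (default 0).
#' @param group_shift named numeric, additive offset for the patient group
#'   per score (default 0).
#' @return A `behavior_spec`.
#' @export
behavior_spec <- function(scores, group_shift = NULL) {
  stopifnot(is.list(scores), length(names(scores)) == length(scores))
  for (nm in names(scores)) {
    sc <- scores[[nm]]
    if (is.null(sc$noise_sd) || sc$noise_sd <= 0) stop("noise_sd must be > 0 for ", nm)
    if (is.null(sc$intercept)) scores[[nm]]$intercept <- 0
  }
  if (is.null(group_shift)) group_shift <- stats::setNames(numeric(length(scores)), names(scores))
  structure(list(scores = scores, group_shift = group_shift), class = "behavior_spec")
}

#' Generate behavioral scores coupled to paired-state probabilities
#'
#' @param cohort a `cohort`.
#' @param spec a `behavior_spec`; score names must be unique.
#' @param seed integer seed.
#' @return data.frame with `subject_id`, `group` and one column per score.
#' @export
generate_behavior <- function(cohort, spec, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "behavior_spec"))
  set.seed(seed)
  n_sub <- length(cohort$subjects)
  out <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    group = vapply(cohort$subjects, `[[`, character(1), "group"))
  emp <- lapply(cohort$subjects, function(s) empirical_distribution(s$patterns)$probs)
  for (nm in names(spec$scores)) {
    sc <- spec$scores[[nm]]
    if (any(sc$target_states < 0 | sc$target_states >= length(emp[[1]])))
      stop("target state out of range for score ", nm)
    p <- vapply(emp, function(pr) mean(pr[sc$target_states + 1L]), numeric(1))
    shift <- ifelse(out$group == "patient", spec$group_shift[[nm]], 0)
    out[[nm]] <- sc$intercept + sc$coefficient * p + shift +
      stats::rnorm(n_sub, sd = sc$noise_sd)
  }
  out
}

#' Build a toy 4D image + label volume carrying known ROI series
#'
#' Each ROI occupies `voxels_per_roi` voxels that all carry the ROI's time
#' series plus i.i.d. Gaussian noise; label 0 is background. A fixture for
#' testing mean-signal extraction.
#'
#' @param n_rois number of ROIs.
#' @param voxels_per_roi voxels per ROI (>= 1).
#' @param series an `roi_ts` with `n_rois` columns (the planted signals).
#' @param noise_sd voxel noise sd.
#' @param seed integer seed.
#' @return list with `image` (4D array) and `labels` (3D integer array).
#' @export
generate_toy_image <- function(n_rois, voxels_per_roi, series, noise_sd = 0,
                               seed = 1L) {
  stopifnot(inherits(series, "roi_ts"), voxels_per_roi >= 1)
  if (ncol(series$values) != n_rois) stop("series must have n_rois columns")
  set.seed(seed)
  t_len <- nrow(series$values)
  labels <- array(0L, dim = c(voxels_per_roi, n_rois + 1L, 1L))
  img <- array(0, dim = c(voxels_per_roi, n_rois + 1L, 1L, t_len))
  for (r in seq_len(n_rois)) {
    labels[, r, 1L] <- r
    for (v in seq_len(voxels_per_roi)) {
      img[v, r, 1L, ] <- series$values[, r] + stats::rnorm(t_len, sd = noise_sd)
    }
  }
  list(image = img, labels = labels)
}
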