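#' Build per-subject state profiles from a cohort
#'
#' Fits a pairwise MEM to every subject's binarized series and collects the
#' empirical state distribution, fitted parameters and energy table — the
#' per-subject quantities the group analysis runs on.
#'
#' @param cohort a `cohort` (or a list of `binary_patterns` plus `groups`).
#' @param tol,lr,max_iter fitting controls passed to [fit_mem()].
#' @return List of `subject_profile` objects: `subject_id`, `group`,
#'   `empirical` (a `state_distribution`), `params`, `energies`
#'   (an `energy_table`), `diagnostics`.
#' @export
fit_cohort <- function(cohort, tol = 1e-6, lr = 0.2, max_iter = 1e5) {
  stopifnot(inherits(cohort, "cohort"))
  lapply(cohort$subjects, function(s) {
    emp <- empirical_distribution(s$patterns)
    fit <- fit_mem(emp, lr = lr, tol = tol, max_iter = max_iter,
                   roi_names = s$patterns$roi_names)
    structure(list(subject_id = s$subject_id, group = s$group,
                   empirical = emp, params = fit$params,
                   energies = energy_table(fit$params),
                   diagnostics = fit$diagnostics),
              class = "subject_profile")
  })
}

profile_groups <- function(profiles) {
  vapply(profiles, `[[`, character(1), "group")
}

profile_probs <- function(profiles) {
  t(vapply(profiles, function(p) p$empirical$probs,
           numeric(length(profiles[[1]]$empirical$probs))))
}

#' Partition states by cross-subject usage rate
#'
#' Usage rates are the mean empirical state probabilities across subjects —
#' how often each connectivity state is visited. States are split into those
#' at approximately the threshold (within `band`), below it, and above it.
#'
#' @param profiles list of `subject_profile`s.
#' @param threshold usage-rate threshold (default 0.05, i.e. 5%).
#' @param band half-width of the "approximately at threshold" band
#'   (default 0.005 absolute).
#' @return List with state-index vectors `at`, `below`, `above` and the
#'   numeric `usage_rate` vector.
#' @export
usage_rate_partition <- function(profiles, threshold = 0.05, band = 0.005) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  rate <- colMeans(profile_probs(profiles))
  states <- seq_along(rate) - 1L
  at <- abs(rate - threshold) <= band
  list(at = states[at],
       below = states[!at & rate < threshold],
       above = states[!at & rate > threshold],
       usage_rate = rate)
}

#' Occurrence sets of states across the two groups
#'
#' A state "appears" in a group when at least `min_visits` time points of at
#' least one subject in the group are spent in it (default: visited at least
#' once, i.e. empirical probability > 0).
#'
#' @param profiles list of `subject_profile`s; both groups must be present.
#' @param min_visits minimum visit count for a state to count as appearing.
#' @return List of disjoint state-index sets `patient_only`, `control_only`,
#'   `shared`.
#' @export
occurrence_sets <- function(profiles, min_visits = 1L) {
  grp <- profile_groups(profiles)
  if (!all(c("control", "patient") %in% grp)) stop("both groups must be present")
  appears <- function(g) {
    pm <- profile_probs(profiles[grp == g])
    tobs <- vapply(profiles[grp == g], function(p) p$empirical$n_observations,
                   integer(1))
    counts <- round(pm * tobs)  # rows are subjects; undo count/T round-off
    which(apply(counts >= min_visits, 2L, any)) - 1L
  }
  pat <- appears("patient")
  ctl <- appears("control")
  list(patient_only = setdiff(pat, ctl),
       control_only = setdiff(ctl, pat),
       shared = intersect(pat, ctl))
}

#' Per-state two-sample t-tests on subject energies
#'
#' For each state, compares the per-subject model energies between patients
#' and controls with a Welch (default) or pooled two-sample t-test,
#' signed patient minus control.
#'
#' @param profiles list of `subject_profile`s (>= 2 subjects per group).
#' @param states state indices to test; default all states.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return data.frame with `state`, `t`, `df`, `p`, `mean_control`,
#'   `mean_patient`; states with zero variance in both groups get `NA`
#'   statistics and are flagged in `degenerate`.
#' @export
energy_ttest_per_state <- function(profiles, states = NULL, var_equal = FALSE) {
  grp <- profile_groups(profiles)
  if (sum(grp == "control") < 2L || sum(grp == "patient") < 2L)
    stop("need at least 2 subjects per group")
  E <- t(vapply(profiles, function(p) p$energies$energies,
                numeric(length(profiles[[1]]$energies$energies))))
  if (is.null(states)) states <- seq_len(ncol(E)) - 1L
  res <- lapply(states, function(k) {
    x <- E[grp == "patient", k + 1L]
    y <- E[grp == "control", k + 1L]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      return(data.frame(state = k, t = NA_real_, df = NA_real_, p = NA_real_,
                        mean_control = mean(y), mean_patient = mean(x),
                        degenerate = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(state = k, t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean_control = mean(y), mean_patient = mean(x),
               degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Bonferroni correction
#'
#' Adjusted p-values are `min(1, m * p)`; a test is flagged significant when
#' its raw p-value is below `alpha / m`.
#'
#' @param p_values raw p-values in `[0, 1]` (NAs propagate).
#' @param m number of tests (>= length of `p_values`); defaults to the
#'   number of p-values.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame with `p_raw`, `p_adjusted`, `significant`.
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (m <= 0) stop("m must be positive")
  if (m < length(p_values)) stop("m must be at least the number of tests")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  data.frame(p_raw = p_values,
             p_adjusted = pmin(1, m * p_values),
             significant = !is.na(p_values) & p_values < alpha / m)
}

hamming <- function(a, b) {
  x <- bitwXor(as.integer(a), as.integer(b))
  sum(as.integer(intToBits(x)))
}

#' Identify complementary paired states
#'
#' `rule = "min_hamming"` greedily pairs the states whose activation maps are
#' closest in Hamming distance; ties are broken toward the lexicographically
#' smaller state-index pair, so the pairing is deterministic. An odd leftover
#' state is reported in `unpaired`, never dropped silently.
#' `rule = "explicit"` accepts a user-supplied pairing (two-column matrix).
#'
#' @param states significant state indices (>= 2 for `min_hamming`).
#' @param rule `"min_hamming"` or `"explicit"`.
#' @param pairs with `rule = "explicit"`: two-column matrix of state pairs.
#' @return List with `pairs` (two-column integer matrix, one row per pair)
#'   and `unpaired` (integer vector).
#' @export
identify_paired_states <- function(states, rule = c("min_hamming", "explicit"),
                                   pairs = NULL) {
  rule <- match.arg(rule)
  states <- sort(unique(as.integer(states)))
  if (rule == "explicit") {
    if (is.null(pairs)) stop("explicit rule needs a pairs matrix")
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    if (!all(pairs %in% states)) stop("explicit pairs must be drawn from the state set")
    return(list(pairs = pairs, unpaired = setdiff(states, as.vector(pairs))))
  }
  if (length(states) < 2L) stop("need at least 2 states to pair")
  out <- NULL
  remaining <- states
  while (length(remaining) >= 2L) {
    cmb <- utils::combn(remaining, 2L)
    d <- apply(cmb, 2L, function(ab) hamming(ab[1], ab[2]))
    # order: distance, then smaller first index, then smaller second index
    best <- order(d, cmb[1, ], cmb[2, ])[1L]
    out <- rbind(out, cmb[, best])
    remaining <- setdiff(remaining, cmb[, best])
  }
  list(pairs = matrix(as.integer(out), ncol = 2L), unpaired = remaining)
}

#' Per-subject averaged paired-state probabilities
#'
#' For each subject and pair, the average of the two empirical state
#' probabilities, `(p_hat(a) + p_hat(b)) / 2` — the quantity summarized in
#' the group boxplots and correlated with behavior.
#'
#' @param profiles list of `subject_profile`s.
#' @param pairs two-column matrix of state pairs (e.g. from
#'   [identify_paired_states()]).
#' @return data.frame with `subject_id`, `group` and one column per pair
#'   (named `pair_<a>_<b>`).
#' @export
paired_state_frequencies <- function(profiles, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  pm <- profile_probs(profiles)
  out <- data.frame(
    subject_id = vapply(profiles, `[[`, character(1), "subject_id"),
    group = profile_groups(profiles))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    out[[sprintf("pair_%d_%d", a, b)]] <- (pm[, a + 1L] + pm[, b + 1L]) / 2
  }
  out
}
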