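test_that("usage-rate partition splits states around the threshold band", {
  unif <- lapply(1:4, function(i) fake_profile(rep(1 / 8, 8),
                                               c("control", "patient")[i %% 2 + 1]))
  part <- usage_rate_partition(unif)
  expect_identical(part$above, 0:7)     # 12.5% > 5% everywhere
  expect_length(part$below, 0)

  probs <- c(0.05, 0.60, 0.35, 0)       # at, above, above, never visited
  pr <- lapply(1:4, function(i) fake_profile(probs,
                                             c("control", "patient")[i %% 2 + 1]))
  part2 <- usage_rate_partition(pr)
  expect_identical(part2$at, 0L)
  expect_true(3L %in% part2$below)
  expect_identical(sort(c(part2$at, part2$below, part2$above)), 0:3)
  expect_error(usage_rate_partition(pr, threshold = 1.2), "threshold")
})

test_that("occurrence sets partition appearing states by group", {
  base <- c(0.5, 0.5, 0, 0)
  p1 <- fake_profile(base, "control")
  p2 <- fake_profile(base, "patient")
  sets <- occurrence_sets(list(p1, p2))
  expect_length(sets$patient_only, 0)
  expect_length(sets$control_only, 0)
  expect_identical(sets$shared, c(0L, 1L))

  # one patient visits state 2 once in 1000 observations
  p3 <- fake_profile(c(0.5, 0.499, 0.001, 0), "patient")
  sets2 <- occurrence_sets(list(p1, p2, p3))
  expect_identical(sets2$patient_only, 2L)
  # disjointness and coverage of everything that appears
  appearing <- sort(unique(c(sets2$patient_only, sets2$control_only, sets2$shared)))
  expect_identical(appearing, c(0L, 1L, 2L))
  expect_error(occurrence_sets(list(p1)), "both groups")

  # a visit-count floor removes the single-visit state
  sets3 <- occurrence_sets(list(p1, p2, p3), min_visits = 2L)
  expect_length(sets3$patient_only, 0)
})

test_that("per-state energy tests are zero for identical groups and flag degenerate states", {
  e1 <- c(1, 2, 3, 4); e2 <- c(1.5, 2.5, 3.5, 4.5)
  profs <- list(fake_profile(rep(0.25, 4), "control", energies = e1),
                fake_profile(rep(0.25, 4), "control", energies = e2),
                fake_profile(rep(0.25, 4), "patient", energies = e1),
                fake_profile(rep(0.25, 4), "patient", energies = e2))
  res <- energy_ttest_per_state(profs)
  expect_equal(res$t, rep(0, 4))
  expect_equal(res$df, rep(2, 4))

  same <- list(fake_profile(rep(0.25, 4), "control", energies = e1),
               fake_profile(rep(0.25, 4), "control", energies = e1),
               fake_profile(rep(0.25, 4), "patient", energies = e1),
               fake_profile(rep(0.25, 4), "patient", energies = e1))
  res2 <- energy_ttest_per_state(same)
  expect_true(all(res2$degenerate))
  expect_true(all(is.na(res2$p)))
  expect_error(energy_ttest_per_state(profs[1:3]), "2 subjects")
})

test_that("per-state false-positive rate sits near alpha before correction", {
  set.seed(101)
  n_states_total <- 0; n_sig <- 0
  for (b in 1:30) {
    cfg <- cohort_config(n_rois = 3, n_controls = 10, n_patients = 10,
                         n_timepoints = 150, subject_jitter_sd = 0.05,
                         base_J = {J <- matrix(0.1, 3, 3); diag(J) <- 0; J},
                         seed = sample.int(1e6, 1))
    res <- energy_ttest_per_state(fit_cohort(generate_cohort(cfg)))
    ok <- !is.na(res$p)
    n_states_total <- n_states_total + sum(ok)
    n_sig <- n_sig + sum(res$p[ok] < 0.05)
  }
  rate <- n_sig / n_states_total
  expect_lt(abs(rate - 0.05), 0.04)
})

test_that("Bonferroni correction adjusts, clips, and is monotone in m", {
  one <- bonferroni(c(0.03, 0.5))
  expect_equal(one$p_adjusted, c(0.06, 1))
  expect_identical(bonferroni(0.03, m = 1)$p_adjusted, 0.03)
  expect_true(bonferroni(0.03, m = 1)$significant)
  expect_equal(bonferroni(0.5, m = 4)$p_adjusted, 1)

  # a connectome-scale denominator: alpha / 1159 as the significance threshold
  thr <- 0.05 / 1159
  expect_equal(thr, 4.3141e-05, tolerance = 1e-4)
  expect_true(bonferroni(thr * 0.9, m = 1159)$significant)
  expect_false(bonferroni(thr * 1.1, m = 1159)$significant)

  set.seed(102)
  p <- runif(20)
  for (i in 1:5) {
    m_small <- sample(20:40, 1); m_big <- m_small + sample(1:50, 1)
    sig_small <- bonferroni(p, m = m_small)$significant
    sig_big <- bonferroni(p, m = m_big)$significant
    expect_true(all(which(sig_big) %in% which(sig_small)))
  }
  expect_error(bonferroni(c(0.1), m = 0), "positive")
})

test_that("paired-state identification is deterministic and reports leftovers", {
  # two states one flip apart pair up
  res <- identify_paired_states(c(4L, 6L))
  expect_identical(res$pairs, matrix(c(4L, 6L), ncol = 2))
  expect_length(res$unpaired, 0)

  # greedy min-Hamming with ties toward the smaller pair on the 23/234/123/134 set
  res2 <- identify_paired_states(c(6L, 14L, 7L, 13L))
  expect_identical(res2$pairs, rbind(c(6L, 7L), c(13L, 14L)))

  # the explicit rule accepts the complementary pairing used for those labels
  res3 <- identify_paired_states(c(6L, 14L, 7L, 13L), rule = "explicit",
                                 pairs = rbind(c(6L, 14L), c(7L, 13L)))
  expect_identical(res3$pairs, rbind(c(6L, 14L), c(7L, 13L)))
  expect_length(res3$unpaired, 0)

  odd <- identify_paired_states(c(1L, 3L, 16L))
  expect_identical(odd$pairs, matrix(c(1L, 3L), ncol = 2))
  expect_identical(odd$unpaired, 16L)
  expect_error(identify_paired_states(5L), "at least 2")
})

test_that("paired-state frequencies average the two state probabilities", {
  p <- fake_profile(c(0.04, 0.02, 0.9, 0.04), "control")
  q <- fake_profile(c(0.10, 0.06, 0.8, 0.04), "patient")
  pf <- paired_state_frequencies(list(p, q), rbind(c(0L, 1L)))
  expect_equal(pf$pair_0_1, c(0.03, 0.08))
  expect_identical(names(pf), c("subject_id", "group", "pair_0_1"))
})

test_that("a planted coupling difference surfaces through the full state pipeline", {
  n <- 4
  J <- matrix(0.15, n, n); diag(J) <- 0
  dJ <- matrix(0, n, n); dJ[1, 2] <- dJ[2, 1] <- -0.8
  cfg <- cohort_config(n_rois = n, n_controls = 15, n_patients = 15,
                       n_timepoints = 600, base_J = J, patient_delta_J = dJ,
                       subject_jitter_sd = 0.05, seed = 77)
  co <- generate_cohort(cfg)
  profiles <- fit_cohort(co)
  res <- energy_ttest_per_state(profiles)
  adj <- bonferroni(res$p, m = sum(!is.na(res$p)))
  affected <- planted_affected_states(co, n_states = 2)
  expect_true(all(affected %in% res$state[which(adj$significant)]))
  # control group keeps the higher frequency on the affected complementary pair
  pf <- paired_state_frequencies(profiles, matrix(sort(affected), ncol = 2))
  means <- tapply(pf[[3]], pf$group, mean)
  expect_gt(means[["control"]], means[["patient"]])
})
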