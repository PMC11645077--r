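test_that("exact sampler reproduces the Boltzmann distribution", {
  # all parameters zero: uniform over the 8 states
  zero <- mem_params(rep(0, 3), matrix(0, 3, 3))
  bps <- sample_ising(zero, 30000, seed = 1)
  freq <- empirical_distribution(bps)$probs
  bound <- 3 * sqrt(0.125 * 0.875 / 30000)
  expect_true(all(abs(freq - 0.125) < bound))

  # dominant coupling concentrates mass on the aligned states
  J <- matrix(0, 2, 2); J[1, 2] <- J[2, 1] <- 3
  bps2 <- sample_ising(mem_params(c(0, 0), J), 20000, seed = 2)
  freq2 <- empirical_distribution(bps2)$probs
  expect_gt(freq2[1] + freq2[4], 0.99)
  expect_lt(abs(freq2[1] - 0.5), 0.02)

  # first and second moments match enumeration within 3 standard errors
  p <- mem_params(c(0.5, -0.2, 0.1), random_mem_params(3, seed = 3)$J)
  model <- oracle_boltzmann(p$h, p$J)
  S <- state_spins(3)
  bps3 <- sample_ising(p, 50000, seed = 4)
  m_model <- colSums(S * model)
  m_emp <- colMeans(bps3$spins)
  se <- sqrt((1 - m_model^2) / 50000)
  expect_true(all(abs(m_emp - m_model) < 3 * se + 1e-9))
  for (i in 1:2) for (j in (i + 1):3) {
    c_model <- sum(S[, i] * S[, j] * model)
    c_emp <- mean(bps3$spins[, i] * bps3$spins[, j])
    expect_lt(abs(c_emp - c_model), 3 * sqrt((1 - c_model^2) / 50000) + 1e-9)
  }
})

test_that("exact sampler converges in total variation", {
  p <- random_mem_params(4, seed = 5)
  freq <- empirical_distribution(sample_ising(p, 1e5, seed = 6))$probs
  model <- boltzmann_distribution(p)$probs
  expect_lt(sum(abs(freq - model)) / 2, 0.02)
})

test_that("Gibbs and exact samplers agree in first and second moments", {
  p <- random_mem_params(4, seed = 7)
  ge <- sample_ising(p, 20000, seed = 8, method = "exact")
  gg <- sample_ising(p, 20000, seed = 9, method = "gibbs")
  expect_lt(max(abs(colMeans(ge$spins) - colMeans(gg$spins))), 0.04)
  ce <- crossprod(ge$spins) / 20000
  cg <- crossprod(gg$spins) / 20000
  expect_lt(max(abs(ce - cg)), 0.04)
})

test_that("cohort generation is bit-reproducible and respects planted deltas", {
  cfg <- cohort_config(n_rois = 3, n_controls = 4, n_patients = 4,
                       n_timepoints = 200, subject_jitter_sd = 0.05, seed = 123)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects[[3]]$patterns$state_index,
                   c2$subjects[[3]]$patterns$state_index)
  expect_equal(c1$subjects[[7]]$params$J, c2$subjects[[7]]$params$J)

  # planted coupling favors the aligned state pair in the affected group
  n <- 3
  dJ <- matrix(0, n, n); dJ[1, 2] <- dJ[2, 1] <- 0.8
  cfg2 <- cohort_config(n_rois = n, n_controls = 6, n_patients = 6,
                        n_timepoints = 5000, base_J = matrix(0, n, n),
                        patient_delta_J = dJ, subject_jitter_sd = 0, seed = 42)
  co <- generate_cohort(cfg2)
  grp <- vapply(co$subjects, `[[`, character(1), "group")
  pc <- oracle_boltzmann(co$truth$control$h, co$truth$control$J)
  pp <- oracle_boltzmann(co$truth$patient$h, co$truth$patient$J)
  favored <- order(pp - pc, decreasing = TRUE)[1:2] - 1
  mean_prob <- function(g) {
    rowMeans(vapply(co$subjects[grp == g],
                    function(s) empirical_distribution(s$patterns)$probs,
                    numeric(2^n)))
  }
  expect_true(all(mean_prob("patient")[favored + 1] > mean_prob("control")[favored + 1]))
})

test_that("continuous surrogates binarize back to the sampled spins", {
  cfg <- cohort_config(n_rois = 4, n_controls = 2, n_patients = 2,
                       n_timepoints = 300, mode = "continuous",
                       noise_sd = 0.05, seed = 11)
  co <- generate_cohort(cfg)
  s <- co$subjects[[1]]
  expect_false(is.null(s$series))
  rebin <- binarize(s$series)
  expect_identical(rebin$spins, s$patterns$spins)
})

test_that("behavioral scores carry the specified linear coupling", {
  cfg <- cohort_config(n_rois = 3, n_controls = 60, n_patients = 58,
                       n_timepoints = 400,
                       base_J = {J <- matrix(0.2, 3, 3); diag(J) <- 0; J},
                       subject_jitter_sd = 0.15, seed = 13)
  co <- generate_cohort(cfg)
  probs <- vapply(co$subjects,
                  function(s) mean(empirical_distribution(s$patterns)$probs[c(1, 8)]),
                  numeric(1))

  spec0 <- behavior_spec(list(null_score = list(target_states = c(0, 7),
                                                coefficient = 0, noise_sd = 1)))
  b0 <- generate_behavior(co, spec0, seed = 14)
  expect_lt(abs(cor(b0$null_score, probs)), 3 / sqrt(118))

  spec1 <- behavior_spec(list(strong = list(target_states = c(0, 7),
                                            coefficient = 50, noise_sd = 1e-4)))
  b1 <- generate_behavior(co, spec1, seed = 15)
  expect_gt(cor(b1$strong, probs), 0.999)

  # closed-form population correlation r = c sd_p / sqrt(c^2 sd_p^2 + s^2)
  spec2 <- behavior_spec(list(mid = list(target_states = c(0, 7),
                                         coefficient = 30, noise_sd = 1)))
  b2 <- generate_behavior(co, spec2, seed = 16)
  sd_p <- sd(probs)
  r_pop <- 30 * sd_p / sqrt(30^2 * sd_p^2 + 1)
  r_hat <- cor(b2$mid, probs)
  expect_lt(abs(atanh(r_hat) - atanh(r_pop)), 3 / sqrt(118 - 3))

  expect_error(generate_behavior(co, behavior_spec(list(bad = list(
    target_states = 99, coefficient = 1, noise_sd = 1))), seed = 17),
    "out of range")
})

test_that("null cohorts give no preferred group in paired frequencies", {
  cfg <- cohort_config(n_rois = 3, n_controls = 15, n_patients = 15,
                       n_timepoints = 300, subject_jitter_sd = 0, seed = 19)
  profiles <- fit_cohort(generate_cohort(cfg))
  pf <- paired_state_frequencies(profiles, rbind(c(0L, 7L)))
  tt <- t.test(pf[[3]] ~ pf$group)
  expect_gt(tt$p.value, 0.001)
})
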