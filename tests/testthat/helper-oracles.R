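# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementation.

oracle_spins <- function(k, n) {
  ifelse(bitwAnd(as.integer(k), 2^(0:(n - 1))) > 0, 1, -1)
}

oracle_energy <- function(h, J, k) {
  n <- length(h)
  s <- oracle_spins(k, n)
  e <- -sum(h * s)
  for (i in 1:(n - 1)) for (j in (i + 1):n) e <- e - J[i, j] * s[i] * s[j]
  e
}

oracle_boltzmann <- function(h, J) {
  n <- length(h)
  w <- vapply(0:(2^n - 1), function(k) exp(-oracle_energy(h, J, k)), numeric(1))
  w / sum(w)
}

# maximum-likelihood fit by generic numerical optimization of the explicit
# log-likelihood (independent of the gradient-ascent implementation)
oracle_fit <- function(probs, n) {
  npair <- n * (n - 1) / 2
  unpack <- function(par) {
    h <- par[1:n]
    J <- matrix(0, n, n)
    J[upper.tri(J)] <- par[(n + 1):(n + npair)]
    J <- J + t(J)
    list(h = h, J = J)
  }
  negll <- function(par) {
    p <- unpack(par)
    -sum(probs * log(oracle_boltzmann(p$h, p$J)))
  }
  opt <- stats::optim(rep(0, n + npair), negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  unpack(opt$par)
}

oracle_neighbors <- function(k, n) bitwXor(as.integer(k), 2^(0:(n - 1)))

oracle_minima <- function(e) {
  n <- round(log2(length(e)))
  out <- integer(0)
  for (k in 0:(length(e) - 1)) {
    if (all(e[k + 1] < e[oracle_neighbors(k, n) + 1])) out <- c(out, k)
  }
  out
}

# exhaustive steepest-descent path simulation (ties to lower index)
oracle_basins <- function(e) {
  n <- round(log2(length(e)))
  vapply(0:(length(e) - 1), function(k) {
    repeat {
      nb <- sort(oracle_neighbors(k, n))
      lowest <- nb[which.min(e[nb + 1])]
      if (e[lowest + 1] < e[k + 1]) k <- lowest else return(k)
    }
  }, numeric(1))
}

# minimax node-weight path search (Floyd-Warshall relaxation) for saddles
oracle_depths <- function(e, minima) {
  m <- length(e)
  n <- round(log2(m))
  if (length(minima) == 1) {
    d <- max(e) - e[minima + 1]
    names(d) <- minima
    return(d)
  }
  W <- matrix(Inf, m, m)
  for (k in 0:(m - 1)) {
    W[k + 1, k + 1] <- e[k + 1]
    for (nb in oracle_neighbors(k, n)) W[k + 1, nb + 1] <- max(e[k + 1], e[nb + 1])
  }
  for (mid in 1:m) for (i in 1:m) {
    relax <- pmax(W[i, mid], W[mid, ])
    W[i, ] <- pmin(W[i, ], relax)
  }
  d <- vapply(minima, function(mm) {
    min(W[mm + 1, setdiff(minima, mm) + 1]) - e[mm + 1]
  }, numeric(1))
  names(d) <- minima
  d
}

random_mem_params <- function(n, seed, h_sd = 0.5, j_sd = 0.4) {
  set.seed(seed)
  h <- rnorm(n, sd = h_sd)
  J <- matrix(0, n, n)
  J[upper.tri(J)] <- rnorm(n * (n - 1) / 2, sd = j_sd)
  J <- J + t(J)
  mem_params(h, J)
}

# bare-bones subject profile for unit tests of the group-comparison logic
fake_profile <- function(probs, group, energies = NULL, n_obs = 1000L,
                         subject_id = "S") {
  if (is.null(energies)) energies <- -log(pmax(probs, 1e-12))
  structure(list(subject_id = subject_id, group = group,
                 empirical = state_distribution(probs, n_observations = n_obs),
                 params = NULL,
                 energies = structure(list(energies = energies,
                                           log_partition = 0,
                                           n_rois = round(log2(length(probs)))),
                                      class = "energy_table"),
                 diagnostics = NULL),
            class = "subject_profile")
}
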