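#' Pairwise maximum entropy model parameters
#'
#' Local fields `h` and pairwise couplings `J` defining the Boltzmann energy
#' \deqn{E(V_k) = -\sum_i h_i \sigma_i^{(k)} - \tfrac12 \sum_{i \ne j} J_{ij}
#'   \sigma_i^{(k)} \sigma_j^{(k)}}
#' over joint activation states of N ROIs with spins in \{-1, +1\}.
#'
#' @param h numeric vector of length N.
#' @param J symmetric N x N matrix with zero diagonal.
#' @param roi_names optional ROI names.
#' @return A `mem_params` object.
#' @export
mem_params <- function(h, J, roi_names = NULL) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  n <- length(h)
  if (!identical(dim(J), c(n, n))) stop("J must be N x N with N = length(h)")
  if (!all(is.finite(h)) || !all(is.finite(J))) stop("parameters must be finite")
  if (max(abs(J - t(J))) > 1e-10) stop("J must be symmetric")
  if (any(diag(J) != 0)) stop("J must have zero diagonal")
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(n))
  J <- (J + t(J)) / 2
  dimnames(J) <- NULL
  structure(list(h = unname(h), J = J, roi_names = roi_names),
            class = "mem_params")
}

# upper-triangle (i < j) index pairs, column-major over pairs
pair_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

# 2^N x n_pairs matrix of spin products sigma_i * sigma_j, i < j
pair_products <- function(S) {
  idx <- pair_index(ncol(S))
  S[, idx[, 1L], drop = FALSE] * S[, idx[, 2L], drop = FALSE]
}

#' Boltzmann energies of activation states
#'
#' @param params a `mem_params` object.
#' @param k optional vector of state indices; default all `2^N` states.
#' @return Numeric vector of energies `E(V_k)` (dimensionless).
#' @export
energy <- function(params, k = NULL) {
  stopifnot(inherits(params, "mem_params"))
  n <- length(params$h)
  S <- state_spins(n)
  if (!is.null(k)) {
    if (any(k < 0 | k > 2^n - 1)) stop("state index out of range")
    S <- S[k + 1L, , drop = FALSE]
  }
  as.numeric(-(S %*% params$h) - 0.5 * rowSums((S %*% params$J) * S))
}

#' Energy table over all states
#'
#' @param params a `mem_params` object.
#' @return An `energy_table`: `energies` over all `2^N` states and
#'   `log_partition` (log Z), with attribute `n_rois`.
#' @export
energy_table <- function(params) {
  e <- energy(params)
  m <- max(-e)
  logz <- m + log(sum(exp(-e - m)))
  structure(list(energies = e, log_partition = logz,
                 n_rois = length(params$h)),
            class = "energy_table")
}

#' Boltzmann distribution of a pairwise MEM
#'
#' `P(V_k) = exp(-E(V_k)) / Z`, computed with a max-shift for overflow safety.
#' Lower energy always means higher probability.
#'
#' @param params a `mem_params` object (N <= 20).
#' @return A `state_distribution` (model distribution, `n_observations = 0`).
#' @export
boltzmann_distribution <- function(params) {
  et <- energy_table(params)
  w <- exp(-(et$energies - min(et$energies)))
  state_distribution(w / sum(w), n_observations = 0L)
}

#' Fit a pairwise maximum entropy model to a state distribution
#'
#' Maximum-likelihood fitting by gradient ascent on the log-likelihood with
#' exact model moments by state enumeration:
#' `dh_i = lr * (<s_i>_data - <s_i>_model)` and likewise for all pairs.
#' Parameters start at zero, so the fit is deterministic given its inputs.
#'
#' @param dist a `state_distribution` (typically empirical).
#' @param lr learning rate on the moment residuals (default 0.1).
#' @param tol convergence tolerance on the maximum absolute moment residual
#'   (default 1e-8).
#' @param max_iter maximum gradient steps (default 5e5).
#' @param l2 optional ridge penalty on the couplings J (default 0, matching a
#'   plain maximum-likelihood fit).
#' @param roi_names optional ROI names attached to the fitted parameters.
#' @return A list with `params` (a `mem_params`) and `diagnostics` (a
#'   `mem_diagnostics`: per-sample log-likelihood, KL(empirical || model),
#'   maximum moment residual, iteration count, convergence flag).
#'   Non-convergence is reported via `converged = FALSE`, never silently.
#' @export
fit_mem <- function(dist, lr = 0.1, tol = 1e-8, max_iter = 5e5, l2 = 0,
                    roi_names = NULL) {
  stopifnot(inherits(dist, "state_distribution"))
  n <- dist$n_rois
  S <- state_spins(n)
  P <- pair_products(S)
  m_data <- as.numeric(crossprod(S, dist$probs))
  c_data <- as.numeric(crossprod(P, dist$probs))
  fit <- fit_mem_cpp(S, P, m_data, c_data, lr, tol, as.integer(max_iter), l2,
                     FALSE)
  idx <- pair_index(n)
  J <- matrix(0, n, n)
  J[idx] <- fit$j
  J <- J + t(J)
  params <- mem_params(fit$h, J, roi_names = roi_names)
  diag_ <- fit_diagnostics(params, dist)
  diag_$n_iterations <- fit$n_iterations
  diag_$converged <- fit$converged
  list(params = params, diagnostics = diag_)
}

#' Fit diagnostics for a MEM against an empirical distribution
#'
#' @param params a `mem_params`.
#' @param dist a `state_distribution` over the same N.
#' @return A `mem_diagnostics` list: `log_likelihood_per_sample`
#'   (`sum_k p_hat_k log P_model(k)`), `kl_empirical_vs_model` (with
#'   `0 log 0 = 0`), `max_moment_residual`, `n_iterations`, `converged`.
#' @export
fit_diagnostics <- function(params, dist) {
  stopifnot(inherits(params, "mem_params"), inherits(dist, "state_distribution"))
  n <- length(params$h)
  if (n != dist$n_rois) stop("parameter and distribution dimensions differ")
  model <- boltzmann_distribution(params)
  p <- dist$probs
  q <- model$probs
  ll <- sum(p * log(q))
  nz <- p > 0
  kl <- sum(p[nz] * (log(p[nz]) - log(q[nz])))
  S <- state_spins(n)
  P <- pair_products(S)
  resid <- max(abs(crossprod(S, p - q)), abs(crossprod(P, p - q)))
  structure(list(log_likelihood_per_sample = ll,
                 kl_empirical_vs_model = max(kl, 0),
                 max_moment_residual = resid,
                 n_iterations = NA_integer_,
                 converged = NA),
            class = "mem_diagnostics")
}

#' Log-likelihood trace of the gradient-ascent fit
#'
#' Runs the same fitting loop as [fit_mem()] while recording the per-sample
#' log-likelihood at every iteration; used to verify the ascent property.
#'
#' @inheritParams fit_mem
#' @return Numeric vector of per-sample log-likelihood values, one per
#'   iteration performed.
#' @export
fit_mem_ll_trace <- function(dist, lr = 0.1, tol = 1e-8, max_iter = 2000, l2 = 0) {
  stopifnot(inherits(dist, "state_distribution"))
  S <- state_spins(dist$n_rois)
  P <- pair_products(S)
  m_data <- as.numeric(crossprod(S, dist$probs))
  c_data <- as.numeric(crossprod(P, dist$probs))
  fit <- fit_mem_cpp(S, P, m_data, c_data, lr, tol, as.integer(max_iter), l2,
                     TRUE)
  fit$ll_trace
}

#' Write / read MEM parameter archives as delimited text
#'
#' The archive is a CSV whose first row holds the local fields `h` and the
#' remaining N rows the coupling matrix `J`, with ROI-name headers.
#'
#' @param params a `mem_params`.
#' @param path file path.
#' @export
write_mem_params <- function(params, path) {
  m <- rbind(h = params$h, params$J)
  rownames(m) <- c("h", params$roi_names)
  colnames(m) <- params$roi_names
  utils::write.csv(m, path)
  invisible(path)
}

#' @rdname write_mem_params
#' @export
read_mem_params <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  mem_params(m[1, ], m[-1, , drop = FALSE], roi_names = colnames(m))
}
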