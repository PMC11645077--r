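# single-flip neighbors of state k (0-based): k XOR 2^(i-1), i = 1..N
flip_neighbors <- function(k, n) {
  bitwXor(as.integer(k), as.integer(2^(seq_len(n) - 1L)))
}

#' Local minima of an energy landscape
#'
#' A state is a local minimum when its energy is strictly lower than the
#' energies of all N single-bit-flip neighbors on the hypercube.
#'
#' @param energies an `energy_table` (or a bare numeric vector of length
#'   `2^N` of state energies).
#' @return Integer vector of state indices of the local minima.
#' @export
local_minima <- function(energies) {
  e <- landscape_energies(energies)
  n <- as.integer(round(log2(length(e))))
  which(vapply(seq_along(e) - 1L, function(k) {
    all(e[k + 1L] < e[flip_neighbors(k, n) + 1L])
  }, logical(1))) - 1L
}

landscape_energies <- function(energies) {
  if (inherits(energies, "energy_table")) return(energies$energies)
  e <- as.numeric(energies)
  if (log2(length(e)) != round(log2(length(e)))) stop("need 2^N energies")
  e
}

#' Basin assignment by steepest single-flip descent
#'
#' From every state, repeatedly move to the lowest-energy single-flip
#' neighbor while that neighbor is strictly lower; the terminal state is the
#' basin label. Exact energy ties among neighbors are broken toward the
#' lower state index, making the descent deterministic.
#'
#' @inheritParams local_minima
#' @return A `landscape_summary`: `minima` (state indices), `basin_of`
#'   (length-`2^N` vector mapping each state to its minimum), `depth`
#'   (named numeric, see [basin_depth()]).
#' @export
basin_assignment <- function(energies) {
  e <- landscape_energies(energies)
  n <- as.integer(round(log2(length(e))))
  n_states <- length(e)
  basin <- rep(NA_integer_, n_states)
  descend <- function(k) {
    path <- integer(0)
    while (is.na(basin[k + 1L])) {
      path <- c(path, k)
      nb <- flip_neighbors(k, n)
      best <- nb[which.min(e[nb + 1L])]   # which.min takes the first = lowest index on ties
      if (e[best + 1L] < e[k + 1L]) k <- best else break
    }
    target <- if (is.na(basin[k + 1L])) k else basin[k + 1L]
    basin[c(path, k) + 1L] <<- target
    target
  }
  for (k in seq_len(n_states) - 1L) descend(k)
  minima <- sort(unique(basin))
  out <- structure(list(minima = minima, basin_of = basin, depth = NULL),
                   class = "landscape_summary")
  out$depth <- basin_depth(e, out)
  out
}

#' Basin depths by threshold percolation
#'
#' The depth of a minimum m is the height of the lowest saddle connecting m
#' to any other minimum along single-flip paths, minus `E(m)`: states are
#' added to the hypercube graph in increasing energy order and the first
#' level at which m's component contains a second minimum is its saddle.
#' A landscape with a single minimum gets `depth = max(E) - E(m)`.
#'
#' @inheritParams local_minima
#' @param summary a `landscape_summary` from [basin_assignment()].
#' @return Named numeric vector of depths (names = minimum state indices);
#'   all depths are nonnegative.
#' @export
basin_depth <- function(energies, summary) {
  e <- landscape_energies(energies)
  n <- as.integer(round(log2(length(e))))
  minima <- summary$minima
  if (length(minima) == 1L) {
    d <- max(e) - e[minima + 1L]
    names(d) <- minima
    return(d)
  }
  ord <- order(e, seq_along(e))      # ascending energy, ties by state index
  parent <- seq_len(length(e))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  added <- logical(length(e))
  n_min_in <- integer(length(e))     # minima count, valid at component roots
  is_min <- logical(length(e)); is_min[minima + 1L] <- TRUE
  saddle <- rep(NA_real_, length(e)) # per minimum (1-based state), saddle level
  # invariant: any component holding >= 2 minima has all of them assigned, so
  # after each merge it suffices to assign every still-unassigned minimum.
  for (pos in ord) {
    added[pos] <- TRUE
    n_min_in[pos] <- as.integer(is_min[pos])
    for (nb in flip_neighbors(pos - 1L, n) + 1L) {
      if (!added[nb]) next
      ra <- find(pos); rb <- find(nb)
      if (ra == rb) next
      parent[rb] <- ra
      n_min_in[ra] <- n_min_in[ra] + n_min_in[rb]
      if (n_min_in[ra] >= 2L) {
        for (m in minima + 1L) {
          if (is.na(saddle[m]) && added[m] && find(m) == ra) saddle[m] <- e[pos]
        }
      }
    }
    if (!anyNA(saddle[minima + 1L])) break
  }
  d <- saddle[minima + 1L] - e[minima + 1L]
  names(d) <- minima
  d
}

#' Full landscape summary report
#'
#' One row per state: index, active-ROI label, energy, model probability,
#' basin minimum, and the basin's depth.
#'
#' @param params a `mem_params`.
#' @return A data.frame with `2^N` rows.
#' @export
landscape_report <- function(params) {
  et <- energy_table(params)
  n <- et$n_rois
  dist <- boltzmann_distribution(params)
  summ <- basin_assignment(et)
  data.frame(
    state = seq_along(et$energies) - 1L,
    label = vapply(seq_along(et$energies) - 1L, state_label, character(1), n_rois = n),
    energy = et$energies,
    probability = dist$probs,
    basin = summ$basin_of,
    basin_depth = unname(summ$depth[as.character(summ$basin_of)])
  )
}
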