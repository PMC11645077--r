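#' Fisher-z ROI-to-ROI connectivity matrix
#'
#' Pearson correlation between every pair of ROI series, Fisher-transformed
#' (`atanh`); correlations are clipped to `+/-(1 - 1e-7)` before the
#' transform so perfectly correlated columns stay finite.
#'
#' @param ts an `roi_ts` with T >= 3 and nonconstant columns.
#' @return A `connectivity_matrix`: symmetric N x N `z` matrix with `NA`
#'   diagonal, plus `subject_id`.
#' @export
connectivity_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  if (nrow(ts$values) < 3L) stop("need at least 3 time points")
  v <- apply(ts$values, 2L, stats::var)
  if (any(v == 0))
    stop("constant ROI(s): ", paste(ts$roi_names[v == 0], collapse = ", "))
  r <- stats::cor(ts$values)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- NA_real_
  structure(list(z = z, roi_names = ts$roi_names, subject_id = ts$subject_id),
            class = "connectivity_matrix")
}

# stack the upper-triangle edge values of a list of connectivity matrices
# into a subjects x edges matrix; attr "edges" holds the (i, j) index pairs
edge_matrix <- function(mats) {
  n <- nrow(mats[[1]]$z)
  idx <- pair_index(n)
  em <- t(vapply(mats, function(m) m$z[idx], numeric(nrow(idx))))
  attr(em, "edges") <- idx
  em
}

# pooled-variance two-sample t per column of X (patient rows minus control rows)
edge_t_stats <- function(X, is_patient) {
  n1 <- sum(is_patient); n2 <- sum(!is_patient)
  m1 <- colMeans(X[is_patient, , drop = FALSE])
  m2 <- colMeans(X[!is_patient, , drop = FALSE])
  v1 <- apply(X[is_patient, , drop = FALSE], 2L, stats::var)
  v2 <- apply(X[!is_patient, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Edge-wise two-sample group contrast on Fisher-z connectivity
#'
#' Pooled-variance two-sample t-statistics per ROI pair, signed by the
#' between-subject contrast (control = -1, patient = +1 by default), with
#' `df = n1 + n2 - 2`.
#'
#' @param mats list of `connectivity_matrix` objects.
#' @param groups character vector (`"control"` / `"patient"`) per subject.
#' @param contrast length-2 numeric `(control, patient)` contrast; only the
#'   sign is used.
#' @return An `edge_stat_map`: symmetric `t` matrix (NA diagonal), `df`.
#' @export
edge_group_ttest <- function(mats, groups, contrast = c(-1, 1)) {
  stopifnot(length(mats) == length(groups))
  if (sum(groups == "control") < 2L || sum(groups == "patient") < 2L)
    stop("need at least 2 subjects per group")
  em <- edge_matrix(mats)
  tvec <- edge_t_stats(em, groups == "patient") * sign(contrast[2])
  n <- nrow(mats[[1]]$z)
  tmat <- matrix(NA_real_, n, n)
  idx <- attr(em, "edges")
  tmat[idx] <- tvec
  tmat[idx[, 2:1, drop = FALSE]] <- tvec
  structure(list(t = tmat, df = length(mats) - 2L,
                 roi_names = mats[[1]]$roi_names),
            class = "edge_stat_map")
}

# ---- optimal leaf ordering (Bar-Joseph style DP on the hclust merge tree) ----

olo_order <- function(hc, d) {
  D <- as.matrix(d)
  n <- attr(d, "Size")
  # node: negative = leaf index, positive = merge row
  node_info <- function(v) {
    if (v < 0) {
      leaf <- -v
      M <- matrix(0, 1, 1, dimnames = list(leaf, leaf))
      return(list(leaves = leaf, M = M,
                  orders = structure(list(leaf), names = paste(leaf, leaf))))
    }
    a <- node_info(hc$merge[v, 1]); b <- node_info(hc$merge[v, 2])
    la <- a$leaves; lb <- b$leaves
    leaves <- c(la, lb)
    M <- matrix(Inf, length(leaves), length(leaves),
                dimnames = list(leaves, leaves))
    orders <- list()
    for (side in 1:2) {
      left <- if (side == 1) a else b
      right <- if (side == 1) b else a
      for (l in left$leaves) for (r in right$leaves) {
        best <- Inf; best_ord <- NULL
        for (m1 in left$leaves) {
          if (!is.finite(left$M[as.character(l), as.character(m1)])) next
          for (m2 in right$leaves) {
            cost <- left$M[as.character(l), as.character(m1)] + D[m1, m2] +
              right$M[as.character(m2), as.character(r)]
            if (cost < best) {
              best <- cost
              best_ord <- c(left$orders[[paste(l, m1)]],
                            right$orders[[paste(m2, r)]])
            }
          }
        }
        if (best < M[as.character(l), as.character(r)]) {
          M[as.character(l), as.character(r)] <- best
          orders[[paste(l, r)]] <- best_ord
        }
      }
    }
    list(leaves = leaves, M = M, orders = orders)
  }
  root <- node_info(nrow(hc$merge))
  pos <- which(root$M == min(root$M), arr.ind = TRUE)[1, ]
  l <- rownames(root$M)[pos[1]]; r <- colnames(root$M)[pos[2]]
  root$orders[[paste(l, r)]]
}

#' Hierarchical ROI ordering with optimal leaf ordering
#'
#' ROIs are clustered by complete linkage on the dissimilarity
#' `1 - cor(edge profiles)` (each ROI's profile is its row of the
#' subject-averaged z matrix, excluding self-entries), optionally blended
#' with normalized Euclidean distance between supplied ROI coordinates.
#' Leaves are then ordered by an exact optimal-leaf-ordering dynamic program
#' (minimum total dissimilarity between adjacent leaves, subject to the
#' dendrogram), which is deterministic given the inputs.
#'
#' @param mats list of `connectivity_matrix` objects.
#' @param coords optional N x 3 matrix of ROI coordinates.
#' @param blend weight in `[0, 1]` on the anatomical (coordinate) distance;
#'   default 0 (purely functional similarity).
#' @return Integer permutation of `1..N` (ROI ordering), with the `hclust`
#'   object attached as attribute `"hclust"`.
#' @export
hierarchical_order <- function(mats, coords = NULL, blend = 0) {
  zbar <- Reduce(`+`, lapply(mats, `[[`, "z")) / length(mats)
  n <- nrow(zbar)
  diag(zbar) <- 0
  # profile correlation of ROIs i and j over the other N - 2 ROIs (the two
  # self-entries would otherwise anticorrelate strongly connected pairs)
  d_fun <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- setdiff(seq_len(n), c(i, j))
    pc <- suppressWarnings(stats::cor(zbar[i, keep], zbar[j, keep]))
    if (!is.finite(pc)) pc <- 0
    d_fun[i, j] <- d_fun[j, i] <- 1 - pc
  }
  if (!is.null(coords) && blend > 0) {
    d_anat <- as.matrix(stats::dist(coords))
    d_anat <- d_anat / max(d_anat)
    d <- (1 - blend) * d_fun + blend * d_anat
  } else {
    d <- d_fun
  }
  diag(d) <- 0
  dd <- stats::as.dist(d)
  hc <- stats::hclust(dd, method = "complete")
  ord <- olo_order(hc, dd)
  attr(ord, "hclust") <- hc
  ord
}

# connected components of suprathreshold cells in the ordered upper triangle,
# 4-connectivity (|di| + |dj| = 1) among cells (i, j), i < j in ordered coords
spc_components <- function(supra_ord) {
  cells <- which(supra_ord, arr.ind = TRUE)
  if (nrow(cells) == 0L) return(list())
  key <- paste(cells[, 1], cells[, 2])
  comp <- rep(NA_integer_, nrow(cells))
  cid <- 0L
  lookup <- stats::setNames(seq_len(nrow(cells)), key)
  for (s in seq_len(nrow(cells))) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- cid
      i <- cells[cur, 1]; j <- cells[cur, 2]
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        nk <- paste(nb[1], nb[2])
        hit <- lookup[nk]
        if (!is.na(hit) && is.na(comp[hit])) queue <- c(queue, hit)
      }
    }
  }
  split(seq_len(nrow(cells)), comp) |>
    lapply(function(ix) cells[ix, , drop = FALSE])
}

cluster_masses <- function(tmat_ord, supra_ord) {
  comps <- spc_components(supra_ord)
  lapply(comps, function(cells) {
    list(cells = cells,
         mass = sum(abs(tmat_ord[cells])),
         size = nrow(cells))
  })
}

#' SPC permutation cluster-mass inference on edge statistics
#'
#' Spatial pairwise clustering: edges are tested with the pooled two-sample
#' t contrast, thresholded two-sided at the `height_p` critical value, and
#' suprathreshold cells of the hierarchically ordered upper-triangular matrix
#' are grouped into 4-connected clusters scored by their mass (sum of |T|).
#' Group labels are permuted (subjects are the exchangeability unit) to build
#' the null: the per-permutation maximum cluster mass gives FWE-corrected
#' p-values, the pooled null cluster-mass distribution gives uncorrected
#' p-values, and Benjamini-Hochberg across observed clusters gives FDR.
#'
#' @param mats list of `connectivity_matrix` objects.
#' @param groups `"control"` / `"patient"` per subject.
#' @param height_p two-sided edge-level height threshold (default 0.05).
#' @param n_perm number of label permutations (>= 100; default 1000).
#' @param seed integer seed for the permutations.
#' @param order optional ROI ordering; default [hierarchical_order()] of the
#'   input matrices.
#' @return An `spc_result`: `clusters` (list of edge set, mass, size,
#'   `p_unc`, `p_FDR`, `p_FWE`), `ordering`, `n_permutations`,
#'   `n_possible_clusters` (dendrogram-defined candidate blocks: unordered
#'   pairs, including self-pairs, of dendrogram nodes), `t_critical`, `df`.
#'   No suprathreshold edges yields an empty cluster list, not an error.
#' @export
spc_cluster_inference <- function(mats, groups, height_p = 0.05,
                                  n_perm = 1000L, seed = 1L, order = NULL) {
  if (n_perm < 100L) stop("need at least 100 permutations")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(order)) order <- hierarchical_order(mats)
  n <- nrow(mats[[1]]$z)
  em <- edge_matrix(mats)
  is_patient <- groups == "patient"
  df <- length(mats) - 2L
  tcrit <- stats::qt(1 - height_p / 2, df)

  idx <- attr(em, "edges")
  rank_of <- order(order)  # ROI -> position in the ordered matrix
  to_ordered_tmat <- function(tvec) {
    tm <- matrix(NA_real_, n, n)
    io <- rank_of[idx[, 1]]; jo <- rank_of[idx[, 2]]
    swap <- io > jo
    tmp <- io[swap]; io[swap] <- jo[swap]; jo[swap] <- tmp
    tm[cbind(io, jo)] <- tvec
    tm
  }

  observed_t <- edge_t_stats(em, is_patient)
  tm_obs <- to_ordered_tmat(observed_t)
  supra_obs <- !is.na(tm_obs) & abs(tm_obs) > tcrit
  obs <- cluster_masses(tm_obs, supra_obs)

  max_null <- numeric(n_perm)
  pooled_null <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(is_patient)
    tv <- edge_t_stats(em, perm)
    tmp <- to_ordered_tmat(tv)
    sup <- !is.na(tmp) & abs(tmp) > tcrit
    masses <- vapply(cluster_masses(tmp, sup), `[[`, numeric(1), "mass")
    max_null[b] <- if (length(masses)) max(masses) else 0
    pooled_null[[b]] <- masses
  }
  pooled <- unlist(pooled_null)

  clusters <- lapply(obs, function(cl) {
    # map ordered cells back to ROI index pairs
    edges <- cbind(order[cl$cells[, 1]], order[cl$cells[, 2]])
    edges <- t(apply(edges, 1L, sort))
    p_unc <- (1 + sum(pooled >= cl$mass)) / (1 + length(pooled))
    p_fwe <- (1 + sum(max_null >= cl$mass)) / (1 + n_perm)
    list(edges = edges, mass = cl$mass, size = cl$size,
         p_unc = p_unc, p_FWE = p_fwe)
  })
  if (length(clusters)) {
    p_fdr <- stats::p.adjust(vapply(clusters, `[[`, numeric(1), "p_unc"), "BH")
    for (i in seq_along(clusters)) clusters[[i]]$p_FDR <- p_fdr[i]
  }
  n_nodes <- 2L * n - 1L
  structure(list(clusters = clusters, ordering = as.integer(order),
                 n_permutations = as.integer(n_perm),
                 n_possible_clusters = n_nodes * (n_nodes + 1L) / 2L,
                 t_critical = tcrit, df = df,
                 roi_names = mats[[1]]$roi_names),
            class = "spc_result")
}

#' @export
print.spc_result <- function(x, ...) {
  cat(sprintf("SPC inference: %d cluster(s), %d permutations, |T| > %.3f (df = %d)\n",
              length(x$clusters), x$n_permutations, x$t_critical, x$df))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %d edge(s), mass = %.2f, p_unc = %.4f, p_FDR = %.4f, p_FWE = %.4f\n",
                i, cl$size, cl$mass, cl$p_unc, cl$p_FDR, cl$p_FWE))
  }
  invisible(x)
}

#' Bonferroni ROI reduction from SPC clusters
#'
#' Keeps clusters whose uncorrected p-value beats `alpha` divided by the
#' number of possible clusters, and returns the union of ROIs incident to
#' the surviving cluster edges.
#'
#' @param result an `spc_result` with `n_possible_clusters > 0`.
#' @param alpha family-wise level (default 0.05).
#' @return Integer vector of ROI indices (possibly empty).
#' @export
bonferroni_roi_reduction <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "spc_result"))
  if (result$n_possible_clusters <= 0) stop("n_possible_clusters must be positive")
  thr <- alpha / result$n_possible_clusters
  keep <- Filter(function(cl) cl$p_unc < thr, result$clusters)
  if (!length(keep)) return(integer(0))
  sort(unique(as.integer(unlist(lapply(keep, `[[`, "edges")))))
}
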