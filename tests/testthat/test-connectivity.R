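make_corr_ts <- function(t_len, n, rho_block = NULL, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(t_len * n), t_len, n)
  if (!is.null(rho_block)) {
    latent <- rnorm(t_len)
    for (i in rho_block$rois) {
      x[, i] <- sqrt(rho_block$rho) * latent + sqrt(1 - rho_block$rho) * x[, i]
    }
  }
  roi_timeseries(x, subject_id = sprintf("S%04.0f", seed))
}

test_that("Fisher-z connectivity is centered, calibrated, and clipped", {
  ts <- make_corr_ts(10000, 4, seed = 21)
  cm <- connectivity_matrix(ts)
  expect_true(all(is.na(diag(cm$z))))
  expect_equal(cm$z, t(cm$z))
  expect_lt(max(abs(cm$z), na.rm = TRUE), 0.05)

  # bivariate rho = 0.6: z within 3 / sqrt(T - 3) of atanh(0.6)
  set.seed(22)
  t_len <- 10000
  a <- rnorm(t_len); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(t_len)
  cm2 <- connectivity_matrix(roi_timeseries(cbind(a, b, rnorm(t_len))))
  expect_lt(abs(cm2$z[1, 2] - atanh(0.6)), 3 / sqrt(t_len - 3))

  # duplicated column: clipped to a finite cap rather than Inf
  dup <- roi_timeseries(cbind(a, a, b), roi_names = c("R1", "R2", "R3"))
  cm3 <- connectivity_matrix(dup)
  expect_true(is.finite(cm3$z[1, 2]))
  expect_equal(cm3$z[1, 2], atanh(1 - 1e-7))
  expect_error(connectivity_matrix(roi_timeseries(cbind(a, rep(1, t_len)))),
               "constant")
})

test_that("edge contrast gives pooled t with the study's degrees of freedom", {
  mats <- lapply(1:8, function(i) connectivity_matrix(make_corr_ts(60, 4, seed = 30 + i)))
  groups <- rep(c("control", "patient"), 4)
  # identical groups: same matrices relabeled -> t = 0 everywhere
  same <- edge_group_ttest(c(mats[1:4], mats[1:4]),
                           rep(c("control", "patient"), each = 4))
  expect_true(all(abs(same$t) < 1e-12, na.rm = TRUE))

  mats118 <- lapply(1:118, function(i) connectivity_matrix(make_corr_ts(40, 3, seed = 200 + i)))
  g118 <- rep(c("control", "patient"), c(63, 55))
  es <- edge_group_ttest(mats118, g118)
  expect_identical(es$df, 116L)

  # antisymmetry under contrast sign flip
  e1 <- edge_group_ttest(mats, groups, contrast = c(-1, 1))
  e2 <- edge_group_ttest(mats, groups, contrast = c(1, -1))
  expect_equal(e1$t, -e2$t)

  # planted lower patient connectivity on one edge dominates the contrast
  set.seed(31)
  lower <- lapply(1:40, function(i) {
    patient <- i > 20
    rho <- if (patient) 0 else 0.7
    connectivity_matrix(make_corr_ts(120, 4, rho_block = list(rois = 1:2, rho = rho),
                                     seed = 400 + i))
  })
  el <- edge_group_ttest(lower, rep(c("control", "patient"), each = 20))
  expect_equal(sort(arrayInd(which.min(el$t), dim(el$t))[1, ]), c(1L, 2L))
})

test_that("hierarchical ordering keeps correlated blocks contiguous and is optimal at N = 3", {
  mats <- lapply(1:10, function(i) {
    ts <- make_corr_ts(300, 6, rho_block = list(rois = c(1, 4, 6), rho = 0.8),
                       seed = 500 + i)
    connectivity_matrix(ts)
  })
  ord <- hierarchical_order(mats)
  pos <- match(c(1, 4, 6), ord)
  expect_equal(diff(range(pos)), 2)  # the correlated trio is contiguous

  # permuting the ROI order permutes the ordering consistently
  perm <- c(3L, 6L, 1L, 5L, 2L, 4L)
  mats_p <- lapply(mats, function(m) {
    structure(list(z = m$z[perm, perm], roi_names = m$roi_names[perm],
                   subject_id = m$subject_id), class = "connectivity_matrix")
  })
  ord_p <- hierarchical_order(mats_p)
  pos_p <- match(match(c(1, 4, 6), perm), ord_p)
  expect_equal(diff(range(pos_p)), 2)

  # small N: exhaustive check of the leaf-ordering objective over all orders
  # consistent with the dendrogram (every cluster's leaves stay contiguous)
  mats4 <- lapply(1:5, function(i) connectivity_matrix(make_corr_ts(100, 4, seed = 600 + i)))
  ord4 <- hierarchical_order(mats4)
  zbar <- Reduce(`+`, lapply(mats4, `[[`, "z")) / 5
  diag(zbar) <- 0
  d <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    keep <- setdiff(1:4, c(i, j))
    d[i, j] <- d[j, i] <- 1 - cor(zbar[i, keep], zbar[j, keep])
  }
  hc <- attr(ord4, "hclust")
  leaves_of <- function(v) if (v < 0) -v else
    c(leaves_of(hc$merge[v, 1]), leaves_of(hc$merge[v, 2]))
  node_leaves <- lapply(seq_len(nrow(hc$merge)), leaves_of)
  consistent <- function(o) all(vapply(node_leaves, function(lv) {
    diff(range(match(lv, o))) == length(lv) - 1
  }, logical(1)))
  cost <- function(o) sum(d[cbind(o[-4], o[-1])])
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  ok <- apply(perms, 1, consistent)
  best <- min(apply(perms[ok, , drop = FALSE], 1, cost))
  expect_equal(cost(as.integer(ord4)), best)
})

test_that("SPC finds planted clusters and returns valid structures", {
  set.seed(40)
  n_sub <- 40
  mats <- lapply(1:n_sub, function(i) {
    patient <- i > 20
    rho <- if (patient) 0.05 else 0.75
    connectivity_matrix(make_corr_ts(150, 8, rho_block = list(rois = 1:3, rho = rho),
                                     seed = 700 + i))
  })
  groups <- rep(c("control", "patient"), each = 20)
  res <- spc_cluster_inference(mats, groups, n_perm = 500, seed = 41)
  expect_gt(length(res$clusters), 0)
  masses <- vapply(res$clusters, `[[`, numeric(1), "mass")
  sizes <- vapply(res$clusters, `[[`, numeric(1), "size")
  expect_true(all(masses > 0))
  expect_equal(sizes, vapply(res$clusters, function(cl) nrow(cl$edges), numeric(1)))
  # clusters are non-overlapping edge sets
  all_edges <- do.call(rbind, lapply(res$clusters, `[[`, "edges"))
  expect_identical(anyDuplicated(all_edges), 0L)
  # all cluster edges are suprathreshold
  tmap <- edge_group_ttest(mats, groups)$t
  tvals <- tmap[all_edges]
  expect_true(all(abs(tvals) > res$t_critical))
  # the planted block is recovered with FWE control
  best <- res$clusters[[which.max(masses)]]
  expect_lt(best$p_FWE, 0.05)
  expect_true(all(sort(unique(as.vector(best$edges))) %in% 1:3) ||
                any(c(1, 2, 3) %in% best$edges))

  # a vanishing height threshold yields no clusters, not an error
  res0 <- spc_cluster_inference(mats, groups, height_p = 1e-300,
                                n_perm = 100, seed = 42)
  expect_length(res0$clusters, 0)
  expect_error(spc_cluster_inference(mats, groups, n_perm = 50), "100")
})

test_that("Bonferroni ROI reduction keeps ROIs of surviving clusters only", {
  fake <- structure(list(
    clusters = list(
      list(edges = rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4), c(1, 4)),
           mass = 50, size = 6, p_unc = 1e-6, p_FWE = 0.001, p_FDR = 0.002),
      list(edges = rbind(c(5, 6), c(5, 7), c(6, 7), c(6, 8), c(7, 8), c(5, 8)),
           mass = 40, size = 6, p_unc = 2e-6, p_FWE = 0.002, p_FDR = 0.002),
      list(edges = rbind(c(9, 10)), mass = 5, size = 1, p_unc = 0.2,
           p_FWE = 0.6, p_FDR = 0.3)),
    ordering = 1:10, n_permutations = 1000L, n_possible_clusters = 1159L,
    t_critical = 2, df = 116L, roi_names = paste0("R", 1:10)),
    class = "spc_result")
  # two surviving 6-edge clusters over disjoint ROI quadruples -> 8 ROIs
  expect_identical(bonferroni_roi_reduction(fake, alpha = 0.05), 1:8)
  loose <- fake; loose$n_possible_clusters <- 1L
  expect_identical(bonferroni_roi_reduction(loose, alpha = 1), 1:10)
  none <- fake; none$clusters[[1]]$p_unc <- 0.9
  none$clusters[[2]]$p_unc <- 0.9; none$clusters[[3]]$p_unc <- 0.9
  expect_identical(bonferroni_roi_reduction(none), integer(0))
})
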