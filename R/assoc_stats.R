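#' Two-group summary statistics
#'
#' @param mean1,sd1,n1 first-group mean, SD, size.
#' @param mean2,sd2,n2 second-group mean, SD, size.
#' @return A `group_summary` list.
#' @export
group_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  structure(list(mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2),
            class = "group_summary")
}

test_result <- function(statistic, df, p, kind) {
  structure(list(statistic = statistic, df = df, p = p, kind = kind),
            class = "assoc_test_result")
}

#' @export
print.assoc_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$kind, x$statistic, x$df, x$p))
  invisible(x)
}

#' Welch two-sample t-test from summary statistics
#'
#' `t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param summary a `group_summary`.
#' @return An `assoc_test_result` with `kind = "welch_t"`.
#' @export
welch_t <- function(summary) {
  stopifnot(inherits(summary, "group_summary"))
  with(summary, {
    if (sd1 == 0 && sd2 == 0) stop("both group SDs are zero")
    se2_1 <- sd1^2 / n1; se2_2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2_1 + se2_2)
    df <- (se2_1 + se2_2)^2 / (se2_1^2 / (n1 - 1) + se2_2^2 / (n2 - 1))
    test_result(t, df, 2 * stats::pt(-abs(t), df), "welch_t")
  })
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' @param summary a `group_summary`.
#' @return An `assoc_test_result` with `kind = "pooled_t"` and
#'   `df = n1 + n2 - 2`.
#' @export
pooled_t <- function(summary) {
  stopifnot(inherits(summary, "group_summary"))
  with(summary, {
    if (sd1 == 0 && sd2 == 0) stop("both group SDs are zero")
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    test_result(t, df, 2 * stats::pt(-abs(t), df), "pooled_t")
  })
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Computed without Yates continuity correction,
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param a,b first row counts (e.g. group 1: male, female).
#' @param c,d second row counts.
#' @return An `assoc_test_result` with `kind = "chi2"`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in the 2x2 table")
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  test_result(chi2, 1, stats::pchisq(chi2, 1, lower.tail = FALSE), "chi2")
}

#' Fisher z-transform of a correlation
#'
#' @param r correlation with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' Correlate paired-state frequencies with behavioral / connectivity covariates
#'
#' Pearson correlation (with two-sided p-value) of each paired-state
#' frequency column against each covariate column, overall and, when
#' `by_group = TRUE`, within each subject group.
#'
#' @param pair_freqs per-subject table from [paired_state_frequencies()]
#'   (`subject_id`, `group`, `pair_*` columns).
#' @param covariates per-subject table with `subject_id` and covariate
#'   columns; subjects must match `pair_freqs` (order may differ).
#' @param by_group also compute within-group correlations.
#' @return data.frame with `pair`, `covariate`, `group` (`"all"` or group
#'   name), `r`, `p`, `n`.
#' @export
correlate_pairs_with_covariates <- function(pair_freqs, covariates,
                                            by_group = FALSE) {
  if (!setequal(pair_freqs$subject_id, covariates$subject_id))
    stop("subject ids do not align between tables")
  cov <- covariates[match(pair_freqs$subject_id, covariates$subject_id), ,
                    drop = FALSE]
  pair_cols <- grep("^pair_", names(pair_freqs), value = TRUE)
  cov_cols <- setdiff(names(cov), c("subject_id", "group"))
  strata <- list(all = rep(TRUE, nrow(pair_freqs)))
  if (by_group) {
    for (g in unique(pair_freqs$group)) strata[[g]] <- pair_freqs$group == g
  }
  out <- NULL
  for (gname in names(strata)) {
    keep <- strata[[gname]]
    if (sum(keep) < 4L) stop("need at least 4 subjects per stratum")
    for (pc in pair_cols) for (cc in cov_cols) {
      y <- cov[[cc]][keep]
      x <- pair_freqs[[pc]][keep]
      if (stats::sd(y) == 0) stop("constant covariate: ", cc)
      ct <- suppressWarnings(stats::cor.test(x, y))
      out <- rbind(out, data.frame(pair = pc, covariate = cc, group = gname,
                                   r = unname(ct$estimate), p = ct$p.value,
                                   n = sum(keep)))
    }
  }
  out
}

#' Demographic and clinical comparisons from a summary table
#'
#' Recomputes two-group tests from printed summary statistics: pooled or
#' Welch t-tests for continuous variables, chi-square for 2x2 count
#' variables. The expected table has columns `variable`, `test`
#' (`pooled_t`/`welch_t`/`chi2`), and for continuous rows `mean1, sd1, n1,
#' mean2, sd2, n2`, for count rows `a, b, c, d`.
#'
#' @param table data.frame as described (see
#'   `system.file("extdata", "cohort_demographics.csv", package = "elscape")`
#'   for the bundled two-group schizophrenia-cohort table).
#' @return data.frame with `variable`, `kind`, `statistic`, `df`, `p`.
#' @export
demographic_tests <- function(table) {
  res <- lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    tr <- switch(as.character(row$test),
      pooled_t = pooled_t(group_summary(row$mean1, row$sd1, row$n1,
                                        row$mean2, row$sd2, row$n2)),
      welch_t = welch_t(group_summary(row$mean1, row$sd1, row$n1,
                                      row$mean2, row$sd2, row$n2)),
      chi2 = chi2_2x2(row$a, row$b, row$c, row$d),
      stop("unknown test kind: ", row$test))
    data.frame(variable = row$variable, kind = tr$kind,
               statistic = tr$statistic, df = tr$df, p = tr$p)
  })
  do.call(rbind, res)
}
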