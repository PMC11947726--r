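#' Bootstrapped permutation test of cluster proportions
#'
#' Tests, for every cluster, whether its share of cells differs between
#' two groups of cells (e.g. two breeds). The statistic is the log2 fold
#' difference of proportions `log2FD = log2(pA / pB)` with a 0.5-cell
#' pseudocount on empty cluster-by-group cells; the null distribution
#' comes from shuffling group labels `n_perm` times (add-one estimator, so
#' p-values are never exactly 0), confidence intervals from resampling
#' cells with replacement within each group, and p-values are BH-adjusted
#' across clusters. A cluster is flagged significant when
#' `FDR < fdr_max` and `|log2FD| > lfd_min` (published thresholds 0.05 and
#' 1.5).
#'
#' @param clusters Per-cell cluster labels.
#' @param groups Per-cell group labels.
#' @param pair Length-2 character vector `(groupA, groupB)`.
#' @param n_perm Label permutations (default 1000).
#' @param n_boot Bootstrap replicates for the CI (default 1000).
#' @param seed Integer seed.
#' @param fdr_max,lfd_min Significance thresholds.
#' @return `data.frame`, one row per cluster: proportions, `log2fd`
#'   (point estimate), `boot_mean`, percentile CI, permutation `p`,
#'   `fdr`, `significant`.
#' @export
proportion_permutation_test <- function(clusters, groups, pair,
                                        n_perm = 1000, n_boot = 1000,
                                        seed = 1L, fdr_max = 0.05,
                                        lfd_min = 1.5) {
  if (length(pair) != 2) stopf("pair must name two groups")
  if (!all(pair %in% groups)) stopf("pair labels absent from groups")
  keep <- groups %in% pair
  cl <- factor(as.character(clusters[keep]))
  grp <- as.character(groups[keep])
  in_a <- grp == pair[1]
  if (!any(in_a) || all(in_a)) stopf("a group has zero cells")
  lev <- levels(cl)
  ci <- as.integer(cl)
  nC <- length(lev)

  lfd <- function(a_mask) {
    ca <- tabulate(ci[a_mask], nC); cb <- tabulate(ci[!a_mask], nC)
    ca <- ca + 0.5 * (ca == 0); cb <- cb + 0.5 * (cb == 0)
    log2((ca / sum(ca)) / (cb / sum(cb)))
  }
  obs <- lfd(in_a)

  set.seed(seed)
  exceed <- integer(nC)
  for (p in seq_len(n_perm)) {
    perm <- sample(in_a)
    exceed <- exceed + (abs(lfd(perm)) >= abs(obs))
  }
  pval <- (1 + exceed) / (n_perm + 1)

  idx_a <- which(in_a); idx_b <- which(!in_a)
  boot <- matrix(NA_real_, n_boot, nC)
  for (bb in seq_len(n_boot)) {
    mask <- rep(FALSE, length(ci))
    ra <- sample(idx_a, length(idx_a), replace = TRUE)
    rb <- sample(idx_b, length(idx_b), replace = TRUE)
    ca <- tabulate(ci[ra], nC); cb <- tabulate(ci[rb], nC)
    ca <- ca + 0.5 * (ca == 0); cb <- cb + 0.5 * (cb == 0)
    boot[bb, ] <- log2((ca / sum(ca)) / (cb / sum(cb)))
  }
  ci_q <- apply(boot, 2, quantile, probs = c(0.025, 0.975))
  fdr <- bh_adjust(pval)
  data.frame(
    cluster = lev,
    prop_a = tabulate(ci[in_a], nC) / sum(in_a),
    prop_b = tabulate(ci[!in_a], nC) / sum(!in_a),
    log2fd = obs,
    boot_mean = colMeans(boot),
    ci_lo = ci_q[1, ], ci_hi = ci_q[2, ],
    p = pval, fdr = fdr,
    significant = fdr < fdr_max & abs(obs) > lfd_min,
    stringsAsFactors = FALSE)
}
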