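#' Gene-set module score with binned background controls
#'
#' The per-cell signal of a gene set relative to expression-matched
#' background: all genes are ranked by mean expression across cells and
#' partitioned into `n_bins` equal-size bins; each set gene draws
#' `n_ctrl` control genes from its own bin (without replacement, or with
#' replacement when the bin is smaller than `n_ctrl`); the score of a cell
#' is the mean expression of the set genes minus the mean over the pooled
#' control draws. Its expectation is 0 for an exchangeable gene set, and
#' adding a constant to all genes of one cell leaves that cell's score
#' unchanged.
#'
#' @param lognorm Log-normalized genes x cells matrix.
#' @param genes Gene-set symbols (missing genes warned and skipped).
#' @param n_bins Expression bins (default 25; must not exceed gene count).
#' @param n_ctrl Control genes per set gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return Numeric per-cell score vector (named by barcode) with
#'   attributes `genes_used` and `params`.
#' @export
module_score <- function(lognorm, genes, n_bins = 25, n_ctrl = 100,
                         seed = 1L) {
  use <- intersect(unique(genes), rownames(lognorm))
  if (!length(use)) stopf("no set gene present in the expression matrix")
  if (length(use) < length(unique(genes)))
    warnf("%d set genes absent and skipped",
          length(unique(genes)) - length(use))
  if (n_bins > nrow(lognorm)) stopf("n_bins exceeds the gene count")
  avg <- Matrix::rowMeans(lognorm)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(n_bins * rk / length(rk))
  set.seed(seed)
  ctrl_idx <- unlist(lapply(use, function(g) {
    pool <- which(bin == bin[match(g, rownames(lognorm))])
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  set_score <- Matrix::colMeans(lognorm[use, , drop = FALSE])
  ctrl_score <- Matrix::colMeans(lognorm[ctrl_idx, , drop = FALSE])
  out <- as.numeric(set_score - ctrl_score)
  names(out) <- colnames(lognorm)
  attr(out, "genes_used") <- use
  attr(out, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  out
}

#' Dot-plot statistics for marker panels
#'
#' Per group and gene: mean log-normalized expression and the fraction of
#' cells with nonzero expression.
#'
#' @param lognorm Log-normalized genes x cells matrix.
#' @param labels Per-cell group labels.
#' @param panels Named list of gene sets, or a single character vector.
#' @return Long `data.frame`: `panel`, `gene`, `group`, `mean_expr`,
#'   `frac_expr`.
#' @export
marker_panel_stats <- function(lognorm, labels, panels) {
  if (!is.list(panels)) panels <- list(panel = panels)
  labels <- as.factor(labels)
  rows <- list()
  for (pn in names(panels)) {
    use <- intersect(panels[[pn]], rownames(lognorm))
    miss <- setdiff(panels[[pn]], use)
    if (length(miss))
      warnf("panel '%s': unknown genes skipped: %s", pn,
            paste(miss, collapse = ", "))
    if (!length(use)) next
    for (g in levels(labels)) {
      sub <- lognorm[use, labels == g, drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        panel = pn, gene = use, group = g,
        mean_expr = as.numeric(Matrix::rowMeans(sub)),
        frac_expr = as.numeric(Matrix::rowMeans(sub > 0)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sarle's bimodality coefficient
#'
#' `(skewness^2 + 1) / (kurtosis + 3 (n-1)^2 / ((n-2)(n-3)))`; values near
#' the uniform benchmark 5/9 and above indicate bimodality. Used to check
#' that score distributions mixing two planted levels register as more
#' bimodal than a single level.
#'
#' @param x Numeric vector, length >= 4.
#' @return Coefficient in (0, 1].
#' @export
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4) stopf("need at least 4 values")
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  g1 <- mean((x - m)^3) / s^3 * sqrt(n * (n - 1)) / (n - 2)
  g2 <- ((n + 1) * (mean((x - m)^4) / s^4 - 3) + 6) *
    (n - 1) / ((n - 2) * (n - 3))
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}
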