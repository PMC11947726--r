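#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure with
#' monotonicity enforcement, capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum differential expression
#'
#' Per gene: two-sided Mann-Whitney test of group A versus group B on
#' log-normalized expression, BH adjustment across genes, and
#' `log2FC = log2((mean(expm1 A) + eps) / (mean(expm1 B) + eps))`. By
#' default the p-value uses the tie-corrected normal approximation; with
#' `exact = TRUE` tie-free genes use the exact rank-sum distribution
#' (small groups only). A gene is flagged `deg` when `padj < alpha` and
#' `|log2FC| > lfc_min` (published thresholds 0.05 and 1.5).
#'
#' @param lognorm Log-normalized genes x cells matrix.
#' @param cells_a,cells_b Column indices, barcodes or logical masks of the
#'   two groups (>= 2 cells each).
#' @param lfc_min,alpha DEG thresholds.
#' @param exact Use the exact null distribution where there are no ties.
#' @param eps Pseudo-expression guard in the fold change (default 1e-9).
#' @return `data.frame`, one row per gene: `gene`, `log2fc`, `stat`
#'   (Mann-Whitney U of group A), `p`, `padj`, `direction`, `deg`.
#' @export
wilcoxon_deg <- function(lognorm, cells_a, cells_b, lfc_min = 1.5,
                         alpha = 0.05, exact = FALSE, eps = 1e-9) {
  resolve <- function(idx) {
    if (is.character(idx)) idx <- match(idx, colnames(lognorm))
    if (is.logical(idx)) idx <- which(idx)
    idx
  }
  a <- resolve(cells_a); b <- resolve(cells_b)
  if (length(a) < 1 || length(b) < 1) stopf("empty group")
  if (length(a) < 2 || length(b) < 2) stopf("both groups need >= 2 cells")
  nA <- length(a); nB <- length(b); n <- nA + nB
  X <- as.matrix(lognorm[, c(a, b), drop = FALSE])
  ranks <- matrixStats::rowRanks(X, ties.method = "average")
  RA <- rowSums(ranks[, seq_len(nA), drop = FALSE])
  U <- RA - nA * (nA + 1) / 2
  tie_term <- apply(X, 1, function(v) {
    t <- rle(sort(v))$lengths
    sum(t^3 - t)
  })
  v <- nA * nB / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- U - nA * nB / 2
  p <- ifelse(v > 0, 2 * pnorm(-abs(z) / sqrt(v)), 1)
  if (exact) {
    no_tie <- tie_term == 0
    if (any(no_tie)) {
      u <- U[no_tie]
      lo <- pwilcox(u, nA, nB)
      hi <- pwilcox(u - 1, nA, nB, lower.tail = FALSE)
      p[no_tie] <- pmin(1, 2 * pmin(lo, hi))
    }
    if (any(!no_tie))
      warnf("%d genes have ties; normal approximation used there",
            sum(!no_tie))
  }
  mean_a <- rowMeans(expm1(X[, seq_len(nA), drop = FALSE]))
  mean_b <- rowMeans(expm1(X[, nA + seq_len(nB), drop = FALSE]))
  log2fc <- log2((mean_a + eps) / (mean_b + eps))
  padj <- bh_adjust(p)
  data.frame(
    gene = rownames(X) %||% seq_len(nrow(X)),
    log2fc = log2fc, stat = U, p = p, padj = padj,
    direction = ifelse(log2fc > 0, "up", "down"),
    deg = padj < alpha & abs(log2fc) > lfc_min,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value of the overlap between a gene list
#' and each gene set, all restricted to a gene universe, BH-adjusted
#' across sets.
#'
#' @param gene_list Character vector of hit genes (must lie in
#'   `universe`).
#' @param gene_sets Named list of gene sets (intersected with the
#'   universe).
#' @param universe Character vector of assayed genes.
#' @param alpha Significance level on the adjusted p-value.
#' @return `data.frame`, one row per set: overlap and size counts, `p`,
#'   `padj`, `significant`.
#' @export
hypergeom_enrich <- function(gene_list, gene_sets, universe, alpha = 0.05) {
  if (!length(universe)) stopf("empty universe")
  if (!length(gene_list)) stopf("empty gene list")
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe))
    stopf("gene_list contains genes outside the universe")
  N <- length(universe); nl <- length(gene_list)
  rows <- lapply(names(gene_sets), function(sn) {
    set <- intersect(unique(gene_sets[[sn]]), universe)
    k <- length(intersect(set, gene_list))
    K <- length(set)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, nl, lower.tail = FALSE)
    data.frame(set = sn, overlap = k, set_size = K, list_size = nl,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out$significant <- out$padj < alpha
  out
}
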