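# Highly variable gene selection: dispersion (var/mean) of log-normalized
# expression, z-scored within equal-size mean-expression bins.
select_hvg <- function(lognorm, n_hvg, n_bins = 20, warn = TRUE) {
  mu <- Matrix::rowMeans(lognorm)
  ex2 <- Matrix::rowMeans(lognorm^2)
  v <- pmax(ex2 - mu^2, 0) * ncol(lognorm) / max(1, ncol(lognorm) - 1)
  ok <- mu > 0 & v > 0
  if (!any(ok)) stopf("no variable genes")
  disp <- v[ok] / mu[ok]
  rk <- rank(mu[ok], ties.method = "first")
  bin <- ceiling(n_bins * rk / length(rk))
  z <- disp
  for (b in unique(bin)) {
    sel <- bin == b
    s <- sd(disp[sel])
    z[sel] <- (disp[sel] - mean(disp[sel])) / (if (is.na(s) || s == 0) 1 else s)
  }
  if (n_hvg > sum(ok)) {
    if (warn) warnf("n_hvg = %d exceeds %d variable genes; clamped",
                    n_hvg, sum(ok))
    n_hvg <- sum(ok)
  }
  names(sort(z, decreasing = TRUE))[seq_len(n_hvg)]
}

#' Normalize, select variable genes and embed cells
#'
#' Depth-normalizes each cell to `target_sum`, log1p-transforms, selects
#' the `n_hvg` most variable genes (binned-dispersion criterion), z-scales
#' them (capped at 10) and computes a truncated PCA. Returns both the full
#' log-normalized matrix (for scoring and differential expression) and the
#' PCA embedding of the variable genes.
#'
#' @param x A [count_matrix()].
#' @param n_hvg Number of highly variable genes (clamped with a warning if
#'   it exceeds the number of variable genes).
#' @param n_pcs Number of principal components.
#' @param target_sum Per-cell total after depth normalization.
#' @param center_by Optional per-cell factor (e.g. library); the embedding
#'   is mean-centered within its levels, a light-weight alternative to
#'   batch integration for multi-library input.
#' @param seed Integer seed (truncated SVD initialization).
#' @return List of class `preprocessed` with `lognorm`, `hvg`,
#'   `embedding` (cells x PCs) and `params`.
#' @export
preprocess <- function(x, n_hvg = 2000, n_pcs = 50, target_sum = 1e4,
                       center_by = NULL, seed = 1L) {
  lognorm <- lognormalize(x$counts, target_sum)
  hvg <- select_hvg(lognorm, n_hvg)
  scaled <- pmin(row_zscore(as.matrix(lognorm[hvg, , drop = FALSE])), 10)
  n_pcs <- min(n_pcs, length(hvg) - 1L, ncol(lognorm) - 1L)
  set.seed(seed)
  sv <- irlba::irlba(t(scaled), nv = n_pcs)
  emb <- sv$u %*% diag(sv$d, n_pcs)
  rownames(emb) <- colnames(lognorm)
  if (!is.null(center_by)) {
    center_by <- as.factor(center_by)
    for (lv in levels(center_by)) {
      sel <- center_by == lv
      emb[sel, ] <- sweep(emb[sel, , drop = FALSE], 2,
                          colMeans(emb[sel, , drop = FALSE]))
    }
  }
  structure(list(lognorm = lognorm, hvg = hvg, embedding = emb,
                 params = list(n_hvg = n_hvg, n_pcs = n_pcs,
                               target_sum = target_sum, seed = seed)),
            class = "preprocessed")
}

#' Leiden clustering on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph on the embedding, weights edges by
#' the Jaccard overlap of neighborhoods (pruned below 1/15), and
#' partitions it with Leiden modularity optimization at the given
#' resolution. Deterministic given `seed`.
#'
#' @param embedding Cells x dimensions matrix (e.g. from [preprocess()]).
#' @param k Neighbor count.
#' @param resolution Leiden resolution (the study sweeps 0.5-2).
#' @param seed Integer seed.
#' @return List of class `clustering` with `cluster` (factor, labels
#'   ordered by decreasing size), `k`, `resolution`.
#' @export
cluster_cells <- function(embedding, k = 15, resolution = 1, seed = 1L) {
  n <- nrow(embedding)
  if (k >= n) stopf("k = %d must be smaller than the %d cells", k, n)
  nn <- BiocNeighbors::findKNN(embedding, k = k)
  # neighbor sets include the cell itself
  B <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), k + 1L),
    j = c(as.vector(nn$index), seq_len(n)),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(B)
  w <- shared
  w@x <- w@x / (2 * (k + 1) - w@x)   # Jaccard: |A&B| / |A|B|
  w@x[w@x < 1 / 15] <- 0
  w <- Matrix::drop0(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  cluster <- factor(relab[as.character(memb)], levels = seq_along(sizes))
  names(cluster) <- rownames(embedding)
  structure(list(cluster = cluster, k = k, resolution = resolution),
            class = "clustering")
}

#' Label clusters with a marker panel
#'
#' For every cluster, computes each panel label's score as the mean of
#' z-scored log-normalized marker expression over the cluster's cells and
#' assigns the argmax label; ties break by panel order; cells inherit
#' their cluster's label. Applied once with the major-lineage panel on all
#' cells, then again with the T/ILC/NK subtype panel within T/ILC/NK cells.
#'
#' @param lognorm Log-normalized genes x cells matrix.
#' @param clusters Per-cell cluster factor (or a `clustering` object).
#' @param panel Named list label -> marker gene symbols, e.g.
#'   [lineage_markers()].
#' @return Character vector of per-cell labels with attributes
#'   `cluster_labels` and `cluster_scores`.
#' @export
annotate_clusters <- function(lognorm, clusters, panel = lineage_markers()) {
  if (inherits(clusters, "clustering")) clusters <- clusters$cluster
  clusters <- as.factor(clusters)
  genes <- unique(unlist(panel, use.names = FALSE))
  present <- intersect(genes, rownames(lognorm))
  if (!length(present)) stopf("no panel gene present in the expression matrix")
  missing <- setdiff(genes, present)
  if (length(missing))
    warnf("panel genes absent and skipped: %s", paste(missing, collapse = ", "))
  z <- row_zscore(as.matrix(lognorm[present, , drop = FALSE]))
  cl_mean <- vapply(levels(clusters), function(cl)
    rowMeans(z[, clusters == cl, drop = FALSE]), numeric(length(present)))
  cl_mean <- matrix(cl_mean, nrow = length(present),
                    dimnames = list(present, levels(clusters)))
  usable <- Filter(function(l) length(intersect(panel[[l]], present)) > 0,
                   names(panel))
  if (!length(usable)) stopf("no panel gene present in the expression matrix")
  scores <- vapply(usable, function(l) {
    g <- intersect(panel[[l]], present)
    colMeans(cl_mean[g, , drop = FALSE])
  }, numeric(nlevels(clusters)))
  scores <- matrix(scores, nrow = nlevels(clusters),
                   dimnames = list(levels(clusters), usable))
  cl_label <- usable[apply(scores, 1, which.max)]
  names(cl_label) <- levels(clusters)
  out <- cl_label[as.character(clusters)]
  names(out) <- names(clusters)
  attr(out, "cluster_labels") <- cl_label
  attr(out, "cluster_scores") <- scores
  out
}

#' Cell-cycle scores and phase calls
#'
#' S and G2/M program scores via the binned-control [module_score()]; a
#' cell with both scores at or below zero is called G1, otherwise the
#' larger score decides.
#'
#' @param lognorm Log-normalized genes x cells matrix.
#' @param s_genes,g2m_genes Phase gene sets (defaults:
#'   [cell_cycle_genes()]).
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return `data.frame` with `barcode`, `s_score`, `g2m_score`, `phase`.
#' @export
cell_cycle_phase <- function(lognorm, s_genes = NULL, g2m_genes = NULL,
                             n_bins = 25, n_ctrl = 100, seed = 1L) {
  cc <- cell_cycle_genes()
  s_genes <- s_genes %||% cc$s
  g2m_genes <- g2m_genes %||% cc$g2m
  s_in <- intersect(s_genes, rownames(lognorm))
  g_in <- intersect(g2m_genes, rownames(lognorm))
  if (!length(s_in) && !length(g_in))
    stopf("no S or G2M gene present in the expression matrix")
  if (!length(s_in) || !length(g_in))
    stopf("one phase gene set is entirely absent")
  s <- module_score(lognorm, s_in, n_bins = n_bins, n_ctrl = n_ctrl,
                    seed = seed)
  g <- module_score(lognorm, g_in, n_bins = n_bins, n_ctrl = n_ctrl,
                    seed = seed + 1L)
  phase <- ifelse(s <= 0 & g <= 0, "G1", ifelse(s > g, "S", "G2M"))
  data.frame(barcode = colnames(lognorm) %||% seq_along(s),
             s_score = as.numeric(s), g2m_score = as.numeric(g),
             phase = phase, stringsAsFactors = FALSE)
}

#' Residualize expression on covariates
#'
#' Per-gene least-squares regression of expression on the given covariates
#' (with intercept); returns the residual matrix. Used to regress
#' cell-cycle scores out of expression before downstream embedding.
#'
#' @param expression Genes x cells matrix.
#' @param covariates Cells x p matrix or data.frame.
#' @return Dense residual matrix, same dimensions and dimnames.
#' @export
regress_out <- function(expression, covariates) {
  Y <- as.matrix(expression)
  X <- cbind(1, as.matrix(covariates))
  XtXi <- solve(crossprod(X))
  coef <- (Y %*% X) %*% XtXi
  Y - coef %*% t(X)
}

#' Cross-group cell-type dendrogram
#'
#' Average-linkage hierarchical clustering of per-(breed, cell type) mean
#' expression profiles under correlation distance (1 - Pearson),
#' serialized as a Newick string.
#'
#' @param lognorm Log-normalized genes x cells matrix.
#' @param groups Per-cell group factor (e.g. `breed:celltype`).
#' @param genes Optional gene subset (e.g. variable genes).
#' @return Newick string with attribute `hclust`.
#' @export
celltype_dendrogram <- function(lognorm, groups, genes = NULL) {
  groups <- as.factor(groups)
  empty <- levels(groups)[!levels(groups) %in% unique(groups)]
  if (length(empty)) {
    warnf("dropping empty groups: %s", paste(empty, collapse = ", "))
    groups <- droplevels(groups)
  }
  if (nlevels(groups) < 2) stopf("need at least 2 non-empty groups")
  if (!is.null(genes)) lognorm <- lognorm[genes, , drop = FALSE]
  prof <- vapply(levels(groups), function(g)
    Matrix::rowMeans(lognorm[, groups == g, drop = FALSE]),
    numeric(nrow(lognorm)))
  d <- as.dist(1 - cor(prof))
  hc <- hclust(d, method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  attr(nwk, "hclust") <- hc
  nwk
}
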