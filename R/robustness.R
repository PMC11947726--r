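#' Subsample cells per group
#'
#' Uniform without-replacement sample of `n` cells from every group
#' (counts untouched); the published robustness check uses n = 2000 per
#' breed.
#'
#' @param x A [count_matrix()].
#' @param n Cells to keep per group.
#' @param groups Per-cell group labels (default: the library column).
#' @param seed Integer seed.
#' @return A `cell_counts` with `n` cells per group.
#' @export
subsample_cells <- function(x, n = 2000, groups = NULL, seed = 1L) {
  groups <- groups %||% x$cells$library
  set.seed(seed)
  idx <- unlist(lapply(unique(groups), function(g) {
    gi <- which(groups == g)
    if (n > length(gi)) stopf("group %s has only %d cells (< n = %d)",
                              g, length(gi), n)
    sample(gi, n)
  }))
  subset_cells(x, sort(idx))
}

#' Downsample counts per cell to a fixed depth
#'
#' Every cell whose total exceeds `counts_per_cell` is thinned to exactly
#' that total by a multivariate hypergeometric draw (uniform sampling of
#' retained reads without replacement); cells at or below the target are
#' unchanged. The published depth targets are 8172 (mean) and 6300
#' (median of the deeper libraries).
#'
#' @param x A [count_matrix()].
#' @param counts_per_cell Target total per cell (>= 1).
#' @param seed Integer seed.
#' @return A `cell_counts` with per-cell totals at most `counts_per_cell`.
#' @export
downsample_counts <- function(x, counts_per_cell, seed = 1L) {
  if (counts_per_cell < 1) stopf("counts_per_cell must be >= 1")
  set.seed(seed)
  m <- x$counts
  totals <- Matrix::colSums(m)
  p <- m@p; iv <- m@i; xv <- m@x
  new_x <- xv
  for (cell in which(totals > counts_per_cell)) {
    lo <- p[cell] + 1L; hi <- p[cell + 1L]
    v <- xv[lo:hi]
    cum <- cumsum(v)
    pos <- sample.int(totals[cell], counts_per_cell)
    sel <- findInterval(pos - 0.5, cum) + 1L
    new_x[lo:hi] <- tabulate(sel, nbins = length(v))
  }
  m@x <- new_x
  count_matrix(Matrix::drop0(m), x$features, x$cells)
}

#' Pseudobulk Pearson agreement between two matrices
#'
#' Sums counts over the cells of every group into a pseudobulk vector,
#' CPM-normalizes and log1p-transforms, and reports the Pearson
#' correlation between the original and downsampled vectors per group
#' (the raw-sum correlation is reported alongside).
#'
#' @param original,downsampled [count_matrix()] objects over the same gene
#'   universe.
#' @param groups_original,groups_downsampled Per-cell group labels
#'   (default: the library column). Every group must appear in both.
#' @return `data.frame` with `group`, `r` (log-CPM) and `r_raw`.
#' @export
pseudobulk_correlation <- function(original, downsampled,
                                   groups_original = NULL,
                                   groups_downsampled = NULL) {
  go <- groups_original %||% original$cells$library
  gd <- groups_downsampled %||% downsampled$cells$library
  if (!identical(rownames(original$counts), rownames(downsampled$counts)))
    stopf("gene universes differ")
  groups <- unique(go)
  if (!all(groups %in% gd)) stopf("group absent from the downsampled matrix")
  logcpm <- function(v) log1p(v / sum(v) * 1e6)
  rows <- lapply(groups, function(g) {
    a <- Matrix::rowSums(original$counts[, go == g, drop = FALSE])
    b <- Matrix::rowSums(downsampled$counts[, gd == g, drop = FALSE])
    data.frame(group = g, r = pearson(logcpm(a), logcpm(b)),
               r_raw = pearson(a, b), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replicated downsampling robustness report
#'
#' Repeats cell-number or depth downsampling `n_rep` times (the study uses
#' 5) and reports the per-group pseudobulk Pearson correlation with the
#' original matrix for every replicate.
#'
#' @param x A [count_matrix()].
#' @param mode `"cells"` (subsample to `target` cells per group) or
#'   `"depth"` (thin every cell to `target` counts).
#' @param target Cells per group or counts per cell.
#' @param n_rep Number of replicates (default 5).
#' @param seed Integer seed; replicate `i` uses `seed + i`.
#' @return `data.frame` with `mode`, `target`, `rep`, `group`, `r`,
#'   `r_raw`.
#' @export
downsample_report <- function(x, mode = c("cells", "depth"), target,
                              n_rep = 5, seed = 1L) {
  mode <- match.arg(mode)
  rows <- lapply(seq_len(n_rep), function(i) {
    ds <- if (mode == "cells") subsample_cells(x, n = target, seed = seed + i)
          else downsample_counts(x, target, seed = seed + i)
    out <- pseudobulk_correlation(x, ds)
    cbind(mode = mode, target = target, rep = i, out)
  })
  do.call(rbind, rows)
}
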