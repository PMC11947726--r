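#' @importFrom Matrix colSums rowSums rowMeans t sparseMatrix Diagonal drop0
#' @importFrom methods as is
#' @importFrom stats rnbinom rlnorm rnorm runif quantile cor sd var hclust
#'   as.dist dist pnorm pwilcox phyper p.adjust setNames
#' @importFrom utils head read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi))
    stopf("`%s` must be numeric in [%g, %g]", name, lo, hi)
  invisible(x)
}

#' Depth-normalize and log-transform a count matrix
#'
#' Scales every cell (column) to a common target sum and applies `log1p`,
#' the standard library-size normalization for UMI counts. Sparsity is
#' preserved.
#'
#' @param counts Sparse or dense genes x cells count matrix.
#' @param target_sum Per-cell total after scaling (default 1e4).
#' @return A `dgCMatrix` of log-normalized expression, same dimnames.
#' @export
lognormalize <- function(counts, target_sum = 1e4) {
  m <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  scal <- target_sum / cs
  # scale the nonzeros column-wise without densifying
  j <- rep.int(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * scal[j])
  m
}

# column-index vector of a dgCMatrix's nonzeros
col_index <- function(m) rep.int(seq_len(ncol(m)), diff(m@p))

# dense row z-score with guard for zero-variance rows (they become 0)
row_zscore <- function(x) {
  mu <- rowMeans(x)
  s <- matrixStats::rowSds(x)
  s[s == 0] <- 1
  (x - mu) / s
}

# Pearson correlation between two numeric vectors, NA-safe
pearson <- function(a, b) suppressWarnings(stats::cor(a, b, method = "pearson"))
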