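#' Sparse count-matrix container
#'
#' Bundles a sparse genes x cells matrix of raw UMI counts with its feature
#' table (gene id, symbol, mitochondrial flag) and cell table (barcode,
#' library label). Rows of `counts` are named by gene symbol and columns by
#' barcode.
#'
#' @param counts Genes x cells matrix of non-negative integer counts
#'   (coerced to `dgCMatrix`).
#' @param features `data.frame` with columns `gene_id`, `symbol` and logical
#'   `mito`; one row per gene.
#' @param cells `data.frame` with columns `barcode` and `library`; one row
#'   per cell.
#' @return An object of class `cell_counts`.
#' @export
count_matrix <- function(counts, features, cells) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != nrow(features))
    stopf("dimension mismatch: %d matrix rows vs %d feature rows",
          nrow(counts), nrow(features))
  if (ncol(counts) != nrow(cells))
    stopf("dimension mismatch: %d matrix columns vs %d barcode rows",
          ncol(counts), nrow(cells))
  if (length(counts@x) && any(counts@x %% 1 != 0))
    stopf("counts must be integers")
  if (length(counts@x) && any(counts@x < 0))
    stopf("counts must be non-negative")
  if (is.null(features$mito))
    features$mito <- grepl("^MT-", features$symbol)
  rownames(counts) <- make.unique(as.character(features$symbol))
  colnames(counts) <- as.character(cells$barcode)
  structure(list(counts = counts, features = features, cells = cells),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d genes x %d cells, %d nonzeros\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  libs <- table(x$cells$library)
  cat("libraries:", paste(sprintf("%s=%d", names(libs), libs), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' Subset cells of a count matrix
#'
#' @param x A [count_matrix()] object.
#' @param idx Integer, logical or barcode index of cells to keep.
#' @return A `cell_counts` with the selected cells, gene table untouched.
#' @export
subset_cells <- function(x, idx) {
  if (is.character(idx)) idx <- match(idx, x$cells$barcode)
  count_matrix(x$counts[, idx, drop = FALSE], x$features,
               x$cells[idx, , drop = FALSE])
}
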