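#' Read / write 10x-style MatrixMarket triplets
#'
#' `write_mtx()` writes `matrix.mtx` (1-based coordinates), `features.tsv`
#' (gene id, symbol) and `barcodes.tsv` (barcode, library) into a
#' directory. `read_mtx()` reads such a triplet back (gzipped variants are
#' accepted), flags genes matching `mito_pattern` as mitochondrial and
#' validates that counts are integers and dimensions agree with the
#' tables. The round trip is lossless.
#'
#' @param x A [count_matrix()].
#' @param dir Directory path.
#' @param mito_pattern Regex on gene symbols marking mitochondrial genes.
#' @return `read_mtx()` returns a `cell_counts`; `write_mtx()` returns
#'   `dir` invisibly.
#' @export
write_mtx <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write.table(x$features[c("gene_id", "symbol")],
              file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(x$cells[c("barcode", "library")],
              file.path(dir, "barcodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

find_triplet_file <- function(dir, base) {
  for (f in file.path(dir, c(base, paste0(base, ".gz"))))
    if (file.exists(f)) return(f)
  stopf("missing %s(.gz) in %s", base, dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir, mito_pattern = "^MT-") {
  m <- Matrix::readMM(find_triplet_file(dir, "matrix.mtx"))
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  if (length(m@x) && any(m@x %% 1 != 0))
    stopf("non-integer counts in matrix.mtx")
  feats <- read.table(find_triplet_file(dir, "features.tsv"), sep = "\t",
                      header = FALSE, stringsAsFactors = FALSE)
  bcs <- read.table(find_triplet_file(dir, "barcodes.tsv"), sep = "\t",
                    header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m))
    stopf("dimension mismatch: %d features rows vs %d matrix rows",
          nrow(feats), nrow(m))
  if (nrow(bcs) != ncol(m))
    stopf("dimension mismatch: %d barcodes rows vs %d matrix columns",
          nrow(bcs), ncol(m))
  features <- data.frame(gene_id = feats[[1]],
                         symbol = if (ncol(feats) >= 2) feats[[2]] else feats[[1]],
                         stringsAsFactors = FALSE)
  features$mito <- grepl(mito_pattern, features$symbol)
  cells <- data.frame(barcode = bcs[[1]],
                      library = if (ncol(bcs) >= 2) bcs[[2]] else NA_character_,
                      stringsAsFactors = FALSE)
  count_matrix(m, features, cells)
}

#' Simulated-doublet score
#'
#' Scores every cell for doublet likeness: `n_sim` artificial doublets are
#' formed by summing random cell pairs, observed and simulated cells are
#' co-embedded in PCA space of log-normalized expression, and each
#' observed cell is scored from the fraction of simulated doublets among
#' its nearest neighbors, converted to a posterior with a doublet prior so
#' that singlets of a homogeneous population score near `prior` rather
#' than near the raw simulated fraction.
#'
#' @param x A [count_matrix()].
#' @param k Neighbor count on the observed scale; default
#'   `round(0.5 * sqrt(n))`. The combined-space neighborhood is
#'   `round(k * (1 + n_sim / n))`.
#' @param n_sim Number of simulated doublets (default: one per observed
#'   cell).
#' @param prior Expected doublet rate used in the posterior (default 0.1).
#' @param n_hvg,n_pcs Highly variable genes and principal components of
#'   the co-embedding.
#' @param seed Integer seed.
#' @return Numeric vector of scores in [0, 1], named by barcode.
#' @export
doublet_score <- function(x, k = NULL, n_sim = NULL, prior = 0.1,
                          n_hvg = 1000, n_pcs = 30, seed = 1L) {
  counts <- x$counts
  n <- ncol(counts)
  if (any(Matrix::colSums(counts) == 0))
    stopf("degenerate matrix: all-zero cells present")
  k <- k %||% max(3L, round(0.5 * sqrt(n)))
  if (2 * k > n) stopf("k = %d too large for %d cells", k, n)
  n_sim <- n_sim %||% n
  r <- n_sim / n
  set.seed(seed)
  i <- sample.int(n, n_sim, replace = TRUE)
  j <- sample.int(n, n_sim, replace = TRUE)
  while (any(i == j)) {
    eq <- i == j
    j[eq] <- sample.int(n, sum(eq), replace = TRUE)
  }
  sim <- counts[, i, drop = FALSE] + counts[, j, drop = FALSE]
  colnames(sim) <- sprintf("SIM_%06d", seq_len(n_sim))
  comb <- lognormalize(cbind(counts, sim))
  hvg <- select_hvg(comb, n_hvg, warn = FALSE)
  scaled <- pmin(row_zscore(as.matrix(comb[hvg, , drop = FALSE])), 10)
  n_pcs <- min(n_pcs, length(hvg) - 1L, ncol(comb) - 1L)
  sv <- irlba::irlba(t(scaled), nv = n_pcs)
  emb <- sv$u %*% diag(sv$d, n_pcs)
  k_use <- max(3L, round(k * (1 + r)))
  nn <- BiocNeighbors::findKNN(emb, k = k_use)
  s <- rowSums(nn$index[seq_len(n), , drop = FALSE] > n)
  score <- prior * (s / r) / (prior * (s / r) + (1 - prior) * (k_use - s))
  setNames(score, colnames(counts))
}

#' Cell-level QC thresholds
#'
#' Defaults follow the published filtering: remove doublet-like cells at
#' score cutoff 0.25 (direction `"high"`: scores at or above the cutoff
#' are removed; the printed phrase "below 0.25" is read as a typo for the
#' conventional direction, and `direction = "low"` restores the literal
#' reading), cells with mitochondrial read fraction above 0.50, and cells
#' with fewer than 200 or more than 7,500 detected genes (boundaries
#' survive).
#'
#' @param doublet_cutoff Doublet-score cutoff in [0, 1].
#' @param mito_max Maximum mitochondrial fraction in [0, 1].
#' @param min_genes,max_genes Detected-gene bounds (strict inequalities).
#' @param direction Which side of `doublet_cutoff` is removed.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(doublet_cutoff = 0.25, mito_max = 0.5,
                          min_genes = 200, max_genes = 7500,
                          direction = c("high", "low")) {
  direction <- match.arg(direction)
  assert_prob(doublet_cutoff, "doublet_cutoff")
  assert_prob(mito_max, "mito_max")
  if (min_genes >= max_genes) stopf("min_genes must be < max_genes")
  structure(list(doublet_cutoff = doublet_cutoff, mito_max = mito_max,
                 min_genes = min_genes, max_genes = max_genes,
                 direction = direction), class = "qc_thresholds")
}

#' Apply cell-level quality filters
#'
#' Removes cells in the fixed order doublet score, mitochondrial
#' fraction, detected-gene bounds; a cell failing several filters is
#' attributed to the first. Survivors keep their raw counts.
#'
#' @param x A [count_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @param scores Optional per-cell doublet scores aligned to `x` (the
#'   doublet filter is skipped when `NULL`).
#' @return List with `matrix` (survivors) and `report` (per-cell metrics,
#'   per-filter removal counts, survivor count; the accounting always
#'   balances).
#' @export
qc_filter <- function(x, thresholds = qc_thresholds(), scores = NULL) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n <- ncol(x$counts)
  if (!is.null(scores) && length(scores) != n)
    stopf("scores not aligned to cells (%d vs %d)", length(scores), n)
  total <- Matrix::colSums(x$counts)
  genes <- Matrix::colSums(x$counts > 0)
  mito_frac <- if (any(x$features$mito)) {
    Matrix::colSums(x$counts[x$features$mito, , drop = FALSE]) / pmax(total, 1)
  } else rep(0, n)

  fail_doublet <- if (is.null(scores)) rep(FALSE, n) else {
    if (thresholds$direction == "high") scores >= thresholds$doublet_cutoff
    else scores < thresholds$doublet_cutoff
  }
  fail_mito <- mito_frac > thresholds$mito_max
  fail_min <- genes < thresholds$min_genes
  fail_max <- genes > thresholds$max_genes

  reason <- rep(NA_character_, n)
  reason[fail_max] <- "max_genes"
  reason[fail_min] <- "min_genes"
  reason[fail_mito] <- "mito"
  reason[fail_doublet] <- "doublet"
  keep <- is.na(reason)

  removed <- vapply(c("doublet", "mito", "min_genes", "max_genes"),
                    function(f) sum(reason == f, na.rm = TRUE), integer(1))
  report <- list(
    metrics = data.frame(barcode = x$cells$barcode, total = as.numeric(total),
                         genes_detected = as.numeric(genes),
                         mito_frac = as.numeric(mito_frac),
                         doublet_score = if (is.null(scores)) NA_real_
                                         else as.numeric(scores),
                         removed_by = reason, stringsAsFactors = FALSE),
    removed = removed, n_input = n, n_survivors = sum(keep),
    thresholds = thresholds)
  class(report) <- "qc_report"
  list(matrix = subset_cells(x, which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d cells in, %d survivors\n", x$n_input,
              x$n_survivors))
  for (f in names(x$removed))
    cat(sprintf("  removed by %-10s %d\n", paste0(f, ":"), x$removed[[f]]))
  invisible(x)
}
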