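# Small synthetic specs and ad-hoc matrices shared across test files.

# compact spec: fewer genes and smaller programs so simulation stays fast
tiny_spec <- function(library_sizes = c(AWB = 200, JH = 120, DU = 180),
                      lineage_weights = NULL, seed = 1, ...) {
  synthetic_spec(
    n_genes = 800,
    library_sizes = library_sizes,
    lineage_weights = lineage_weights,
    program_size = c(lineage = 30, subtype = 15),
    seed = seed, ...)
}

# single-population spec with no doublets / damaged cells (clean null)
null_spec <- function(n = 300, lineage = "epithelial", seed = 1, ...) {
  w <- setNames(1, lineage)
  tiny_spec(library_sizes = c(POOL = n),
            lineage_weights = list(POOL = w),
            doublet_rate = 0, damaged_rate = 0, seed = seed, ...)
}

# build a cell_counts from a dense matrix with auto gene/cell tables
quick_counts <- function(m, mito = NULL, library = "L1") {
  n_genes <- nrow(m)
  symbols <- rownames(m) %||% sprintf("G%04d", seq_len(n_genes))
  mito <- mito %||% startsWith(symbols, "MT-")
  count_matrix(
    m,
    data.frame(gene_id = sprintf("ID%04d", seq_len(n_genes)),
               symbol = symbols, mito = mito),
    data.frame(barcode = colnames(m) %||% sprintf("BC%04d", seq_len(ncol(m))),
               library = library))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# exact two-sided rank-sum p-value by full enumeration of group
# assignments (oracle; independent of the package implementation)
enumerate_wilcox_p <- function(a, b) {
  vals <- c(a, b)
  nA <- length(a)
  n <- length(vals)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  combs <- utils::combn(n, nA)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - nA * (nA + 1) / 2)
  mu <- nA * (length(b)) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# brute-force BH step-up definition (oracle)
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    cand <- p[o][i:n] * n / (i:n)
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

# truth labels aligned to the surviving cells of annotate_synthetic_atlas()
aligned_truth <- function(res) {
  tr <- res$truth
  rownames(tr) <- tr$barcode
  tr[colnames(res$matrix$counts), ]
}
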