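#' Specification of a synthetic multi-breed jejunum atlas
#'
#' Defines the generative model for a synthetic single-cell atlas that
#' emulates the structure of the three-breed pig jejunum study: three
#' libraries (Asian wild boar `AWB`, Jinhua `JH`, Duroc `DU`), six major
#' lineages, five T/ILC/NK subtypes, three plasma-cell subtypes,
#' marker-gene overexpression, mitochondrial content, variable library
#' sizes and a doublet rate.
#'
#' Counts follow a gamma-Poisson (negative binomial) law: each gene has a
#' heavy-tailed lognormal baseline rate, marker genes of a cell's lineage
#' and subtype are multiplied by `marker_fold`, rates are renormalized so
#' the mitochondrial gene block carries the expected mitochondrial read
#' fraction of the cell's condition, and the per-cell depth is lognormal.
#'
#' Default composition: the pooled major-lineage weights are the published
#' atlas percentages (T/ILC/NK 65.4, epithelial 25.1, plasma 7.3, myeloid
#' 1.4, B 0.6, mesenchymal 0.2). Per-breed weights fix the published
#' breed-specific figures (AWB T/ILC/NK 83.0%, JH plasma 32.0%) and fill
#' the unpublished remainder with the fixed constants below; the DU weights
#' are then derived as the library-size-weighted residual so that pooling
#' the three libraries reproduces the published pooled composition exactly.
#' T-subtype weights fix the published CD4/CD8 percentages per breed, and
#' plasma-subtype weights fix the published 13.1% Type 3 share in JH
#' (Type 3 absent outside JH).
#'
#' @param n_genes Number of genes in the universe (named marker/panel genes
#'   plus `MT-` mitochondrial genes plus numbered fillers).
#' @param library_sizes Named integer vector of cells per breed library.
#' @param lineage_weights Named list breed -> simplex over the six lineages.
#' @param t_subtype_weights Named list breed -> simplex over
#'   ILC, NK, CD4_T, CD8_T, gdT.
#' @param plasma_subtype_weights Named list breed -> simplex over
#'   Type1, Type2, Type3.
#' @param marker_fold Multiplicative marker effect size, >= 1.
#' @param program_size Number of background "program" genes per lineage and
#'   per subtype: cell types differ not only in their diagnostic markers
#'   but in a broad transcriptional program, so each lineage (and subtype)
#'   additionally elevates a disjoint random draw of filler genes.
#' @param program_fold Multiplicative effect on program genes, >= 1
#'   (milder than `marker_fold`; set both to 1 for a fully exchangeable
#'   null atlas).
#' @param baseline_lnorm `c(meanlog, sdlog)` of the per-gene baseline rate.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param libsize_lognormal `c(meanlog, sdlog)` of per-cell depth.
#' @param mito_gene_fraction Proportion of genes flagged mitochondrial.
#' @param mito_expr_fraction Named vector condition -> expected
#'   mitochondrial read fraction; must contain `normal`.
#' @param damaged_rate Proportion of cells drawn from the high-mitochondrial
#'   `damaged` condition (exercises the QC mito filter).
#' @param doublet_rate Doublet proportion in [0, 1) used by pipeline
#'   wrappers when appending doublets via [inject_doublets()].
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 3000,
                           library_sizes = c(AWB = 11929, JH = 2645, DU = 11672),
                           lineage_weights = NULL,
                           t_subtype_weights = NULL,
                           plasma_subtype_weights = NULL,
                           marker_fold = 8,
                           program_size = c(lineage = 100, subtype = 50),
                           program_fold = 3,
                           baseline_lnorm = c(meanlog = 0, sdlog = 1.2),
                           dispersion = 2,
                           libsize_lognormal = c(meanlog = log(2500), sdlog = 0.35),
                           mito_gene_fraction = 0.01,
                           mito_expr_fraction = c(normal = 0.05, damaged = 0.65),
                           damaged_rate = 0.02,
                           doublet_rate = 0.05,
                           seed = 1L) {
  breeds <- names(library_sizes)
  fill_defaults <- function(given, defaults, fallback, what) {
    out <- given %||% setNames(vector("list", length(breeds)), breeds)
    for (b in breeds) {
      if (is.null(out[[b]])) {
        if (!is.null(defaults[[b]])) out[[b]] <- defaults[[b]]
        else if (!is.null(fallback)) out[[b]] <- fallback
        else stopf("no default %s for library '%s'; provide them", what, b)
      }
    }
    out
  }
  lineage_weights <- fill_defaults(lineage_weights,
                                   default_lineage_weights(), NULL,
                                   "lineage weights")
  # unknown libraries fall back to the AWB/DU-like subtype pattern
  t_subtype_weights <- fill_defaults(t_subtype_weights,
                                     default_t_subtype_weights(),
                                     default_t_subtype_weights()$AWB,
                                     "T-subtype weights")
  plasma_subtype_weights <- fill_defaults(plasma_subtype_weights,
                                          default_plasma_subtype_weights(),
                                          default_plasma_subtype_weights()$AWB,
                                          "plasma-subtype weights")
  spec <- structure(list(
    n_genes = as.integer(n_genes),
    library_sizes = library_sizes,
    lineage_weights = lineage_weights,
    t_subtype_weights = t_subtype_weights,
    plasma_subtype_weights = plasma_subtype_weights,
    marker_fold = marker_fold,
    program_size = program_size,
    program_fold = program_fold,
    baseline_lnorm = baseline_lnorm,
    dispersion = dispersion,
    libsize_lognormal = libsize_lognormal,
    mito_gene_fraction = mito_gene_fraction,
    mito_expr_fraction = mito_expr_fraction,
    damaged_rate = damaged_rate,
    doublet_rate = doublet_rate,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
  validate_spec(spec)
}

#' Default atlas specification
#'
#' The study conditions: library sizes AWB 11,929 / JH 2,645 / DU 11,672
#' (26,246 cells in total) with the published composition figures wired in
#' as described in [synthetic_spec()].
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
default_spec <- function(seed = 1L, ...) synthetic_spec(seed = seed, ...)

# Published pooled major-lineage composition (percent / 100) of the atlas.
#' @rdname synthetic_spec
#' @export
pooled_lineage_weights <- function() {
  c(`T/ILC/NK` = 0.654, epithelial = 0.251, plasma = 0.073,
    myeloid = 0.014, B = 0.006, mesenchymal = 0.002)
}

# AWB fixes the published T/ILC/NK share (0.830); JH fixes the published
# plasma share (0.320); every other AWB/JH entry is a fixed filler constant.
# DU is the size-weighted residual making the pool match exactly.
default_lineage_weights <- function() {
  sizes <- c(AWB = 11929, JH = 2645, DU = 11672)
  awb <- c(`T/ILC/NK` = 0.830, epithelial = 0.121, plasma = 0.030,
           myeloid = 0.012, B = 0.005, mesenchymal = 0.002)
  jh  <- c(`T/ILC/NK` = 0.400, epithelial = 0.210, plasma = 0.320,
           myeloid = 0.040, B = 0.020, mesenchymal = 0.010)
  pool <- pooled_lineage_weights()
  du <- (sum(sizes) * pool - sizes["AWB"] * awb - sizes["JH"] * jh) / sizes["DU"]
  du <- setNames(pmax(as.numeric(du), 0), names(pool))
  du <- du / sum(du)
  list(AWB = awb, JH = jh, DU = du)
}

# CD4/CD8 shares per breed are published; ILC/NK/gdT fillers are fixed
# constants completing each simplex.
default_t_subtype_weights <- function() {
  list(
    AWB = c(ILC = 0.030, NK = 0.030, CD4_T = 0.036, CD8_T = 0.834, gdT = 0.070),
    JH  = c(ILC = 0.130, NK = 0.100, CD4_T = 0.142, CD8_T = 0.328, gdT = 0.300),
    DU  = c(ILC = 0.030, NK = 0.030, CD4_T = 0.035, CD8_T = 0.843, gdT = 0.062)
  )
}

# JH Type 3 share (0.131) is published; Type 3 is exclusive to JH.
default_plasma_subtype_weights <- function() {
  list(
    AWB = c(Type1 = 0.600, Type2 = 0.400, Type3 = 0.000),
    JH  = c(Type1 = 0.500, Type2 = 0.369, Type3 = 0.131),
    DU  = c(Type1 = 0.600, Type2 = 0.400, Type3 = 0.000)
  )
}

validate_spec <- function(spec) {
  check_simplex <- function(w, what) {
    if (any(w < 0)) stopf("%s has negative weights", what)
    if (abs(sum(w) - 1) > 1e-9) stopf("%s does not sum to 1", what)
  }
  if (spec$n_genes < 200) stopf("n_genes too small for the gene universe")
  if (any(spec$library_sizes <= 0)) stopf("library_sizes must be positive")
  if (spec$marker_fold < 1) stopf("marker_fold must be >= 1")
  if (spec$program_fold < 1) stopf("program_fold must be >= 1")
  if (any(spec$program_size < 0)) stopf("program_size must be non-negative")
  if (spec$dispersion <= 0) stopf("dispersion must be positive")
  if (spec$doublet_rate < 0 || spec$doublet_rate >= 1)
    stopf("doublet_rate must be in [0, 1)")
  assert_prob(spec$damaged_rate, "damaged_rate")
  assert_prob(spec$mito_gene_fraction, "mito_gene_fraction")
  assert_prob(spec$mito_expr_fraction, "mito_expr_fraction")
  if (!"normal" %in% names(spec$mito_expr_fraction))
    stopf("mito_expr_fraction must contain a 'normal' condition")
  for (b in names(spec$library_sizes)) {
    check_simplex(spec$lineage_weights[[b]],
                  sprintf("lineage_weights[%s]", b))
    check_simplex(spec$t_subtype_weights[[b]],
                  sprintf("t_subtype_weights[%s]", b))
    check_simplex(spec$plasma_subtype_weights[[b]],
                  sprintf("plasma_subtype_weights[%s]", b))
  }
  spec
}

# Gene universe: named biology genes first, then MT- genes, then numbered
# fillers up to n_genes.
gene_universe <- function(spec) {
  named <- unique(c(
    unlist(lineage_markers(), use.names = FALSE),
    unlist(t_subtype_markers(), use.names = FALSE),
    unlist(plasma_subtype_markers(), use.names = FALSE),
    resolve_aliases(inflammation_genes()),
    resolve_aliases(unlist(t_state_panels(), use.names = FALSE)),
    unlist(cell_cycle_genes(), use.names = FALSE),
    lr_gene_symbols()
  ))
  n_mito <- max(1L, round(spec$mito_gene_fraction * spec$n_genes))
  core_mt <- c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3", "ND3",
               "ND4L", "ND4", "ND5", "ND6", "CYB")
  mt <- paste0("MT-", c(core_mt, sprintf("G%02d", seq_len(max(0, n_mito - 13)))))
  mt <- mt[seq_len(n_mito)]
  n_fill <- spec$n_genes - length(named) - length(mt)
  if (n_fill < 0) stopf("n_genes smaller than the named gene universe (%d)",
                        length(named) + length(mt))
  symbols <- c(named, mt, sprintf("GENE%04d", seq_len(n_fill)))
  data.frame(gene_id = sprintf("SYNG%07d", seq_along(symbols)),
             symbol = symbols,
             mito = startsWith(symbols, "MT-"),
             stringsAsFactors = FALSE)
}

# Marker genes elevated in a cell of the given lineage/subtype. Lineage
# markers that double as subtype markers (CD4, PRF1, NKG7, ...) are only
# elevated in their own subtype so the subtype signal stays recoverable.
markers_for <- function(lineage, subtype) {
  lin <- lineage_markers()
  if (lineage == "T/ILC/NK") {
    sub <- t_subtype_markers()
    shared <- setdiff(lin[["T/ILC/NK"]], unlist(sub, use.names = FALSE))
    c(shared, if (!is.na(subtype)) sub[[subtype]])
  } else if (lineage == "plasma") {
    sub <- plasma_subtype_markers()
    c(lin[["plasma"]], if (!is.na(subtype)) sub[[subtype]])
  } else {
    lin[[lineage]]
  }
}

#' Simulate a multi-breed synthetic atlas
#'
#' Draws, for every cell: a lineage (and subtype where the lineage has
#' them) from its library's weights, a condition (`normal` or `damaged`),
#' a lognormal depth, and negative-binomial counts around the cell's rate
#' profile. Deterministic given `spec$seed`. Doublets are not generated
#' here; append them with [inject_doublets()].
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (a [count_matrix()]) and `truth`
#'   (`data.frame`: barcode, library, lineage, subtype, condition,
#'   is_doublet).
#' @export
simulate_atlas <- function(spec) {
  validate_spec(spec)
  set.seed(spec$seed)
  feats <- gene_universe(spec)
  baseline <- rlnorm(spec$n_genes, spec$baseline_lnorm[["meanlog"]],
                     spec$baseline_lnorm[["sdlog"]])
  names(baseline) <- feats$symbol
  mito <- feats$mito
  programs <- draw_programs(feats$symbol, spec)

  conds <- c("normal", "damaged")
  blocks <- list(); truths <- list()
  for (b in names(spec$library_sizes)) {
    n <- spec$library_sizes[[b]]
    w <- spec$lineage_weights[[b]]
    lineage <- sample(names(w), n, replace = TRUE, prob = w)
    subtype <- rep(NA_character_, n)
    is_t <- lineage == "T/ILC/NK"
    if (any(is_t)) {
      wt <- spec$t_subtype_weights[[b]]
      subtype[is_t] <- sample(names(wt), sum(is_t), replace = TRUE, prob = wt)
    }
    is_pc <- lineage == "plasma"
    if (any(is_pc)) {
      wp <- spec$plasma_subtype_weights[[b]]
      subtype[is_pc] <- sample(names(wp), sum(is_pc), replace = TRUE, prob = wp)
    }
    condition <- sample(conds, n, replace = TRUE,
                        prob = c(1 - spec$damaged_rate, spec$damaged_rate))
    depth <- rlnorm(n, spec$libsize_lognormal[["meanlog"]],
                    spec$libsize_lognormal[["sdlog"]])

    key <- paste(lineage, subtype, condition, sep = "|")
    mat <- Matrix::Matrix(0, spec$n_genes, 0, sparse = TRUE)
    cols <- integer(0)
    for (k in sort(unique(key))) {
      idx <- which(key == k)
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      p <- cell_rate_profile(baseline, mito, parts[1],
                             ifelse(parts[2] == "NA", NA, parts[2]),
                             spec$mito_expr_fraction[[parts[3]]],
                             spec$marker_fold, programs,
                             spec$program_fold)
      mu <- p %o% depth[idx]
      block <- matrix(rnbinom(length(mu), size = spec$dispersion, mu = mu),
                      nrow = spec$n_genes)
      mat <- cbind(mat, as(block, "CsparseMatrix"))
      cols <- c(cols, idx)
    }
    mat <- mat[, order(cols), drop = FALSE]
    blocks[[b]] <- mat
    truths[[b]] <- data.frame(
      barcode = sprintf("%s_%05d", b, seq_len(n)),
      library = b, lineage = lineage, subtype = subtype,
      condition = condition, is_doublet = FALSE,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  counts <- do.call(cbind, blocks)
  cm <- count_matrix(counts, feats,
                     data.frame(barcode = truth$barcode,
                                library = truth$library,
                                stringsAsFactors = FALSE))
  list(matrix = cm, truth = truth, programs = programs)
}

# disjoint random program-gene draws from the filler pool, one per lineage
# and per subtype
draw_programs <- function(symbols, spec) {
  pool <- symbols[startsWith(symbols, "GENE")]
  keys <- c(names(lineage_markers()),
            paste0("T:", names(t_subtype_markers())),
            paste0("PC:", names(plasma_subtype_markers())))
  sizes <- rep(c(spec$program_size[["lineage"]], spec$program_size[["subtype"]]),
               c(length(lineage_markers()),
                 length(keys) - length(lineage_markers())))
  if (sum(sizes) > length(pool))
    stopf("n_genes too small for the requested program sizes")
  drawn <- sample(pool, sum(sizes))
  split(drawn, rep(keys, sizes))[keys]
}

# program genes elevated in a cell of the given lineage/subtype
programs_for <- function(programs, lineage, subtype) {
  key2 <- if (!is.na(subtype)) {
    if (lineage == "T/ILC/NK") paste0("T:", subtype)
    else if (lineage == "plasma") paste0("PC:", subtype)
  }
  c(programs[[lineage]], if (!is.null(key2)) programs[[key2]])
}

# relative expression profile of one (lineage, subtype, condition) state
cell_rate_profile <- function(baseline, mito, lineage, subtype, mito_frac,
                              fold, programs, program_fold) {
  p <- baseline
  mk <- intersect(markers_for(lineage, subtype), names(p))
  p[mk] <- p[mk] * fold
  pg <- programs_for(programs, lineage, subtype)
  p[pg] <- p[pg] * program_fold
  p[mito] <- p[mito] / sum(p[mito]) * mito_frac
  p[!mito] <- p[!mito] / sum(p[!mito]) * (1 - mito_frac)
  p
}

#' Append synthetic doublets to an atlas
#'
#' Appends `round(rate * n)` doublets per library, each formed by summing
#' the counts of two distinct randomly chosen cells of that library
#' (droplet doublets cannot span libraries), and flags them in the ground
#' truth. Heterotypic doublets get lineage `"doublet_mixed"`.
#'
#' @param x A [count_matrix()].
#' @param truth Ground-truth `data.frame` aligned to `x` (as returned by
#'   [simulate_atlas()]).
#' @param rate Doublet proportion in [0, 1).
#' @param seed Integer seed.
#' @return List with `matrix` and `truth` including the appended doublets.
#' @export
inject_doublets <- function(x, truth, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  if (rate == 0) return(list(matrix = x, truth = truth))
  set.seed(seed)
  new_cols <- list(); new_truth <- list()
  for (b in unique(x$cells$library)) {
    lib_idx <- which(x$cells$library == b)
    nd <- round(rate * length(lib_idx))
    if (nd == 0 || length(lib_idx) < 2) next
    i <- sample(lib_idx, nd, replace = TRUE)
    j <- sample(lib_idx, nd, replace = TRUE)
    while (any(i == j)) {
      eq <- i == j
      j[eq] <- sample(lib_idx, sum(eq), replace = TRUE)
    }
    dbl <- x$counts[, i, drop = FALSE] + x$counts[, j, drop = FALSE]
    lin_i <- truth$lineage[i]; lin_j <- truth$lineage[j]
    new_cols[[b]] <- dbl
    new_truth[[b]] <- data.frame(
      barcode = sprintf("%s_DBL_%05d", b, seq_len(nd)),
      library = b,
      lineage = ifelse(lin_i == lin_j, lin_i, "doublet_mixed"),
      subtype = NA_character_, condition = "normal", is_doublet = TRUE,
      parent1 = truth$barcode[i], parent2 = truth$barcode[j],
      stringsAsFactors = FALSE)
  }
  if (!length(new_cols)) return(list(matrix = x, truth = truth))
  add <- do.call(cbind, new_cols)
  addt <- do.call(rbind, new_truth)
  truth$parent1 <- truth$parent1 %||% NA_character_
  truth$parent2 <- truth$parent2 %||% NA_character_
  truth2 <- rbind(truth[names(addt)], addt)
  rownames(truth2) <- NULL
  cm <- count_matrix(cbind(x$counts, add), x$features,
                     data.frame(barcode = truth2$barcode,
                                library = truth2$library,
                                stringsAsFactors = FALSE))
  list(matrix = cm, truth = truth2)
}
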