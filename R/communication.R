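#' Ligand-receptor pair fixture
#'
#' The ligand-receptor pairs reported for the jejunal immune compartment,
#' with complexes written as `_`-joined subunits (e.g. `CD8A_CD8B`,
#' `TGFBR1_TGFBR2`). Symbols are kept as printed (including `HLA-DRA`);
#' [resolve_aliases()] maps them onto the synthetic gene universe.
#'
#' @return `data.frame` with columns `ligand` and `receptor`.
#' @export
lr_pair_table <- function() {
  pairs <- list(
    B2M = "KLRD1", CD22 = "PTPRC", HSPA8 = "LDLR",
    CCL5 = c("CCR4", "CCR5", "CXCR3", "SDC1", "CCRL2", "DPP4"),
    CALM1 = c("KCNQ5", "PDE1C", "TRPC3", "GLP1R", "HMMR"),
    ADAM10 = "TSPAN5", CD48 = "CD2", LCK = "CD8A_CD8B",
    LGALS1 = "PTPRC", MAML2 = c("NOTCH1", "NOTCH2"),
    TGFB1 = c("TGFBR1_TGFBR2", "CXCR4"), `HLA-DRA` = "CD4",
    TFF3 = "CXCR4", CD40LG = "CD53")
  data.frame(
    ligand = rep(names(pairs), lengths(pairs)),
    receptor = unlist(pairs, use.names = FALSE),
    stringsAsFactors = FALSE)
}

# all single-gene symbols referenced by the pair fixture (aliases resolved)
lr_gene_symbols <- function() {
  tab <- lr_pair_table()
  unique(resolve_aliases(unlist(strsplit(c(tab$ligand, tab$receptor), "_"))))
}

# per-cluster entity summaries: value = min over subunits of the mean
# log-normalized expression, frac = min over subunits of the expressed
# fraction
entity_values <- function(means, fracs, entities) {
  val <- sapply(entities, function(e) {
    sub <- resolve_aliases(strsplit(e, "_")[[1]])
    matrixStats::colMins(means[sub, , drop = FALSE])
  })
  frc <- sapply(entities, function(e) {
    sub <- resolve_aliases(strsplit(e, "_")[[1]])
    matrixStats::colMins(fracs[sub, , drop = FALSE])
  })
  list(value = t(val), frac = t(frc))   # entities x clusters
}

cluster_gene_means <- function(expr_sub, labels) {
  lv <- levels(labels)
  m <- vapply(lv, function(g)
    rowMeans(expr_sub[, labels == g, drop = FALSE]),
    numeric(nrow(expr_sub)))
  matrix(m, nrow = nrow(expr_sub), dimnames = list(rownames(expr_sub), lv))
}

#' Ligand-receptor interaction means between cell types
#'
#' For every (source cluster, target cluster, pair): the interaction mean
#' is the average of the ligand entity's mean log-normalized expression in
#' the source cluster and the receptor entity's in the target cluster;
#' complexes take the minimum over subunits. Interactions where either
#' entity is expressed in at most `min_frac` of its cluster's cells are
#' gated out (`mean` is `NA`, not 0). Autocrine interactions (source =
#' target) are computed like any other.
#'
#' @param lognorm Log-normalized genes x cells matrix.
#' @param labels Per-cell cluster labels.
#' @param pairs Pair table as in [lr_pair_table()]; pairs whose genes are
#'   absent are skipped with a warning.
#' @param min_frac Expressed-fraction gate (default 0.1).
#' @return `data.frame`: `source`, `target`, `ligand`, `receptor`,
#'   `lig_value`, `rec_value`, `mean`, `gated`.
#' @export
interaction_means <- function(lognorm, labels, pairs = lr_pair_table(),
                              min_frac = 0.1) {
  labels <- as.factor(labels)
  subunits <- function(e) resolve_aliases(strsplit(e, "_")[[1]])
  ok <- vapply(seq_len(nrow(pairs)), function(i)
    all(c(subunits(pairs$ligand[i]), subunits(pairs$receptor[i])) %in%
          rownames(lognorm)), logical(1))
  if (any(!ok))
    warnf("skipping %d pairs with unresolvable genes", sum(!ok))
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs)) stopf("no resolvable ligand-receptor pair")
  genes <- unique(resolve_aliases(unlist(strsplit(
    c(pairs$ligand, pairs$receptor), "_"))))
  expr_sub <- as.matrix(lognorm[genes, , drop = FALSE])
  means <- cluster_gene_means(expr_sub, labels)
  fracs <- cluster_gene_means((expr_sub > 0) * 1, labels)
  ents <- entity_values(means, fracs, unique(c(pairs$ligand, pairs$receptor)))
  lv <- levels(labels)
  grid <- expand.grid(source = lv, target = lv,
                      pair = seq_len(nrow(pairs)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lig <- pairs$ligand[grid$pair]; rec <- pairs$receptor[grid$pair]
  lig_value <- ents$value[cbind(lig, grid$source)]
  rec_value <- ents$value[cbind(rec, grid$target)]
  gated <- ents$frac[cbind(lig, grid$source)] > min_frac &
    ents$frac[cbind(rec, grid$target)] > min_frac
  imean <- (lig_value + rec_value) / 2
  imean[!gated] <- NA_real_
  data.frame(source = grid$source, target = grid$target,
             ligand = lig, receptor = rec,
             lig_value = lig_value, rec_value = rec_value,
             mean = imean, gated = gated, stringsAsFactors = FALSE)
}

#' Permutation test for ligand-receptor interactions
#'
#' Null distribution by shuffling cluster labels `n_perm` times and
#' recomputing interaction means;
#' `p = (1 + #\{null mean >= observed\}) / (n_perm + 1)` per (source,
#' target, pair). Gated-out interactions keep `p = NA`. The expressed-
#' fraction gate is evaluated on the observed labels only.
#'
#' @inheritParams interaction_means
#' @param n_perm Number of label permutations (>= 1).
#' @param seed Integer seed.
#' @return The [interaction_means()] table with an added `p` column,
#'   carrying attribute `n_perm`.
#' @export
lr_permutation_test <- function(lognorm, labels, pairs = lr_pair_table(),
                                min_frac = 0.1, n_perm = 1000, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stopf("need at least 2 clusters")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  obs <- interaction_means(lognorm, labels, pairs, min_frac)
  used_pairs <- unique(obs[c("ligand", "receptor")])
  genes <- unique(resolve_aliases(unlist(strsplit(
    c(used_pairs$ligand, used_pairs$receptor), "_"))))
  expr_sub <- as.matrix(lognorm[genes, , drop = FALSE])
  entities <- unique(c(obs$ligand, obs$receptor))
  set.seed(seed)
  exceed <- integer(nrow(obs))
  for (p in seq_len(n_perm)) {
    pl <- sample(labels)
    means <- cluster_gene_means(expr_sub, pl)
    val <- sapply(entities, function(e) {
      sub <- resolve_aliases(strsplit(e, "_")[[1]])
      matrixStats::colMins(means[sub, , drop = FALSE])
    })
    val <- t(val)   # entities x clusters (sapply gives clusters x entities)
    null_mean <- (val[cbind(obs$ligand, obs$source)] +
                    val[cbind(obs$receptor, obs$target)]) / 2
    exceed <- exceed + (null_mean >= obs$mean)
  }
  obs$p <- (1 + exceed) / (n_perm + 1)
  obs$p[!obs$gated] <- NA_real_
  attr(obs, "n_perm") <- n_perm
  obs
}

#' Top-ranked significant interactions
#'
#' Filters to interactions with `p < p_max`, ranks by interaction mean
#' (descending) and returns the top `k`; equal means break by the
#' lexicographic pair name `ligand->receptor`, then source and target.
#'
#' @param result A [lr_permutation_test()] table.
#' @param k Number of rows to return (default 20).
#' @param p_max P-value filter (default 0.01).
#' @return Ranked subset of `result` (possibly fewer than `k` rows).
#' @export
top_interactions <- function(result, k = 20, p_max = 0.01) {
  keep <- !is.na(result$mean) & !is.na(result$p) & result$p < p_max
  sub <- result[keep, , drop = FALSE]
  if (!nrow(sub)) return(sub)
  pair_name <- paste0(sub$ligand, "->", sub$receptor)
  ord <- order(-sub$mean, pair_name, sub$source, sub$target)
  head(sub[ord, , drop = FALSE], k)
}
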