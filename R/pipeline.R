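#' @keywords internal
"_PACKAGE"

#' End-to-end annotation of a synthetic atlas
#'
#' Chains the full recovery experiment: simulate an atlas from a spec,
#' append doublets at the spec's rate, score and QC-filter cells,
#' preprocess, cluster and annotate with a marker panel. Each stage uses
#' a seed derived from `seed` so the whole run is reproducible.
#'
#' @param spec A [synthetic_spec()].
#' @param panel Marker panel for [annotate_clusters()] (default: major
#'   lineages).
#' @param resolution,k Clustering parameters.
#' @param n_hvg,n_pcs Preprocessing parameters. The default retains 1000
#'   variable genes — a third of the default synthetic gene universe —
#'   rather than [preprocess()]'s 2000, which would be two thirds of the
#'   universe and dilute the lineage programs with noise genes.
#' @param qc Apply [doublet_score()] + [qc_filter()] before clustering.
#' @param seed Integer seed (default: the spec's).
#' @return List with `matrix`, `truth`, `qc_report`, `prep`, `clusters`,
#'   `labels` (per surviving cell).
#' @export
annotate_synthetic_atlas <- function(spec, panel = lineage_markers(),
                                     resolution = 1, k = 15, n_hvg = 1000,
                                     n_pcs = 50, qc = TRUE,
                                     seed = NULL) {
  seed <- seed %||% spec$seed
  sim <- simulate_atlas(spec)
  if (spec$doublet_rate > 0)
    sim <- inject_doublets(sim$matrix, sim$truth, spec$doublet_rate,
                           seed = seed + 1L)
  x <- sim$matrix
  report <- NULL
  if (qc) {
    scores <- doublet_score(x, seed = seed + 2L)
    filt <- qc_filter(x, qc_thresholds(), scores)
    x <- filt$matrix
    report <- filt$report
  }
  prep <- preprocess(x, n_hvg = n_hvg, n_pcs = n_pcs, seed = seed + 3L)
  clus <- cluster_cells(prep$embedding, k = k, resolution = resolution,
                        seed = seed + 4L)
  labels <- annotate_clusters(prep$lognorm, clus, panel)
  list(matrix = x, truth = sim$truth, qc_report = report, prep = prep,
       clusters = clus, labels = labels)
}

#' Percentage composition of a label vector
#'
#' @param labels Per-cell labels.
#' @return Named numeric vector of percentages summing to 100.
#' @export
label_percentages <- function(labels) {
  100 * prop.table(table(labels))
}
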