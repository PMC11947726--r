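# jejumap

Breed-comparative single-cell immune analysis of the pig jejunum.

`jejumap` implements the analysis stack used to compare jejunal
single-cell RNA-seq atlases across pigs at three domestication stages —
Asian wild boar (AWB), the Chinese local Jinhua breed (JH) and the
intensive Duroc breed (DU) — as a tested, reusable R package. The study
design it mirrors profiles one 10x library per breed (11,929 / 2,645 /
11,672 cells; 26,246 in total), annotates six major lineages and the
T/ILC/NK and plasma-cell subtypes with marker panels, and asks how
composition, immune gene programs and cell–cell communication differ along
the domestication order AWB → JH → DU.

The package covers, stage by stage:

* **Simulation** — a gamma–Poisson multi-breed atlas generator with known
  ground truth (`synthetic_spec()`, `simulate_atlas()`,
  `inject_doublets()`), whose defaults are the study's library sizes and
  reported composition percentages;
* **I/O and QC** — 10x-style MatrixMarket triplets (`read_mtx()`,
  `write_mtx()`), a simulated-doublet kNN score (`doublet_score()`) and
  the published cell filters: doublet score ≥ 0.25, mitochondrial fraction
  > 50%, detected genes outside [200, 7500] (`qc_filter()`);
* **Clustering and annotation** — depth normalization, binned-dispersion
  HVG selection, PCA, Leiden clustering on a shared-nearest-neighbor graph
  and two-tier marker-panel annotation (`preprocess()`,
  `cluster_cells()`, `annotate_clusters()`), plus cell-cycle phase calls
  and a cross-breed cell-type dendrogram;
* **Composition** — a bootstrapped permutation test of per-cluster
  proportions, significant at FDR < 0.05 and |log2 fold difference| > 1.5
  (`proportion_permutation_test()`);
* **Scoring** — gene-module scores with binned background controls
  (`module_score()`), the inflammation gene set and T-cell state panels;
* **Differential expression** — vectorized tie-corrected Wilcoxon
  rank-sum tests with BH adjustment and the published DEG thresholds
  (`wilcoxon_deg()`), and hypergeometric over-representation against
  user-supplied gene sets (`hypergeom_enrich()`);
* **Domestication patterns** — fuzzy c-means soft clustering of
  standardized AWB → JH → DU profiles (c = 9, empirical fuzzifier)
  intersected with DEG evidence into four patterns: increasing, JH-high,
  JH-low, decreasing (`fuzzy_cmeans()`, `classify_patterns()`);
* **Communication** — ligand–receptor interaction means with
  complex-subunit minima, a cluster-label permutation null and top-20
  selection at p < 0.01 (`lr_permutation_test()`, `top_interactions()`);
* **Robustness** — cell-number and depth downsampling with pseudobulk
  log-CPM Pearson agreement, five replicates (`downsample_report()`).

## Worked example

Simulate a small three-breed atlas, run QC, cluster, annotate, and test
which cell types differ in proportion between Jinhua and wild boar:

```r
library(jejumap)

spec <- synthetic_spec(library_sizes = c(AWB = 1200, JH = 800, DU = 1000),
                       seed = 1)
res <- annotate_synthetic_atlas(spec)
res$qc_report
#> <qc_report> 3150 cells in, 3001 survivors
#>   removed by doublet:   98
#>   removed by mito:      51
#>   removed by min_genes: 0
#>   removed by max_genes: 0

round(label_percentages(res$labels), 1)
#> labels
#> epithelial    myeloid     plasma   T/ILC/NK
#>       25.2        2.2       11.6       61.0

comp <- proportion_permutation_test(res$labels, res$matrix$cells$library,
                                    pair = c("JH", "AWB"), seed = 1)
comp[, c("cluster", "prop_a", "prop_b", "log2fd", "p", "fdr", "significant")]
#>      cluster prop_a prop_b log2fd        p      fdr significant
#> 1 epithelial 0.2572 0.1225   1.07 0.000999 0.000999       FALSE
#> 2    myeloid 0.0587 0.0150   1.97 0.000999 0.000999        TRUE
#> 3     plasma 0.3059 0.0317   3.27 0.000999 0.000999        TRUE
#> 4   T/ILC/NK 0.3783 0.8308  -1.14 0.000999 0.000999       FALSE
```

The 3,150 input cells are the 3,000 simulated singlets plus 5% injected
doublets; QC removes most doublets and the high-mitochondrial "damaged"
cells. The annotation percentages track the simulated composition. The
composition test recovers the built-in breed differences: Jinhua is
plasma-cell-rich (30.6% vs 3.2% of cells, log2FD 3.27) and the wild boar
library is dominated by T/ILC/NK lymphocytes; only clusters passing both
FDR < 0.05 and |log2FD| > 1.5 are flagged significant, so the epithelial
and T/ILC/NK shifts, though distinguishable from label noise (p ≈ 0.001),
are not called. The `p` and `fdr` floor of 1/1001 is the add-one
permutation estimator at 1,000 iterations.

The methods vignette (`vignettes/jejumap-methods.Rmd`) documents the
models, parameter choices and limitations in detail.

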