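---
title: "Methods: breed-comparative single-cell immune analysis of the pig jejunum"
author: "jejumap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breed-comparative single-cell immune analysis of the pig jejunum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jejumap)
```

# Scope

`jejumap` implements the analysis stack of a breed-comparative single-cell
RNA-seq study of the pig jejunum: three 10x-style libraries from pigs at
three domestication stages — Asian wild boar (AWB), the Chinese local
Jinhua breed (JH) and the intensive Duroc breed (DU) — are quality
controlled, clustered, annotated with a two-tier marker panel, and compared
through composition statistics, gene-module scores, differential
expression, expression-pattern classification along the domestication
order, ligand–receptor communication statistics, and downsampling
robustness checks. A synthetic atlas generator with full ground truth
drives verification: every stage of the pipeline is exercised end-to-end on
data whose composition, marker structure, doublet content and depth
distribution are known exactly.

# The synthetic atlas generator

The generator (`synthetic_spec()`, `simulate_atlas()`) is a gamma–Poisson
(negative binomial) simulator, the standard generative model for UMI
counts:

* every gene gets a heavy-tailed baseline rate,
  $\lambda_g \sim \mathrm{LogNormal}(0, 1.2)$;
* every cell draws a lineage (and a subtype inside the T/ILC/NK and plasma
  lineages) from its library's weight simplex, and a sequencing depth
  $L \sim \mathrm{LogNormal}(\log 2500, 0.35)$ — typical 10x depths;
* the diagnostic marker genes of the cell's lineage and subtype are
  multiplied by `marker_fold` (default 8), and a disjoint random set of
  "program" genes per lineage (100) and subtype (50) by `program_fold`
  (default 3). The program block reflects that real cell types differ in a
  broad transcriptional program, not only in their diagnostic markers;
  without it a clustering would have to work from a handful of genes,
  which no real tissue resembles;
* rates are renormalized so the mitochondrial gene block (1% of genes,
  `MT-` prefix) carries an expected read fraction of 0.05 in normal cells
  and 0.65 in a 2% "damaged" sub-population, which exercises the
  mitochondrial QC filter;
* counts are $\mathrm{NB}(\mu = L\,p_g,\ \mathrm{size} = 2)$, and
  `inject_doublets()` appends 5% doublets per library by summing two
  random cells of the same library.

Composition defaults are the study conditions: library sizes 11,929 (AWB),
2,645 (JH) and 11,672 (DU) — 26,246 cells in total — with pooled lineage
weights T/ILC/NK 65.4%, epithelial 25.1%, plasma 7.3%, myeloid 1.4%,
B 0.6%, mesenchymal 0.2%. The reported breed-specific values are pinned
(AWB T/ILC/NK 83.0%; JH plasma 32.0%; per-breed CD4/CD8 αβ T shares; JH
Type 3 plasma share 13.1%, absent outside JH). The remaining per-breed
entries are not reported; they are fixed filler constants in
`default_lineage_weights()` and friends, and the DU lineage weights are
derived as the library-size-weighted residual so that pooling the three
libraries reproduces the pooled composition exactly. Plasma-subtype marker
panels are synthetic constructs (`plasma_subtype_markers()`): the study
characterizes the subtypes through expression programs (oxidative
phosphorylation in Type 1, conventional plasma-cell markers in Type 2,
secretory IGHM/PRDX4/ATP5PO in Type 3) rather than a published panel, so
small representative panels are fixed once for simulation and annotation.

What the generator does **not** emulate: batch effects beyond library
identity, ambient RNA, UMI collisions, gene–gene correlation beyond the
program blocks, and realistic gene-length or GC structure. Passing the
recovery tests therefore shows that the pipeline's statistics behave
correctly under a faithful null-plus-signal model — not that they would
resolve subtypes in arbitrarily noisy real tissue.

# Quality control

`doublet_score()` follows the simulated-doublet strategy: artificial
doublets are formed by summing random cell pairs, co-embedded with the
observed cells in PCA space of log-normalized expression, and each cell is
scored from the simulated fraction among its
$k' = k\,(1 + n_{sim}/n)$ nearest neighbors with
$k = \lfloor 0.5\sqrt{n} \rceil$. The raw fraction is converted to a
posterior with a doublet prior $\pi$ (default 0.1):
$s = \pi q' / (\pi q' + (1-\pi)(k'-s_{raw}))$ with $q' = s_{raw}/r$, so
that singlets of a homogeneous population score near $\pi$ — comfortably
below the 0.25 removal cutoff — while heterotypic doublets approach 1.
Homotypic doublets are indistinguishable from singlets after depth
normalization (in any method of this family) and are only caught by
chance; this is why the end-to-end composition recovery tolerates a small
surviving-doublet contamination.

`qc_filter()` applies the published thresholds in a fixed order — doublet
score ≥ 0.25, mitochondrial fraction > 0.50, detected genes < 200 or
> 7,500 (boundaries survive) — attributing each removed cell to the first
failing filter so the report always balances. The printed phrase removing
cells with scores *below* 0.25 is read as a typo for the conventional
direction; the literal reading (`direction = "low"`) is available.

# Clustering and annotation

`preprocess()` normalizes each cell to 10,000 counts, applies
$\log(1+x)$, selects highly variable genes by binned dispersion, z-scales
them (capped at 10) and embeds cells with truncated PCA (50 components;
`irlba`). `cluster_cells()` builds a shared-nearest-neighbor graph
(k = 15, Jaccard weights pruned below 1/15) and partitions it with Leiden
modularity optimization (`igraph`), resolution 1 by default, inside the
0.5–2 range the study sweeps. An optional per-library centering of the
embedding stands in for batch integration; the synthetic data is
batch-free, so nothing stronger is needed or shipped.

`annotate_clusters()` scores each cluster for each panel label as the mean
z-scored log-normalized expression of the label's markers over the
cluster's cells and assigns the argmax (ties break by panel order); it is
applied twice, first with the six-lineage panel on all cells, then with
the T/ILC/NK-subtype (or plasma-subtype) panel within the compartment.
Because the assignment is per cluster, oversplitting is harmless while
undersplitting loses minority populations; the synthetic-recovery wrapper
`annotate_synthetic_atlas()` therefore keeps resolution 1 but retains
1,000 variable genes — a third of the 3,000-gene synthetic universe —
rather than `preprocess()`'s default 2,000, which on so small a universe
would mean keeping two thirds of all genes and diluting the 50-gene
subtype programs with noise. On the default universe this choice is what
lets ~100-cell plasma subtypes survive subclustering.

Cell-cycle phases (`cell_cycle_phase()`) use the binned-control module
score on the standard S and G2/M program lists; a cell with both scores at
or below zero is G1, otherwise the larger score decides. The printed
"geometric mean expression" is implemented as the arithmetic mean in
log1p space — the logarithm of a geometric-type mean — which makes the
cycle score and the module score one mechanism. `celltype_dendrogram()`
averages log-normalized profiles per (breed, cell type), takes correlation
distance and average linkage, and serializes Newick via `ape`.

# Composition statistics

`proportion_permutation_test()` computes, per cluster,
$\mathrm{log2FD} = \log_2(p^A_c / p^B_c)$ with a 0.5-cell pseudocount on
empty cluster-by-group cells (avoiding infinite ratios), a permutation
p-value from shuffling group labels (1,000 iterations, add-one estimator
so p is never 0), a percentile bootstrap CI from resampling cells within
groups, and BH adjustment across clusters. Significance uses the published
thresholds FDR < 0.05 and |log2FD| > 1.5. With one library per breed the
test is a cell-level statement, not a donor-level one — the same caveat
applies to the study design it mirrors.

# Module scores, DE, enrichment

`module_score()` is the binned-control score: genes are ranked by mean
expression and cut into 25 equal-size bins; each set gene draws 100
control genes from its own bin; the score is mean(set) − mean(controls).
Its expectation is zero for exchangeable gene sets and it is invariant to
per-cell constant shifts; both are tested. The inflammation fixture keeps
the printed symbol "PRF" verbatim with an alias to PRF1.

`wilcoxon_deg()` is a vectorized tie-corrected normal-approximation
Mann–Whitney test with $\log_2$ fold changes on the
$\mathrm{expm1}$-of-log-normalized scale (ε = 1e-9), BH adjustment, and
the published DEG thresholds (adjusted p < 0.05, |log2FC| > 1.5, applied
two-sided). `exact = TRUE` switches tie-free genes to the exact rank-sum
null, which the test suite verifies against full enumeration for group
sizes ≤ 8. `hypergeom_enrich()` is the upper-tail hypergeometric
over-representation test against user-supplied gene sets (GO/KEGG
databases are fixtures, never downloaded).

# Domestication patterns

`breed_profile()` reduces expression to per-gene breed means in the fixed
order AWB → JH → DU and standardizes rows with the population standard
deviation, so a monotone profile maps to (−1.2247, 0, 1.2247).
`fuzzy_cmeans()` is the Bezdek alternating optimizer (Euclidean distance,
membership exponent $2/(m-1)$, default c = 9 clusters as in the study),
initialized from jittered random data rows: random-membership
initialization underflows $U^m$ at large fuzzifiers and collapses
centroids onto single data points (reference implementations degenerate
identically), whereas distance-driven initialization is stable for any
$m$. The per-iteration objective is recorded and non-increasing.
`estimate_fuzzifier()` implements the empirical formula
$m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243)D^{-0.0406\ln N - 0.1134}$.
A caveat worth knowing: with only D = 3 conditions this estimate is large
(≈ 3.8 at N = 1000), memberships become diffuse (maxima ≈ 0.3) and the
conventional 0.5 membership threshold then assigns nothing; for pattern
classification on 3-point profiles a crisper fuzzifier (≈ 1.2–1.5) is the
practical choice, and the planted-pattern tests use one.
`min_centroid_distance()` reports the Dmin table used to sanity-check the
cluster number; it is advisory, c = 9 stays the default.

`classify_patterns()` intersects cluster shape with DEG evidence:
increasing centroids (a < b < c) yield type1 when the gene is up in JH vs
AWB or down in JH vs DU; decreasing centroids type4 symmetrically; JH-high
centroids yield type2 only with up-DEGs in both JH comparisons, JH-low
type3 with down-DEGs in both; everything else — including exact centroid
ties, which are measure-zero on standardized profiles — is `none`.
Membership must reach 0.5 in the supporting cluster.

# Communication statistics

`interaction_means()` scores each (source, target, ligand→receptor)
triple as the average of the ligand entity's mean expression in the source
cluster and the receptor entity's in the target cluster, complexes taking
the minimum over subunits (`CD8A_CD8B`, `TGFBR1_TGFBR2`); entities
expressed in ≤ 10% of their cluster's cells gate the interaction out as
undefined (NA, never 0). `lr_permutation_test()` shuffles cluster labels
(1,000 permutations, add-one estimator, upper tail) and
`top_interactions()` returns the top 20 interactions with p < 0.01 ranked
by mean, ties broken lexicographically. The pair fixture
(`lr_pair_table()`) contains the interactions the study reports, with an
alias map (e.g. HLA-DRA → SLA-DRA) onto the synthetic universe.

# Downsampling robustness

`subsample_cells()` draws a fixed number of cells per group without
replacement (the study checks 2,000 per breed); `downsample_counts()`
thins each cell to an exact target total by a multivariate hypergeometric
draw, implemented by uniform sampling of retained read positions — the
published depth targets 8,172 and 6,300 counts/cell are kept as documented
defaults. `pseudobulk_correlation()` sums counts per group, CPM-normalizes,
log1p-transforms and reports Pearson r (raw-sum r alongside);
`downsample_report()` repeats the procedure five times, as in the study,
where the reported bound is r > 0.9.

# Problem sizes, seeds, numerics

The verification suite simulates at the study's scales: the full
26,246-cell atlas for the downsampling check, ~10,000 cells for pooled and
AWB recovery, 2,645 for the JH library, ~3,000 for the JH T compartment
and ~800 for the JH plasma compartment; unit tests use smaller universes
(800 genes, hundreds of cells) built by the same generator. Every
stochastic step takes an explicit integer seed and is bit-reproducible
given it. At n ≈ 800 the Type 3 plasma share carries ≈ 1.2 percentage
points of multinomial sampling noise before any analysis runs — deviations
of that order from the nominal 13.1% are sampling variation, not pipeline
bias (the annotated share tracks the realized ground truth to well under a
point).

Numerical conventions: permutation p-values use the add-one estimator and
can never be exactly 0; BH adjustment is delegated to `stats::p.adjust`
behind a validating wrapper; zero-variance genes are dropped before
standardization; fuzzy c-means treats exact zero distances as crisp
assignments; annotation ties break by panel order; ranking ties in
`top_interactions()` break lexicographically.

# Known limitations

One library per breed means all between-breed statistics are cell-level;
the composition test quantifies sampling noise within libraries, not
biological replication. The doublet score cannot detect homotypic
doublets. Harmony-style integration is out of scope (single-batch
synthetic data); per-library embedding centering is the only correction
offered. GO/KEGG content is user-supplied. The fuzzifier estimate is
unreliable at D = 3 (above). Real-data cluster counts (the study reports
28) are not a target on synthetic data — only label recovery and
composition are pinned.
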