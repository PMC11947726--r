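#' Marker panels and curated gene sets
#'
#' The two-tier marker panels used for annotation of the jejunal atlas and
#' the curated gene sets used by the scoring module. Major-lineage and
#' T/ILC/NK-subtype panels follow the published pig jejunum marker selection
#' (EPCAM/KRT8 epithelium, JCHAIN/MZB1 plasma cells, and so on). Plasma-cell
#' subtype panels are synthetic constructs of this package: the three
#' subtypes are reported through expression characteristics (oxidative
#' phosphorylation in Type 1, conventional early plasma-cell markers in
#' Type 2, secretory IGHM/PRDX4/ATP5PO in Type 3), not a published panel,
#' so small representative panels are fixed here for simulation and
#' annotation.
#'
#' @return A named list of character vectors (label -> gene symbols).
#' @name marker_panels
NULL

#' @rdname marker_panels
#' @export
lineage_markers <- function() {
  list(
    epithelial   = c("EPCAM", "KRT8"),
    plasma       = c("JCHAIN", "MZB1"),
    B            = c("CD19", "CD79A", "CD79B", "BACH2"),
    `T/ILC/NK`   = c("CD3E", "ZAP70", "CD4", "IL7R", "CD8A", "GNLY", "NKG7", "PRF1"),
    myeloid      = c("CD68", "CSF2RB", "C1QC", "APOE", "FCER1A", "KIT"),
    mesenchymal  = c("CALD1", "VIM", "ZEB2")
  )
}

#' @rdname marker_panels
#' @export
t_subtype_markers <- function() {
  list(
    ILC     = c("KLRB1", "CSF2"),
    NK      = c("PRF1", "NKG7", "EOMES"),
    CD4_T   = c("CD4"),
    CD8_T   = c("CD8B"),
    gdT     = c("BLK")
  )
}

#' @rdname marker_panels
#' @export
plasma_subtype_markers <- function() {
  list(
    Type1 = c("COX4I1", "NDUFB1"),
    Type2 = c("CD38", "CD27"),
    Type3 = c("IGHM", "PRDX4", "ATP5PO")
  )
}

#' @rdname marker_panels
#' @export
inflammation_genes <- function() {
  # "PRF" is kept verbatim as printed in the source list; resolve_aliases()
  # maps it to PRF1.
  c("GZMB", "GZMA", "PRF", "IFNG", "IFNGR1", "ISG20", "IL4", "IL4R",
    "IL5", "IL6", "IL10", "IRF2", "IL12B", "IL17A", "IL17F", "IL17RA",
    "IL2", "IL2RB", "IL21", "IL21R", "NFKBIA", "RORA", "RORC", "S100A8",
    "S100A9", "STAT1", "STAT3", "STAT4", "TGFB1I1", "TNFRSF1B", "TNF")
}

#' @rdname marker_panels
#' @export
t_state_panels <- function() {
  list(
    memory          = c("KLRB1", "IL7R"),
    tissue_resident = c("RUNX3", "CD69", "NR4A1", "CXCR6", "CD103"),
    cytotoxic       = c("GZMA", "GZMB", "PRF1", "GNLY", "CST7", "TNFSF10"),
    exhaustion      = c("PDCD1", "CTLA4", "HAVCR2", "LAG3"),
    costimulatory   = c("CD28", "CD226", "ICOS", "TNFRSF9")
  )
}

#' Resolve gene-symbol aliases
#'
#' Maps legacy or shorthand symbols onto the symbols used by a gene
#' universe (e.g. `PRF` -> `PRF1`, `CD103` -> `ITGAE`). Symbols without an
#' alias entry pass through unchanged.
#'
#' @param symbols Character vector of gene symbols.
#' @return Character vector of the same length.
#' @export
resolve_aliases <- function(symbols) {
  map <- c(PRF = "PRF1", CD103 = "ITGAE", `HLA-DRA` = "SLA-DRA")
  hit <- symbols %in% names(map)
  symbols[hit] <- map[symbols[hit]]
  symbols
}

#' Cell-cycle phase gene sets
#'
#' S-phase and G2/M-phase gene programs (the widely used tumor single-cell
#' consensus lists) for cycle scoring; used with [cell_cycle_phase()].
#'
#' @return List with character vectors `s` and `g2m`.
#' @export
cell_cycle_genes <- function() {
  list(
    s = c("MCM5", "PCNA", "TYMS", "FEN1", "MCM2", "MCM4", "RRM1", "UNG",
          "GINS2", "MCM6", "CDCA7", "DTL", "PRIM1", "UHRF1", "HELLS",
          "RFC2", "RPA2", "NASP", "RAD51AP1", "GMNN", "WDR76", "SLBP",
          "CCNE2", "UBR7", "POLD3", "MSH2", "ATAD2", "RAD51", "RRM2",
          "CDC45", "CDC6", "EXO1", "TIPIN", "DSCC1", "BLM", "CASP8AP2",
          "USP1", "CLSPN", "POLA1", "CHAF1B", "BRIP1", "E2F8"),
    g2m = c("HMGB2", "CDK1", "NUSAP1", "UBE2C", "BIRC5", "TPX2", "TOP2A",
            "NDC80", "CKS2", "NUF2", "CKS1B", "MKI67", "TMPO", "CENPF",
            "TACC3", "SMC4", "CCNB2", "CKAP2L", "CKAP2", "AURKB", "BUB1",
            "KIF11", "ANP32E", "TUBB4B", "GTSE1", "KIF20B", "HJURP",
            "CDCA3", "CDC20", "TTK", "CDC25C", "KIF2C", "RANGAP1",
            "NCAPD2", "DLGAP5", "CDCA2", "CDCA8", "ECT2", "KIF23",
            "HMMR", "AURKA", "PSRC1", "ANLN", "LBR", "CKAP5", "CENPE",
            "CTCF", "NEK2", "G2E3", "GAS2L3", "CBX5", "CENPA")
  )
}
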