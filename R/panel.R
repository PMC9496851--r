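#' The 16-locus KIR gene-content panel
#'
#' Constructs the panel of KIR loci scored by presence/absence typing:
#' 14 expressed genes plus the two pseudogenes KIR2DP1 and KIR3DP1.
#' The four framework genes (KIR3DL3, KIR3DP1, KIR2DL4, KIR3DL2) delimit
#' the centromeric and telomeric regions and sit on essentially every
#' haplotype; the B-specific set distinguishes Bx from AA genotypes.
#'
#' @param genes Ordered character vector of locus names (default: the
#'   standard 16-gene panel).
#' @param framework Subset of `genes` treated as framework loci.
#' @param b_specific Subset of `genes` whose presence marks a group-B
#'   haplotype; a genotype carrying none of them is labelled AA.
#' @return An object of class `kir_panel`: a list with elements `genes`,
#'   `framework` and `b_specific`.
#' @examples
#' p <- kir_panel()
#' p$framework
#' @export
kir_panel <- function(genes = c("KIR2DL1", "KIR2DL2", "KIR2DL3", "KIR2DL4",
                                "KIR2DL5", "KIR2DS1", "KIR2DS2", "KIR2DS3",
                                "KIR2DS4", "KIR2DS5", "KIR3DL1", "KIR3DL2",
                                "KIR3DL3", "KIR3DS1", "KIR2DP1", "KIR3DP1"),
                      framework = c("KIR3DL3", "KIR3DP1", "KIR2DL4", "KIR3DL2"),
                      b_specific = c("KIR2DL2", "KIR2DL5", "KIR2DS1", "KIR2DS2",
                                     "KIR2DS3", "KIR2DS5", "KIR3DS1")) {
  genes <- as.character(genes)
  if (length(genes) != 16L) {
    stop("a KIR gene-content panel has exactly 16 loci, got ", length(genes))
  }
  if (anyDuplicated(genes)) stop("panel gene names must be unique")
  if (!all(framework %in% genes)) stop("framework genes must belong to the panel")
  if (!all(b_specific %in% genes)) stop("b_specific genes must belong to the panel")
  if (length(intersect(framework, b_specific)) > 0L) {
    stop("framework and b_specific gene sets must be disjoint")
  }
  structure(list(genes = genes, framework = framework, b_specific = b_specific),
            class = "kir_panel")
}

#' @export
print.kir_panel <- function(x, ...) {
  cat("KIR gene-content panel (", length(x$genes), " loci)\n", sep = "")
  cat("  framework:  ", paste(x$framework, collapse = ", "), "\n", sep = "")
  cat("  B-specific: ", paste(x$b_specific, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Canonicalise locus names: tolerant to case and to a missing/extra "KIR"
# prefix ("2dl1" -> "KIR2DL1").  Unmatched names are returned as NA.
normalize_gene_names <- function(x, panel = kir_panel()) {
  key <- toupper(sub("^KIR", "", toupper(trimws(x))))
  ref <- toupper(sub("^KIR", "", panel$genes))
  panel$genes[match(key, ref)]
}
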