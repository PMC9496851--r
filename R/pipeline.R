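#' Gene and genotype frequency analysis
#'
#' Orchestrates the frequency stage: per-gene carrier/Bernstein
#' frequencies with confidence intervals, the genotype-content frequency
#' table, and KIR2DS4 variant frequencies. When `outdir` is given, writes
#' `gene_frequencies_long.csv` (tidy, full precision),
#' `gene_frequencies_wide.csv` (genes as columns, four statistic rows,
#' percentages to one decimal), `genotype_frequencies.csv` and
#' `ds4_variants.csv`.
#'
#' @param profiles A [kir_genotypes()] table.
#' @param catalog Genotype catalog for ID lookup.
#' @param panel A [kir_panel()].
#' @param level Confidence level.
#' @param outdir Optional output directory.
#' @return List with `gene_summary`, `genotype_table`, `ds4`, `findings`.
#' @export
run_frequency_analysis <- function(profiles,
                                   catalog = default_genotype_catalog(),
                                   panel = attr(profiles, "panel") %||% kir_panel(),
                                   level = 0.95, outdir = NULL) {
  findings <- validate_profiles(profiles, panel)
  gene_summary <- population_summary(profiles, panel, level)
  genotype_table <- genotype_frequency_table(profiles, catalog, panel)
  ds4 <- ds4_variant_frequencies(profiles)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    utils::write.csv(gene_summary,
                     file.path(outdir, "gene_frequencies_long.csv"),
                     row.names = FALSE)
    wide <- rbind(`Direct Count` = gene_summary$carriers,
                  `Carrier Frequencies (%)` = round_half_up(gene_summary$cf * 100, 1),
                  `Gene Frequencies (%)` = round_half_up(gene_summary$gf * 100, 1),
                  `CI lower (%)` = round_half_up(gene_summary$ci_lower * 100, 1),
                  `CI upper (%)` = round_half_up(gene_summary$ci_upper * 100, 1))
    colnames(wide) <- gene_summary$gene
    utils::write.csv(wide, file.path(outdir, "gene_frequencies_wide.csv"))
    utils::write.csv(genotype_table,
                     file.path(outdir, "genotype_frequencies.csv"),
                     row.names = FALSE)
    utils::write.csv(ds4, file.path(outdir, "ds4_variants.csv"),
                     row.names = FALSE)
  }
  list(gene_summary = gene_summary, genotype_table = genotype_table,
       ds4 = ds4, findings = findings)
}

#' Haplotype inference analysis
#'
#' Enumerates compatible diplotypes, fits haplotype frequencies by EM
#' under Hardy-Weinberg equilibrium and summarises resolution. When
#' `outdir` is given, writes `haplotype_frequencies.csv` and a JSON run
#' report (`haplotype_report.json`: iterations, final log-likelihood,
#' residual, resolution summary).
#'
#' @param profiles A [kir_genotypes()] table.
#' @param refs Reference haplotypes.
#' @param tol,max_iter EM controls (see [em_haplotype_frequencies()]).
#' @param panel A [kir_panel()].
#' @param outdir Optional output directory.
#' @return List with `estimate`, `table`, `resolution`.
#' @export
run_haplotype_analysis <- function(profiles,
                                   refs = default_reference_haplotypes(),
                                   tol = 1e-8, max_iter = 1000L,
                                   panel = attr(refs, "panel") %||% kir_panel(),
                                   outdir = NULL) {
  est <- em_haplotype_frequencies(profiles, refs, tol, max_iter, panel)
  tab <- haplotype_frequency_table(est)
  res <- resolution_summary(profiles, refs, panel)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    utils::write.csv(tab, file.path(outdir, "haplotype_frequencies.csv"),
                     row.names = FALSE)
    report <- list(n_individuals = est$n_individuals,
                   n_chromosomes = est$n_chromosomes,
                   iterations = est$n_iter, converged = est$converged,
                   log_likelihood = est$log_likelihood[est$n_iter],
                   residual = est$residual, resolution = res)
    jsonlite::write_json(report, file.path(outdir, "haplotype_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(estimate = est, table = tab, resolution = res)
}

#' KIR-HLA ligand analysis
#'
#' Joins genotype and HLA tables, classifies ligands, and produces the
#' four-state combination table, the inhibitory-pair multiplicity
#' distribution, and the ligand carriage summary. When `outdir` is given,
#' writes `kir_hla_pairs.csv`, `inhibitory_multiplicity.csv` and
#' `ligand_carriage.csv`.
#'
#' @param profiles A [kir_genotypes()] table.
#' @param hla An HLA typing table ([read_hla_table()]) or a ready
#'   `kir_ligands` flag table.
#' @param lookup Ligand lookup.
#' @param pairs Pair definitions.
#' @param panel A [kir_panel()].
#' @param outdir Optional output directory.
#' @return List with `ligands`, `pair_table`, `multiplicity`, `carriage`.
#' @export
run_ligand_analysis <- function(profiles, hla,
                                lookup = default_ligand_lookup(),
                                pairs = default_pair_definitions(),
                                panel = attr(profiles, "panel") %||% kir_panel(),
                                outdir = NULL) {
  ligands <- if (inherits(hla, "kir_ligands")) hla else classify_ligands(hla, lookup)
  pair_table <- kir_hla_pair_table(profiles, ligands, pairs, panel)
  multiplicity <- inhibitory_pair_multiplicity(profiles, ligands, panel)
  carriage <- ligand_carriage_summary(ligands)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    utils::write.csv(pair_table, file.path(outdir, "kir_hla_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(multiplicity,
                     file.path(outdir, "inhibitory_multiplicity.csv"),
                     row.names = FALSE)
    utils::write.csv(carriage, file.path(outdir, "ligand_carriage.csv"),
                     row.names = FALSE)
  }
  list(ligands = ligands, pair_table = pair_table,
       multiplicity = multiplicity, carriage = carriage)
}

#' Inter-population comparison analysis
#'
#' Nei distances on a population x gene carrier-frequency table, the
#' neighbor-joining dendrogram, correlation PCA and Euclidean hierarchical
#' clustering. When `outdir` is given, writes the square distance CSV, a
#' PHYLIP lower-triangular matrix, the Newick tree, PCA scores/loadings
#' CSVs and a clustering JSON (leaf order and merge heights).
#'
#' @param table A `kir_pop_freq` table ([read_population_frequencies()]).
#' @param genes Optional gene-set restriction (e.g. 14 genes without the
#'   pseudogenes); applied to the whole analysis, never by imputation.
#' @param standardize Standardise genes in the PCA (default TRUE).
#' @param linkage Hierarchical clustering linkage (default "complete").
#' @param outdir Optional output directory.
#' @return List with `distances`, `newick`, `pca`, `clustering`.
#' @export
run_population_comparison <- function(table, genes = NULL,
                                      standardize = TRUE,
                                      linkage = "complete", outdir = NULL) {
  if (!is.null(genes)) {
    keep <- normalize_gene_names(genes, kir_panel())
    meta <- intersect(c("population", "n", "region"), names(table))
    table <- structure(table[, c(meta, keep)],
                       class = class(table), genes = keep)
  }
  d <- nei_distance(table)
  nwk <- neighbor_joining(d)
  pca <- pca_frequencies(table, standardize = standardize)
  clust <- hierarchical_clustering(table, method = linkage)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_distance_matrix(d, file.path(outdir, "nei_distances.csv"),
                          file.path(outdir, "nei_distances.phy"))
    writeLines(as.character(nwk), file.path(outdir, "nj_tree.nwk"))
    utils::write.csv(as.data.frame(pca$scores),
                     file.path(outdir, "pca_scores.csv"), row.names = TRUE)
    utils::write.csv(as.data.frame(pca$loadings),
                     file.path(outdir, "pca_loadings.csv"), row.names = TRUE)
    jsonlite::write_json(list(leaf_order = clust$leaf_order,
                              merge_heights = clust$merge_heights,
                              linkage = linkage,
                              explained_variance = pca$explained_variance),
                         file.path(outdir, "clustering.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(distances = d, newick = nwk, pca = pca, clustering = clust)
}
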