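#!/usr/bin/env Rscript
# Stage 5: inter-population comparison.
#
# Nei (1972) standard genetic distances on the population x gene carrier
# frequency table (study frequencies + synthetic archetype populations +
# the simulated cohort), the neighbor-joining dendrogram, correlation PCA
# and Euclidean complete-linkage clustering; repeated on the 14-gene panel
# (pseudogenes excluded) as done for panels lacking KIR2DP1/KIR3DP1.
# Outputs under results/comparison/.

suppressPackageStartupMessages(library(kirpop))
outdir <- "results/comparison"

pf <- read_population_frequencies("results/cohort/population_frequencies.csv")
cat("Populations:", paste(pf$population, collapse = ", "), "\n\n")

res <- suppressWarnings(run_population_comparison(pf, outdir = outdir))
cat("Nei distances (rounded):\n")
print(round(res$distances, 4))
cat("\nNJ tree:\n", as.character(res$newick), "\n")
cat("\nPCA explained variance (first 3 PCs): ",
    paste(sprintf("%.1f%%", 100 * res$pca$explained_variance[1:3]),
          collapse = ", "), "\n", sep = "")
lead <- rownames(res$pca$loadings)[order(-abs(res$pca$loadings[, 1]))][1:3]
cat("PC1 dominated by:", paste(lead, collapse = ", "), "\n")
cat("Clustering leaf order:", paste(res$clustering$leaf_order, collapse = " | "),
    "\n")

# 14-gene restriction (no pseudogenes)
g14 <- setdiff(kir_panel()$genes, c("KIR2DP1", "KIR3DP1"))
res14 <- suppressWarnings(
  run_population_comparison(pf, genes = g14,
                            outdir = file.path(outdir, "panel14")))
cat("\n14-gene panel leaf order:",
    paste(res14$clustering$leaf_order, collapse = " | "), "\n")

# optional heatmap rendering when pheatmap is available
if (requireNamespace("pheatmap", quietly = TRUE)) {
  m <- as.matrix(pf[, attr(pf, "genes")])
  rownames(m) <- pf$population
  grDevices::pdf(file.path(outdir, "heatmap.pdf"), width = 8, height = 5)
  pheatmap::pheatmap(m, clustering_method = "complete",
                     clustering_distance_rows = "euclidean",
                     main = "KIR carrier frequencies")
  grDevices::dev.off()
  cat("Heatmap written to", file.path(outdir, "heatmap.pdf"), "\n")
}
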