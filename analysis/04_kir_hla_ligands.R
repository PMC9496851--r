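#!/usr/bin/env Rscript
# Stage 4: KIR-HLA ligand combinations on the simulated cohort.
#
# Classifies the allele-level HLA typing into ligand groups (C1/C2, Bw4,
# Bw4-80I, A3/A11, C*16), builds the four-state KIR-ligand combination
# table, the inhibitory-pair multiplicity distribution and the ligand
# carriage summary. Outputs under results/ligands/.

suppressPackageStartupMessages(library(kirpop))
outdir <- "results/ligands"

g <- read_genotype_table("results/cohort/genotypes.csv")
hla <- read_hla_table("results/cohort/hla.csv")
res <- run_ligand_analysis(g, hla, outdir = outdir)

cat("Ligand carriage (% of typed individuals):\n")
print(transform(res$carriage, percent = round(percent, 2)), row.names = FALSE)

cat("\nKIR-HLA four-state combinations (n = evaluated individuals):\n")
print(transform(res$pair_table[, c("pair", "class", "pp", "pa", "ap", "aa",
                                   "n", "n_excluded")],
                pp_pct = round(res$pair_table$pp_pct, 1)),
      row.names = FALSE)

m <- res$multiplicity
cat("\nInhibitory pair multiplicity (", attr(m, "n_evaluated"),
    " HLA-C-typed individuals, ", attr(m, "n_excluded"), " excluded):\n",
    sep = "")
print(transform(m, percent = round(percent, 2)), row.names = FALSE)
cat("Totals by cardinality:\n")
print(attr(m, "cardinality_totals"))
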