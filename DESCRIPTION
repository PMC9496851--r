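Package: kirpop
Title: KIR Gene-Content Diversity, Haplotype Inference and Population
    Comparison
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of killer-cell immunoglobulin-like receptor (KIR)
    gene-content (presence/absence) genotyping in diploid cohorts: carrier
    frequencies, Bernstein gene frequencies with Wald-type confidence
    intervals, genotype cataloguing with AA/Bx classification,
    constraint-based haplotype inference with EM frequency estimation under
    Hardy-Weinberg equilibrium, KIR-HLA ligand combination tables, and
    inter-population comparison via Nei (1972) standard genetic distance,
    neighbour-joining dendrograms, principal component analysis and
    hierarchical clustering. Includes a seeded synthetic cohort generator
    so every stage runs without individual-level study data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
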