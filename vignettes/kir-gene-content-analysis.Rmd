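---
title: "KIR gene-content analysis: models, assumptions and design choices"
author: "kirpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KIR gene-content analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirpop)
```

# The problem

Killer-cell immunoglobulin-like receptors (KIR) are a family of activating
and inhibitory NK-cell receptors encoded in a ~150 kb cluster on chromosome
19q13.4. Routine KIR typing (PCR-SSO/SSP) reports only *gene content*:
presence or absence of each of 16 loci (14 expressed genes and the
pseudogenes KIR2DP1/KIR3DP1), not copy number or alleles. Four *framework*
genes (KIR3DL3, KIR3DP1, KIR2DL4, KIR3DL2) sit on essentially every
haplotype; genotypes carrying none of the seven B-specific genes (KIR2DL2,
2DL5, 2DS1, 2DS2, 2DS3, 2DS5, 3DS1) are labelled AA, all others Bx (A/B
heterozygotes and B/B homozygotes are indistinguishable from gene content).

`kirpop` implements the complete analysis chain for such data in a diploid
cohort: frequency estimation, genotype cataloguing, haplotype inference,
KIR-HLA ligand combination tables, and inter-population comparison, plus a
synthetic cohort generator so every stage is testable without
individual-level data.

# Frequency estimation

The carrier frequency of a gene is the direct-count fraction CF = k/N.
Under Hardy-Weinberg equilibrium (HWE) a locus with gene (haplotype-level)
frequency GF is absent from an individual with probability $(1-GF)^2$,
giving Bernstein's estimator

$$GF = 1 - \sqrt{1 - CF}.$$

The confidence interval is the Wald-type
$GF \pm z_{1-\alpha/2}\sqrt{GF(1-GF)/n}$ with $n = 2N$ *gene copies* as the
denominator. Both choices — the normal quantile (1.96 at 95%) for the
multiplier and 2N for the denominator — were fixed by verifying that they
reproduce the published interval tables this package models; the tests pin
that behaviour. Two cells of those published tables sit exactly on a 0.05
rounding boundary (the upper CI bound for the 153-carrier genes computes to
82.2549, printed as 82.2; the KIR2DS2 gene frequency computes to 31.748,
printed as 31.8). The implementation keeps the unrounded formula values and
the acceptance tests document the two cells explicitly; `round_half_up()`
is provided because the printed tables round ties away from zero, which
base `round()` does not.

KIR2DS4 occurs as a full-length (F) and a 22-bp-deleted, non-expressed (D)
variant. Typing reports which variants are detected, so individuals fall in
categories FF (only F seen — including hemizygotes), FD, DD.
`ds4_variant_frequencies()` applies Bernstein's equation *per category*,
reproducing the arithmetic of the modelled study. This is deliberately not
a proper two-allele frequency estimator (the categories are not genotype
counts at a biallelic locus); it is documented as study-faithful behaviour.

# Haplotype inference

## The constraint model

Inference from unphased gene content uses a reference set of cen~tel
haplotypes (Vierra-Green nomenclature, e.g. `cA01~tB01 2DS5`) and four
structural rules: framework genes are always present (I); KIR2DL5 implies
KIR2DS3 and/or KIR2DS5 (II); KIR2DL2 and KIR2DL3 are mutually exclusive on
one haplotype (III); KIR2DS4 implies KIR3DL1 (IV). A pair of reference
haplotypes *explains* a genotype when the union of their gene sets equals
the observed present set exactly. Because the KIR2DS3/2DS5 locus is
duplicated across the centromeric and telomeric motifs, haplotypes are
matched on total gene content only; motif-level placement is metadata.

The bundled reference file carries the seven most frequent haplotypes of
the modelled population. The study's full 23-haplotype appendix is not
available in the source text, so the gene content of `cA01~tB05` was fixed
from the structure of telomeric-B variants as {2DL4, 3DS1, 2DS1, 3DL2} (a
tB01-like motif lacking the 2DL5/2DS5 cassette); the file is plain CSV and
user-replaceable, and every entry is re-validated against rules I-IV on
load.

## EM under HWE

With haplotype frequencies $f$ on a simplex, HWE makes an unordered pair
$(a,b)$ occur with probability $c\,f_a f_b$ ($c=2$ for $a \ne b$). The
likelihood of a genotype is the sum over its compatible pairs, and
`em_haplotype_frequencies()` maximises the product over individuals by EM:
the E-step distributes each individual over its compatible pairs
proportionally to $c f_a f_b$, the M-step re-estimates $f$ from expected
allele counts over $2N$ chromosomes. Initialisation is uniform,
convergence is `max |Δf| < 1e-8` (default) with a 1000-iteration cap; the
log-likelihood trace is retained and is nondecreasing by construction. The
landscape at this scale is effectively unimodal, so no random restarts are
used and the fit is deterministic.

Genotypes matched by *no* reference pair are not discarded. They are
explained through a *residual* class: if some reference haplotype's gene
set is contained in the profile, the individual is modelled as (reference,
residual); otherwise as (residual, residual). This was a genuinely open
design point, and the exclusion alternative (dropping unexplained
individuals from the likelihood) was rejected for a structural reason: an
excluded individual usually carries one chromosome that *is* a reference
haplotype, and dropping it deflates every reference frequency — with ~8%
unrepresented haplotype mass the bias (~0.03 on the major haplotype)
exceeds sampling error at realistic cohort sizes. With the residual class,
estimated reference frequencies plus the residual mass lie on one simplex,
recovery is unbiased (the parameter-recovery test at n = 2000 confirms
estimates within 3 binomial SE), and the residual reproduces the
"explained haplotype mass" accounting of pattern-based inference tools.

`resolution_summary()` reports the same structure at the individual level:
both chromosomes resolved (an exact pair exists), one resolved (a reference
contained in the profile, remainder unexplained), or neither, with
explained chromosomes / 2N as a percentage. Haplotypes estimated below
eight chromosomes are flagged `below_threshold` in the frequency table —
the confidence cut-off of the modelled study — rather than dropped.

Known limitation: if the true unrepresented haplotype's union with a
reference haplotype coincides with the union of two references, such
individuals are silently "resolved" to the wrong pair. With the bundled
reference set and the synthetic rare haplotype this affects ~1% of
simulated individuals and biases the affected frequencies by < 0.005,
well inside the acceptance band; it is an intrinsic ambiguity of
gene-content data, not an implementation artefact.

# KIR-HLA ligand combinations

HLA class I epitopes gate KIR function: C1/C2 (HLA-C position 80), Bw4
(HLA-B plus A*23/24/32), its isoleucine-80 subset Bw4-80I, A3/A11, and
C*16 as a separately tracked group. `classify_ligands()` maps allele-group
typing (two-digit resolution, the resolution of SSO/SSP studies) through
an editable lookup CSV; flags are unions over typed alleles, so adding an
allele can only switch flags on. Known group-level ambiguities (B-groups
mixing 80I/80T alleles) are resolved in favour of the majority allele and
the lookup restricts Bw4-80I to B-locus groups, the convention for the
KIR3DS1 ligand; both choices live in the data file, not the code.

`kir_hla_pair_table()` produces four-state (present/present ...
absent/absent) tables per receptor-ligand pair — the four cells always
partition the evaluated cohort — and `inhibitory_pair_multiplicity()`
groups individuals by how many of the four canonical inhibitory pairs
(2DL1+C2, 2DL2/3+C1, 3DL1+Bw4, 3DL2+A3/11) they satisfy. KIR2DS4F pairs
require a full-length copy (zygosity FF or FD). Individuals without HLA-C
typing — common in registry data — are excluded from C-dependent pairs
with explicit accounting, never silently.

# Population comparison

`nei_distance()` implements Nei's (1972) standard distance treating each
locus as biallelic with allele frequencies (p, 1-p), p being the *carrier*
frequency — deliberately so, because published KIR comparison tables are
carrier-frequency tables; Bernstein-converted frequencies can be fed
through the same function for sensitivity analysis. Identity zero returns
`Inf` explicitly. Trees come from Saitou-Nei neighbor joining (`ape::nj`)
with negative branches clamped to zero and the deficit moved to the
sibling branch (NJ's usual clamp-and-transfer convention; the choice only
matters on non-additive inputs — on additive matrices the generating tree
is recovered exactly, which the tests assert to 1e-9). PCA defaults to the
correlation form (unit-scaled genes), matching correlation-circle biplots;
each component's sign is fixed so its dominant loading is positive.
Hierarchical clustering uses Euclidean distance with complete linkage (the
common heatmap default; configurable). Panels lacking the pseudogenes are
handled by restricting the gene set for the *whole* analysis — never by
imputation.

# The synthetic cohort generator

`simulate_kir_population()` draws, per individual, two haplotypes i.i.d.
from a frequency vector (HWE) and unions their gene content. The defaults
are the study conditions this package models: N = 161; the seven reference
haplotype frequencies (41.615, 16.46, 10.87, 9.938, 5.901, 4.969, 2.484%);
and the remaining 7.76% assigned to a rare haplotype (framework + 2DL3 +
2DS3) that is structurally valid but absent from the reference file, so
simulated cohorts exercise the partially- and un-resolved paths.
KIR2DS4-bearing chromosomes are full-length with probability 2/3, the F:D
ratio of the study's calculated variant frequencies.

`simulate_hla_ligands()` draws ligand flags as independent Bernoulli at
the study's marginal rates (C1 = Bw4 = 0.87, C2 = 0.5839, A3/A11 =
0.2236), with nesting enforced where epitopes are structurally nested:
C*16 within C1; Bw4 provenance drawn conditionally on Bw4 so the A- and
B-locus margins match; Bw4-80I within B-locus Bw4; A3/A11 mutually
exclusive at a 26:10 split. KIR genotype and HLA carriage are independent
in the generator — the analyses examine their joint distribution but the
generating model deliberately contains no dependence, so any association
found by the pair tables on simulated data is sampling noise.

One seed drives everything; the HLA stream uses a fixed large offset of
the seed so the two tables are reproducible independently and mutually
non-correlated. `write_fixture_bundle()` emits a five-file mini-study
(genotypes, allele-level HLA typing, reference haplotypes, genotype
catalog, population frequency table). Two generator realism caveats: flag
independence occasionally produces individuals with neither C1 nor C2
(genotypically impossible), which the bundle writer emits as HLA-C
untyped, mirroring partially missing registry typing; and gene-level
marginals (e.g. the KIR2DS4 carrier rate) follow from the 7-haplotype
model, not from the study's per-gene table, so they agree only
approximately. Passing tests on synthetic data therefore demonstrate
correctness of the machinery under the stated model, not distributional
realism of real cohorts (no linkage beyond the haplotype list, no allelic
diversity, no admixture structure).

# Numerical and interface choices

- Presence encodings accepted: `1/0` and `POS/NEG` (case-insensitive);
  anything else is a hard error naming row and column. Missing panel
  columns and duplicate individual IDs are hard errors; absent framework
  genes are warning-level findings (real data contain rare exceptions).
- Genotype IDs come from a catalog file; contents not in the catalog get
  sequential `NPR` labels in first-encounter order, stable within a run.
  The bundled catalog is synthetic (built from reference-pair unions)
  because published per-genotype content tables are not machine-readable;
  it is user-replaceable, and catalog entries with duplicate content are
  rejected.
- Frequency tables order by descending count with ties broken by ID/name
  ascending (numeric-aware for catalog IDs).
- Full precision is kept in all returned objects and long-format CSVs;
  only the wide "publication-style" CSV rounds (half-up, one decimal).
- Analysis problem sizes used by the test-suite: parameter recovery at
  n = 2000 individuals, generator calibration checks at n = 50,000,
  enumeration/NJ/Nei property checks at 500/100/25 random cases — sizes at
  which binomial standard errors are small enough to detect the biases
  discussed above.

# Reproducing the workflow

The `analysis/` directory contains the numbered drivers
(`01_simulate_cohort.R` ... `05_population_comparison.R`) writing under
`results/`; `scripts/acceptance.R --seed <int> --out <path>` recomputes
the headline published quantities (gene frequencies and CI bounds from the
published direct counts, and the KIR2DS4 variant conversion) from scratch
against the installed package.
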