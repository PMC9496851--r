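# kirpop — KIR gene-content diversity, haplotype inference and population comparison

`kirpop` is an R package for analysing **killer-cell immunoglobulin-like
receptor (KIR) gene-content data** — the presence/absence typing of the 16
KIR loci produced by PCR-SSO/SSP kits — in diploid cohorts, for
immunogeneticists characterising NK-cell receptor diversity in a
population. It implements the full analysis chain of a population KIR
study:

- **Frequencies.** Carrier frequencies by direct count (CF = k/N),
  gene frequencies by Bernstein's equation under Hardy–Weinberg
  equilibrium, GF = 1 − √(1 − CF), with Wald-type confidence intervals
  GF ± z·√(GF(1−GF)/2N) on gene copies; KIR2DS4 full-length/deleted
  variant frequencies.
- **Genotypes.** AA/Bx classification (AA ⇔ no B-specific gene present),
  catalog-based genotype IDs with stable `NPR` labels for contents never
  reported before, and direct-count genotype frequency tables.
- **Haplotypes.** Constraint-based enumeration of reference-haplotype
  pairs whose gene-content union matches each genotype (under the four
  structural rules: framework genes always present; 2DL5 ⇒ 2DS3/2DS5;
  2DL2 xor 2DL3; 2DS4 ⇒ 3DL1), followed by EM estimation of haplotype
  frequencies maximising the HWE multinomial likelihood
  ∏ᵢ Σ₍ₐ,ᵦ₎ c·f(a)f(b), with a residual class for unrepresented
  haplotypes and per-individual resolution statistics.
- **KIR–HLA ligands.** Allele-group classification into C1/C2, Bw4,
  Bw4-80I, A3/A11 and C\*16; four-state receptor–ligand combination
  tables; inhibitory-pair multiplicity distributions.
- **Population comparison.** Nei (1972) standard genetic distance
  D = −ln(J_xy/√(J_x·J_y)) on carrier-frequency tables, neighbor-joining
  dendrograms (Newick), correlation PCA biplot ingredients, and
  Euclidean/complete hierarchical clustering.
- **Synthetic cohorts.** A seeded generator drawing diploid individuals
  under HWE from configurable haplotype frequencies, with matching HLA
  ligand carriage, so the whole pipeline runs and is tested without any
  individual-level study data.

## Worked example

Simulate a 161-individual cohort at the default study conditions and push
it through frequency estimation and haplotype inference:

```r
library(kirpop)

cfg  <- sim_config(n = 161, seed = 2776)
g    <- simulate_kir_population(cfg)
refs <- default_reference_haplotypes()

table(classify_ab(g))
#>  AA  Bx
#>  28 133

run_haplotype_analysis(g, refs)$table
#>            name count   percent below_threshold
#>       cA01~tA01   140 43.471762           FALSE
#>  cA01~tB01 2DS5    48 14.813170           FALSE
#>       cB02~tB01    48 14.900689           FALSE
#>       cB02~tA01    23  7.004657           FALSE
#>  cB01~tA01 2DS3    21  6.666437           FALSE
#>       cA01~tB05    19  6.000782           FALSE
#>  cB01~tB01 2DS3     4  1.241881            TRUE
```

Counts are chromosomes out of 2n = 322; percentages are haplotype
frequencies; `below_threshold` flags haplotypes inferred on fewer than
eight chromosomes (the usual confidence cut-off). With this seed, 143
individuals resolve on both chromosomes, 17 on one, 1 on neither, and the
residual (unexplained) mass is 5.9% — the generator plants 7.76% of
chromosome mass on a haplotype deliberately absent from the reference set.

Feeding published per-gene direct counts through the frequency chain
reproduces a publication-style table:

```r
rec <- kir_frequency_records(c(KIR2DL1 = 153, KIR2DS3 = 32, KIR3DS1 = 115), 161)
round_half_up(100 * rec$gf, 1)
#> [1] 77.7 10.5 46.5
round_half_up(100 * rec$ci_upper, 1)
#> [1] 82.3 13.8 52.0
```

i.e. 153/161 carriers give CF 95.0%, gene frequency 77.7% and a 95% CI of
73.2–82.3%. The numbered drivers under `analysis/` run the complete
workflow (simulation → frequencies → haplotypes → ligand combinations →
population comparison), writing tables, Newick trees and JSON reports
under `results/`.

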