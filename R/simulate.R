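#' Default haplotype frequencies for the synthetic cohort
#'
#' The seven reference haplotype frequencies of the modelled admixed
#' population (fractions of 322 chromosomes), with the remaining 7.76%
#' mass assigned to a synthetic rare haplotype (`"rare-unref"`: framework
#' genes + KIR2DL3 + KIR2DS3) that satisfies structural rules I-IV but is
#' absent from the reference file, so that simulated cohorts exercise the
#' one-resolved and unresolved paths of the inference.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_haplotype_frequencies <- function() {
  f <- c("cA01~tA01" = 0.41615, "cA01~tB01 2DS5" = 0.1646,
         "cB02~tB01" = 0.1087, "cB02~tA01" = 0.09938,
         "cA01~tB05" = 0.05901, "cB01~tA01 2DS3" = 0.04969,
         "cB01~tB01 2DS3" = 0.02484)
  c(f, "rare-unref" = 1 - sum(f))
}

rare_haplotype_content <- function(panel = kir_panel()) {
  g <- c("KIR3DL3", "KIR3DP1", "KIR2DL4", "KIR3DL2", "KIR2DL3", "KIR2DS3")
  stats::setNames(panel$genes %in% g, panel$genes)
}

#' Simulation configuration
#'
#' Study conditions for the synthetic generator: 161 diploid individuals
#' drawn under Hardy-Weinberg equilibrium from the default haplotype
#' frequencies; HLA ligand carriage at the study rates (C1 and Bw4 0.87,
#' C2 0.5839, A3/A11 combined 0.2236); KIR2DS4 chromosomes carry the
#' full-length allele with probability 2/3 (the 2:1 ratio of the
#' full-length to deleted calculated gene frequencies).
#'
#' @param n Number of diploid individuals.
#' @param haplotype_freqs Named frequency vector (must sum to 1 within
#'   1e-9); names absent from the reference set are treated as
#'   unrepresented haplotypes.
#' @param seed Integer seed; one seed reproduces the whole cohort.
#' @param ligand_rates Named carriage rates (`C1`, `C2`, `Bw4`, `A3_A11`,
#'   `C16`, `Bw4_80I_given_B`, `Bw4_from_B_given_Bw4`,
#'   `Bw4_from_A_given_Bw4`, `A3_share`).
#' @param ds4_full_fraction Probability that a KIR2DS4-bearing chromosome
#'   carries the full-length (expressed) variant.
#' @return List of class `kir_sim_config`.
#' @export
sim_config <- function(n = 161L,
                       haplotype_freqs = default_haplotype_frequencies(),
                       seed = 1L,
                       ligand_rates = c(C1 = 0.87, C2 = 0.5839, Bw4 = 0.87,
                                        A3_A11 = 0.2236, C16 = 0.0807,
                                        Bw4_from_B_given_Bw4 = 94 / 140,
                                        Bw4_from_A_given_Bw4 = 82 / 140,
                                        Bw4_80I_given_B = 0.64,
                                        A3_share = 26 / 36),
                       ds4_full_fraction = 2 / 3) {
  if (n < 1L) stop("n must be at least 1")
  if (abs(sum(haplotype_freqs) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1 (got ", sum(haplotype_freqs), ")")
  }
  if (any(haplotype_freqs < 0)) stop("haplotype frequencies must be nonnegative")
  if (any(ligand_rates < 0 | ligand_rates > 1)) stop("rates must lie in [0, 1]")
  if (ds4_full_fraction < 0 || ds4_full_fraction > 1) {
    stop("ds4_full_fraction must lie in [0, 1]")
  }
  structure(list(n = as.integer(n), haplotype_freqs = haplotype_freqs,
                 seed = as.integer(seed), ligand_rates = ligand_rates,
                 ds4_full_fraction = ds4_full_fraction),
            class = "kir_sim_config")
}

# Gene-content matrix for the simulated haplotype pool: reference
# haplotypes by name, plus the synthetic rare haplotype for names not in
# the reference file.
sim_haplotype_pool <- function(freqs, refs, panel) {
  m <- hap_matrix(refs, panel)
  out <- matrix(FALSE, length(freqs), length(panel$genes),
                dimnames = list(names(freqs), panel$genes))
  for (nm in names(freqs)) {
    if (nm %in% rownames(m)) {
      out[nm, ] <- m[nm, ]
    } else {
      out[nm, ] <- rare_haplotype_content(panel)
    }
  }
  out
}

#' Simulate a KIR gene-content cohort under Hardy-Weinberg equilibrium
#'
#' Each individual receives two haplotypes drawn independently from the
#' configured frequency vector; the observed genotype is the union of
#' their gene contents. KIR2DS4 variant calls mimic presence/absence
#' typing of the full-length (F) and deleted (D) alleles: FF when only F
#' alleles are present (including hemizygotes), FD when both, DD when only
#' D. The generating diplotype of every individual is attached for
#' recovery testing.
#'
#' @param config A [sim_config()].
#' @param refs Reference haplotypes providing gene contents.
#' @param panel A [kir_panel()].
#' @return A [kir_genotypes()] table with attribute `truth`: data.frame
#'   `individual_id`, `hap_a`, `hap_b`.
#' @export
simulate_kir_population <- function(config = sim_config(),
                                    refs = default_reference_haplotypes(),
                                    panel = kir_panel()) {
  set.seed(config$seed)
  pool <- sim_haplotype_pool(config$haplotype_freqs, refs, panel)
  K <- nrow(pool)
  n <- config$n
  draws <- matrix(sample.int(K, 2L * n, replace = TRUE,
                             prob = config$haplotype_freqs), ncol = 2L)
  present <- pool[draws[, 1L], , drop = FALSE] | pool[draws[, 2L], , drop = FALSE]
  ds4_hap <- matrix(pool[, "KIR2DS4"][draws], ncol = 2L)
  # each 2DS4-bearing chromosome is full-length with prob ds4_full_fraction
  full <- matrix(stats::runif(2L * n) < config$ds4_full_fraction, ncol = 2L) & ds4_hap
  deleted <- ds4_hap & !full
  z <- ifelse(!present[, "KIR2DS4"], NA_character_,
              ifelse(rowSums(full) > 0 & rowSums(deleted) > 0, "FD",
                     ifelse(rowSums(full) > 0, "FF", "DD")))
  ids <- sprintf("S%04d", seq_len(n))
  out <- kir_genotypes(ids, present, z, panel)
  attr(out, "truth") <- data.frame(individual_id = ids,
                                   hap_a = rownames(pool)[draws[, 1L]],
                                   hap_b = rownames(pool)[draws[, 2L]],
                                   stringsAsFactors = FALSE)
  out
}

#' Simulate HLA ligand carriage
#'
#' Per-individual Bernoulli carriage at the configured marginal rates,
#' independent of the KIR genotype (no KIR-HLA dependence is modelled).
#' Internal consistency is enforced where epitopes are nested: C*16 is a
#' sub-event of C1; Bw4 provenance (A- and/or B-locus) is drawn
#' conditionally on Bw4 so the marginals match; Bw4-80I is a sub-event of
#' B-locus Bw4 (the bundled lookup restricts 80I to HLA-B groups); A3 and
#' A11 split the combined A3/A11 rate and are mutually exclusive.
#'
#' @param config A [sim_config()].
#' @return A data.frame of class `kir_ligands` with the same columns as
#'   [classify_ligands()] output, plus attribute `hla`: an allele-level
#'   typing table consistent with the flags (individuals simulated with
#'   neither C1 nor C2 are emitted as HLA-C untyped).
#' @export
simulate_hla_ligands <- function(config = sim_config()) {
  # offset keeps the HLA stream independent of the KIR stream under one seed
  set.seed(config$seed + 1000003L)
  n <- config$n
  r <- config$ligand_rates
  C1 <- stats::runif(n) < r[["C1"]]
  C2 <- stats::runif(n) < r[["C2"]]
  C16 <- C1 & (stats::runif(n) < r[["C16"]] / r[["C1"]])
  Bw4 <- stats::runif(n) < r[["Bw4"]]
  pB <- r[["Bw4_from_B_given_Bw4"]]
  pA <- r[["Bw4_from_A_given_Bw4"]]
  # joint provenance: P(both) chosen so the conditional margins are matched
  p_both <- max(0, pB + pA - 1)
  u <- stats::runif(n)
  from_B <- Bw4 & (u < pB)
  from_A <- Bw4 & (u >= pB - p_both)
  Bw4_80I <- from_B & (stats::runif(n) < r[["Bw4_80I_given_B"]])
  a3a11 <- stats::runif(n) < r[["A3_A11"]]
  A3 <- a3a11 & (stats::runif(n) < r[["A3_share"]])
  A11 <- a3a11 & !A3
  out <- data.frame(individual_id = sprintf("S%04d", seq_len(n)),
                    C1 = C1, C2 = C2, Bw4 = Bw4, Bw4_80I = Bw4_80I,
                    Bw4_from_A = from_A, Bw4_from_B = from_B,
                    A3 = A3, A11 = A11, C16 = C16,
                    stringsAsFactors = FALSE)
  out$A3_A11 <- out$A3 | out$A11
  out$c_typed <- out$C1 | out$C2
  attr(out, "hla") <- ligand_flags_to_hla(out)
  structure(out, class = c("kir_ligands", "data.frame"))
}

# Representative allele-group typing consistent with a flag table; used to
# write round-trippable HLA fixtures. Individuals carrying neither C1 nor
# C2 (possible under independent flag draws, impossible genotypically) are
# written as HLA-C untyped.
ligand_flags_to_hla <- function(flags) {
  n <- nrow(flags)
  pick_c <- function(i) {
    c1 <- if (flags$C16[i]) "C*16" else "C*07"
    if (flags$C1[i] && flags$C2[i]) c(c1, "C*04")
    else if (flags$C1[i]) c(c1, "C*12")
    else if (flags$C2[i]) c("C*04", "C*06")
    else c(NA_character_, NA_character_)
  }
  pick_b <- function(i) {
    if (flags$Bw4_from_B[i]) {
      b1 <- if (flags$Bw4_80I[i]) "B*51" else "B*44"
      c(b1, "B*07")
    } else c("B*07", "B*35")
  }
  pick_a <- function(i) {
    a <- character(0)
    if (flags$A3[i]) a <- c(a, "A*03")
    if (flags$A11[i]) a <- c(a, "A*11")
    if (flags$Bw4_from_A[i]) a <- c(a, "A*24")
    c(a, "A*01", "A*02")[1:2]
  }
  m <- t(vapply(seq_len(n), function(i) c(pick_a(i), pick_b(i), pick_c(i)),
                character(6)))
  colnames(m) <- c("A_1", "A_2", "B_1", "B_2", "C_1", "C_2")
  data.frame(individual_id = flags$individual_id, m,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a complete synthetic study bundle
#'
#' Produces an internally consistent mini-study in `outdir`: the genotype
#' table, the allele-level HLA table, copies of the bundled reference
#' haplotype file and synthetic genotype catalog, and a population x gene
#' carrier-frequency table combining the simulated cohort with the bundled
#' synthetic comparison populations. Every analysis stage can run
#' end-to-end from these five files.
#'
#' @param outdir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture_bundle <- function(outdir, config = sim_config()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  panel <- kir_panel()
  refs <- default_reference_haplotypes(panel)
  geno <- simulate_kir_population(config, refs, panel)
  lig <- simulate_hla_ligands(config)

  paths <- c(genotypes = file.path(outdir, "genotypes.csv"),
             hla = file.path(outdir, "hla.csv"),
             reference_haplotypes = file.path(outdir, "reference_haplotypes.csv"),
             genotype_catalog = file.path(outdir, "genotype_catalog.csv"),
             population_frequencies = file.path(outdir, "population_frequencies.csv"))

  gm <- presence_matrix(geno, panel)
  gdf <- data.frame(individual_id = geno$individual_id,
                    ifelse(gm, 1L, 0L),
                    ds4_zygosity = ifelse(is.na(geno$ds4_zygosity), "",
                                          geno$ds4_zygosity),
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(gdf, paths[["genotypes"]], row.names = FALSE, quote = FALSE)

  hla <- attr(lig, "hla")
  hla[is.na(hla)] <- ""
  utils::write.csv(hla, paths[["hla"]], row.names = FALSE, quote = FALSE)

  file.copy(system.file("extdata", "reference_haplotypes.csv",
                        package = "kirpop", mustWork = TRUE),
            paths[["reference_haplotypes"]], overwrite = TRUE)
  file.copy(system.file("extdata", "genotype_catalog_synthetic.csv",
                        package = "kirpop", mustWork = TRUE),
            paths[["genotype_catalog"]], overwrite = TRUE)

  base <- utils::read.csv(system.file("extdata",
                                      "population_carrier_frequencies_synthetic.csv",
                                      package = "kirpop", mustWork = TRUE),
                          check.names = FALSE, comment.char = "#")
  cohort_cf <- colSums(gm) / nrow(gm)
  sim_row <- data.frame(population = "SimulatedCohort", n = nrow(gm),
                        region = "synthetic",
                        as.list(round(cohort_cf, 6)),
                        stringsAsFactors = FALSE, check.names = FALSE)
  combined <- rbind(sim_row[, names(base)], base)
  utils::write.csv(combined, paths[["population_frequencies"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
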