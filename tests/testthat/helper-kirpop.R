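# Shared fixtures built in code: tiny cohorts, random valid haplotypes and
# independently coded oracles used by the property tests.

PANEL <- kir_panel()

# A-haplotype background used when toggling B-specific genes.
A_BACKGROUND <- c("KIR3DL3", "KIR2DL3", "KIR2DP1", "KIR2DL1", "KIR3DP1",
                  "KIR2DL4", "KIR3DL1", "KIR2DS4", "KIR3DL2")

# Build a kir_genotypes table from a list of gene-name character vectors.
make_profiles <- function(contents, ids = NULL, ds4 = NULL) {
  if (is.null(ids)) ids <- paste0("I", seq_along(contents))
  m <- t(vapply(contents, function(g) PANEL$genes %in% g,
                logical(length(PANEL$genes))))
  colnames(m) <- PANEL$genes
  kir_genotypes(ids, m, ds4, PANEL)
}

# Minimal ligand flag table for pair/multiplicity tests.
make_ligand_flags <- function(ids, ..., c_typed = TRUE) {
  flags <- list(...)
  out <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (fl in c("C1", "C2", "Bw4", "Bw4_80I", "Bw4_from_A", "Bw4_from_B",
               "A3", "A11", "C16")) {
    out[[fl]] <- if (fl %in% names(flags)) rep_len(flags[[fl]], length(ids))
                 else rep(FALSE, length(ids))
  }
  out$A3_A11 <- out$A3 | out$A11
  out$c_typed <- rep_len(c_typed, length(ids))
  structure(out, class = c("kir_ligands", "data.frame"))
}

# Random gene-content haplotype satisfying structural rules I-IV.
random_valid_haplotype <- function() {
  repeat {
    present <- stats::setNames(PANEL$genes %in% PANEL$framework, PANEL$genes)
    optional <- setdiff(PANEL$genes, PANEL$framework)
    present[optional] <- stats::runif(length(optional)) < 0.5
    if (present["KIR2DL2"] && present["KIR2DL3"]) {
      drop <- sample(c("KIR2DL2", "KIR2DL3"), 1)
      present[drop] <- FALSE
    }
    if (present["KIR2DL5"] && !(present["KIR2DS3"] || present["KIR2DS5"])) {
      present[sample(c("KIR2DS3", "KIR2DS5"), 1)] <- TRUE
    }
    if (present["KIR2DS4"] && !present["KIR3DL1"]) present["KIR3DL1"] <- TRUE
    if (length(check_haplotype_rules(present, PANEL)) == 0L) return(present)
  }
}

# Random reference set of k distinct valid haplotypes as a kir_haplotypes-like
# data.frame (built directly, bypassing the CSV reader).
random_reference_set <- function(k) {
  haps <- list()
  while (length(haps) < k) {
    h <- random_valid_haplotype()
    key <- paste(which(h), collapse = ",")
    if (!key %in% names(haps)) haps[[key]] <- h
  }
  m <- do.call(rbind, haps)
  out <- data.frame(name = paste0("H", sprintf("%02d", seq_len(k))),
                    cen_motif = "synthetic", tel_motif = "synthetic",
                    m, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("kir_haplotypes", "data.frame"), panel = PANEL)
}

# Independent brute-force oracle for diplotype enumeration: naive double loop
# over unordered pairs comparing union sets element-wise.
brute_force_diplotypes <- function(present_genes, refs) {
  hits <- list()
  for (i in seq_len(nrow(refs))) {
    for (j in i:nrow(refs)) {
      gi <- PANEL$genes[as.logical(refs[i, PANEL$genes])]
      gj <- PANEL$genes[as.logical(refs[j, PANEL$genes])]
      if (setequal(union(gi, gj), present_genes)) {
        pair <- sort(c(refs$name[i], refs$name[j]))
        hits[[length(hits) + 1L]] <- pair
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(hap_a = character(), hap_b = character()))
  }
  out <- unique(do.call(rbind, hits))
  data.frame(hap_a = out[, 1], hap_b = out[, 2], stringsAsFactors = FALSE)
}

# Independent Nei-1972 oracle: explicit per-locus accumulation.
nei_oracle <- function(px, py) {
  jx <- 0; jy <- 0; jxy <- 0
  for (l in seq_along(px)) {
    ax <- c(px[l], 1 - px[l])
    ay <- c(py[l], 1 - py[l])
    jx <- jx + sum(ax^2)
    jy <- jy + sum(ay^2)
    jxy <- jxy + sum(ax * ay)
  }
  -log(jxy / sqrt(jx * jy))
}

# Frequency table wrapper for a bare matrix of carrier frequencies.
make_pop_table <- function(m, populations = rownames(m)) {
  out <- data.frame(population = populations, n = 100L,
                    m, stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, class = c("kir_pop_freq", "data.frame"), genes = colnames(m))
}

ref_gene_set <- function(refs, name) {
  PANEL$genes[as.logical(refs[refs$name == name, PANEL$genes])]
}
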