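LIGAND_FLAGS <- c("C1", "C2", "Bw4", "Bw4_80I", "Bw4_from_A", "Bw4_from_B",
                  "A3", "A11", "C16")

#' HLA allele-group to KIR-ligand epitope lookup
#'
#' Reads a two-column CSV (`allele_group`, `epitopes`; epitopes separated
#' by `;`) mapping allele groups such as `C*04` or `B*51` to the epitope
#' labels C1, C2, Bw4, Bw4_80I, A3, A11, C16. Group-level (two-digit)
#' assignment is deliberate: study data of this kind are typed at low to
#' intermediate resolution, and groups whose epitope varies by allele are
#' resolved in favour of the majority allele. The bundled table restricts
#' Bw4_80I to B-locus groups (the convention for the KIR3DS1 ligand).
#'
#' @param path Path to a lookup CSV; default is the bundled table.
#' @return data.frame of class `kir_ligand_lookup` with columns
#'   `allele_group` and `epitopes` (list column of character vectors).
#' @export
read_ligand_lookup <- function(path = system.file("extdata",
                                                  "hla_ligand_groups.csv",
                                                  package = "kirpop",
                                                  mustWork = TRUE)) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         comment.char = "#", strip.white = TRUE)
  if (!all(c("allele_group", "epitopes") %in% names(raw))) {
    stop("ligand lookup needs columns allele_group, epitopes")
  }
  if (anyDuplicated(raw$allele_group)) stop("duplicate allele groups in lookup")
  eps <- strsplit(raw$epitopes, ";", fixed = TRUE)
  eps <- lapply(eps, function(e) trimws(e[nzchar(trimws(e))]))
  bad <- setdiff(unique(unlist(eps)), LIGAND_FLAGS)
  if (length(bad) > 0L) stop("unknown epitope label(s): ", paste(bad, collapse = ", "))
  # invariants: HLA-C groups carry exactly one of C1/C2; Bw4_80I implies Bw4
  is_c <- grepl("^C\\*", raw$allele_group)
  for (i in which(is_c)) {
    k <- sum(c("C1", "C2") %in% eps[[i]])
    if (k != 1L) stop("HLA-C group ", raw$allele_group[i],
                      " must map to exactly one of C1/C2")
  }
  for (i in seq_along(eps)) {
    if ("Bw4_80I" %in% eps[[i]] && !"Bw4" %in% eps[[i]]) {
      stop("Bw4_80I without Bw4 for group ", raw$allele_group[i])
    }
    if (all(c("A3", "A11") %in% eps[[i]])) {
      stop("A3 and A11 are disjoint epitopes (group ", raw$allele_group[i], ")")
    }
  }
  out <- data.frame(allele_group = raw$allele_group, stringsAsFactors = FALSE)
  out$epitopes <- eps
  structure(out, class = c("kir_ligand_lookup", "data.frame"))
}

#' @rdname read_ligand_lookup
#' @export
default_ligand_lookup <- function() read_ligand_lookup()

#' Read an HLA typing table
#'
#' CSV/TSV with `individual_id` and allele columns `A_1`, `A_2`, `B_1`,
#' `B_2`, `C_1`, `C_2` holding allele-group strings (`A*24`); empty cells
#' or missing C columns denote untyped loci.
#'
#' @param path Path to the file.
#' @return data.frame with `individual_id` and the six allele columns
#'   (NA for untyped).
#' @export
read_hla_table <- function(path) {
  raw <- utils::read.csv(path, sep = sniff_sep(path), check.names = FALSE,
                         colClasses = "character", comment.char = "#",
                         strip.white = TRUE)
  if (!"individual_id" %in% names(raw)) stop("HLA table lacks individual_id")
  if (anyDuplicated(raw$individual_id)) stop("duplicate individual_id in HLA table")
  cols <- c("A_1", "A_2", "B_1", "B_2", "C_1", "C_2")
  for (cc in cols) {
    if (!cc %in% names(raw)) raw[[cc]] <- NA_character_
    raw[[cc]][!nzchar(trimws(raw[[cc]])) | is.na(raw[[cc]])] <- NA_character_
  }
  raw[, c("individual_id", cols)]
}

#' Classify one individual's HLA alleles into KIR-ligand flags
#'
#' @param alleles Character vector of allele-group strings (`"C*04"`).
#' @param lookup A [read_ligand_lookup()] table.
#' @return Named logical vector over the ligand flags; unknown allele
#'   groups are ignored and returned in the `"unknown"` attribute.
#' @export
classify_ligand_alleles <- function(alleles, lookup = default_ligand_lookup()) {
  alleles <- alleles[!is.na(alleles)]
  flags <- stats::setNames(rep(FALSE, length(LIGAND_FLAGS)), LIGAND_FLAGS)
  unknown <- character()
  for (a in alleles) {
    i <- match(a, lookup$allele_group)
    if (is.na(i)) { unknown <- c(unknown, a); next }
    eps <- lookup$epitopes[[i]]
    flags[eps] <- TRUE
    if ("Bw4" %in% eps) {
      if (grepl("^A\\*", a)) flags["Bw4_from_A"] <- TRUE
      if (grepl("^B\\*", a)) flags["Bw4_from_B"] <- TRUE
    }
  }
  attr(flags, "unknown") <- unknown
  flags
}

#' Classify an HLA typing table into per-individual ligand profiles
#'
#' Flags are the union of the epitopes of all typed alleles, so adding an
#' allele can only switch flags on. Bw4 provenance (A- vs B-locus) is
#' recorded separately. Individuals without HLA-C typing get `c_typed =
#' FALSE` and are excluded downstream from C-dependent pair tables.
#'
#' @param hla An HLA typing table ([read_hla_table()]).
#' @param lookup A [read_ligand_lookup()] table.
#' @return data.frame of class `kir_ligands`: `individual_id`, one logical
#'   column per ligand flag, `A3_A11` (either), and `c_typed`. Unknown
#'   allele groups are collected as warning findings in the
#'   `"unknown_alleles"` attribute.
#' @export
classify_ligands <- function(hla, lookup = default_ligand_lookup()) {
  allele_cols <- c("A_1", "A_2", "B_1", "B_2", "C_1", "C_2")
  rows <- lapply(seq_len(nrow(hla)), function(r) {
    classify_ligand_alleles(unlist(hla[r, allele_cols]), lookup)
  })
  m <- do.call(rbind, lapply(rows, as.logical))
  colnames(m) <- LIGAND_FLAGS
  unknown <- do.call(rbind, lapply(seq_along(rows), function(r) {
    u <- attr(rows[[r]], "unknown")
    if (length(u) == 0L) return(NULL)
    data.frame(individual_id = hla$individual_id[r], allele = u,
               stringsAsFactors = FALSE)
  }))
  out <- data.frame(individual_id = hla$individual_id, m,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$A3_A11 <- out$A3 | out$A11
  out$c_typed <- !is.na(hla$C_1) | !is.na(hla$C_2)
  if (length(unknown) && nrow(unknown) > 0L) {
    warning("unknown allele group(s) ignored: ",
            paste(unique(unknown$allele), collapse = ", "))
  }
  structure(out, class = c("kir_ligands", "data.frame"),
            unknown_alleles = unknown)
}

#' KIR-HLA pair definitions
#'
#' The receptor-ligand combinations tabulated in four-state
#' (present/present ... absent/absent) tables. `kir_genes` is
#' comma-separated; the KIR side is "present" when any listed gene is
#' present. `requires_ds4_full` marks combinations restricted to the
#' full-length KIR2DS4 variant (zygosity FF or FD).
#'
#' @return data.frame with columns `pair`, `kir_genes`, `ligand_flag`,
#'   `class`, `requires_ds4_full`.
#' @export
default_pair_definitions <- function() {
  def <- rbind(
    c("2DL1/C2",           "KIR2DL1",          "C2",      "inhibition", FALSE),
    c("2DL2/C1",           "KIR2DL2",          "C1",      "inhibition", FALSE),
    c("2DL3/C1",           "KIR2DL3",          "C1",      "inhibition", FALSE),
    c("3DL1/Bw4",          "KIR3DL1",          "Bw4",     "inhibition", FALSE),
    c("3DL1/Bw4 (HLA-B)",  "KIR3DL1",          "Bw4_from_B", "inhibition", FALSE),
    c("3DL1/Bw4 (HLA-A)",  "KIR3DL1",          "Bw4_from_A", "inhibition", FALSE),
    c("3DL2/A3 A11",       "KIR3DL2",          "A3_A11",  "inhibition", FALSE),
    c("3DL2/A3",           "KIR3DL2",          "A3",      "inhibition", FALSE),
    c("3DL2/A11",          "KIR3DL2",          "A11",     "inhibition", FALSE),
    c("2DS1/C2",           "KIR2DS1",          "C2",      "activation", FALSE),
    c("2DS2/C1",           "KIR2DS2",          "C1",      "activation", FALSE),
    c("2DS2/HLA-C*16",     "KIR2DS2",          "C16",     "activation", FALSE),
    c("2DS2/A11",          "KIR2DS2",          "A11",     "activation", FALSE),
    c("2DS4F/A3 A11",      "KIR2DS4",          "A3_A11",  "activation", TRUE),
    c("3DS1/Bw4-80I",      "KIR3DS1",          "Bw4_80I", "activation", FALSE))
  data.frame(pair = def[, 1], kir_genes = def[, 2], ligand_flag = def[, 3],
             class = def[, 4], requires_ds4_full = as.logical(def[, 5]),
             stringsAsFactors = FALSE)
}

# C-locus-derived flags: pairs using them skip individuals without HLA-C
# typing.
C_DEPENDENT_FLAGS <- c("C1", "C2", "C16")

join_cohort <- function(profiles, ligands) {
  if (!setequal(profiles$individual_id, ligands$individual_id)) {
    only_g <- setdiff(profiles$individual_id, ligands$individual_id)
    only_l <- setdiff(ligands$individual_id, profiles$individual_id)
    stop("unmatched individual_id between genotype and ligand tables",
         if (length(only_g)) paste0("; genotypes only: ",
                                    paste(utils::head(only_g, 5), collapse = ", ")),
         if (length(only_l)) paste0("; ligands only: ",
                                    paste(utils::head(only_l, 5), collapse = ", ")))
  }
  ligands[match(profiles$individual_id, ligands$individual_id), ]
}

kir_side_present <- function(profiles, kir_genes, requires_ds4_full, panel) {
  genes <- normalize_gene_names(strsplit(kir_genes, ",")[[1L]], panel)
  m <- presence_matrix(profiles, panel)
  pres <- rowSums(m[, genes, drop = FALSE]) > 0L
  if (requires_ds4_full) {
    pres <- pres & profiles$ds4_zygosity %in% c("FF", "FD")
  }
  pres
}

#' Four-state KIR-HLA combination table
#'
#' For each pair definition, counts individuals in the four mutually
#' exclusive cells KIR-present/ligand-present, present/absent,
#' absent/present and absent/absent (percentages of the evaluated N).
#' Individuals without HLA-C typing are excluded from C-dependent pairs and
#' counted in `n_excluded`.
#'
#' @param profiles A [kir_genotypes()] table.
#' @param ligands A [classify_ligands()] table.
#' @param pairs Pair definitions ([default_pair_definitions()]).
#' @param panel A [kir_panel()].
#' @return data.frame with one row per pair: counts `pp`, `pa`, `ap`, `aa`,
#'   their percentages, `n` (evaluated) and `n_excluded`.
#' @export
kir_hla_pair_table <- function(profiles, ligands,
                               pairs = default_pair_definitions(),
                               panel = attr(profiles, "panel") %||% kir_panel()) {
  lig <- join_cohort(profiles, ligands)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    keep <- if (p$ligand_flag %in% C_DEPENDENT_FLAGS) lig$c_typed else
      rep(TRUE, nrow(lig))
    kir <- kir_side_present(profiles, p$kir_genes, p$requires_ds4_full, panel)[keep]
    hla <- lig[[p$ligand_flag]][keep]
    n <- sum(keep)
    data.frame(pair = p$pair, class = p$class,
               pp = sum(kir & hla), pa = sum(kir & !hla),
               ap = sum(!kir & hla), aa = sum(!kir & !hla),
               n = n, n_excluded = sum(!keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (cc in c("pp", "pa", "ap", "aa")) {
    out[[paste0(cc, "_pct")]] <- out[[cc]] / out$n * 100
  }
  rownames(out) <- NULL
  out
}

INHIBITORY_MULTIPLICITY_PAIRS <- data.frame(
  pair = c("2DL1+C2", "2DL2/3+C1", "3DL1+Bw4", "3DL2+A3/11"),
  kir_genes = c("KIR2DL1", "KIR2DL2,KIR2DL3", "KIR3DL1", "KIR3DL2"),
  ligand_flag = c("C2", "C1", "Bw4", "A3_A11"),
  requires_ds4_full = FALSE,
  stringsAsFactors = FALSE)

#' Multiplicity of inhibitory KIR-ligand pairs per individual
#'
#' Evaluates the four canonical inhibitory pairs (2DL1+C2, 2DL2/3+C1,
#' 3DL1+Bw4, 3DL2+A3/11; "2DL2/3" means either gene) per individual and
#' groups the cohort by how many pairs are satisfied (0-4), with a
#' per-combination breakdown. Individuals without HLA-C typing are excluded
#' (attribute `n_excluded`).
#'
#' @param profiles A [kir_genotypes()] table.
#' @param ligands A [classify_ligands()] table.
#' @param panel A [kir_panel()].
#' @return data.frame with columns `cardinality`, `combination`, `n`,
#'   `percent`, plus attributes `cardinality_totals` and `n_excluded`.
#' @export
inhibitory_pair_multiplicity <- function(profiles, ligands,
                                         panel = attr(profiles, "panel") %||% kir_panel()) {
  lig <- join_cohort(profiles, ligands)
  keep <- lig$c_typed
  defs <- INHIBITORY_MULTIPLICITY_PAIRS
  sat <- sapply(seq_len(nrow(defs)), function(i) {
    kir_side_present(profiles, defs$kir_genes[i], defs$requires_ds4_full[i],
                     panel) & lig[[defs$ligand_flag[i]]]
  })
  if (nrow(profiles) == 1L) sat <- matrix(sat, nrow = 1L)
  colnames(sat) <- defs$pair
  sat <- sat[keep, , drop = FALSE]
  n_eval <- nrow(sat)
  combo <- apply(sat, 1L, function(r) {
    if (!any(r)) "none" else paste(defs$pair[r], collapse = " + ")
  })
  card <- rowSums(sat)
  tab <- table(card, combo)
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    nz <- which(tab[i, ] > 0)
    data.frame(cardinality = as.integer(rownames(tab)[i]),
               combination = colnames(tab)[nz],
               n = as.integer(tab[i, nz]), stringsAsFactors = FALSE)
  }))
  rows$percent <- rows$n / n_eval * 100
  rows <- rows[order(rows$cardinality, -rows$n, rows$combination), ]
  rownames(rows) <- NULL
  totals <- tapply(rows$n, rows$cardinality, sum)
  attr(rows, "cardinality_totals") <- totals
  attr(rows, "n_excluded") <- sum(!keep)
  attr(rows, "n_evaluated") <- n_eval
  rows
}

#' Ligand carriage summary
#'
#' Percentage of individuals carrying each ligand group. C-locus flags are
#' computed over individuals with HLA-C typing; other flags over the whole
#' cohort.
#'
#' @param ligands A [classify_ligands()] table.
#' @return data.frame with columns `flag`, `n`, `n_typed`, `percent`.
#' @export
ligand_carriage_summary <- function(ligands) {
  flags <- c(LIGAND_FLAGS, "A3_A11")
  rows <- lapply(flags, function(fl) {
    typed <- if (fl %in% C_DEPENDENT_FLAGS) ligands$c_typed else
      rep(TRUE, nrow(ligands))
    data.frame(flag = fl, n = sum(ligands[[fl]] & typed),
               n_typed = sum(typed),
               percent = if (sum(typed) > 0) sum(ligands[[fl]] & typed) / sum(typed) * 100 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
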