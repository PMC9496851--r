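#' Construct a KIR genotype table in memory
#'
#' Internal-friendly constructor used by the reader, the simulator and the
#' test-suite. `present` is a logical matrix (individuals x panel genes).
#'
#' @param individual_id Character vector of unique individual identifiers.
#' @param present Logical matrix with one column per panel gene (columns are
#'   matched to the panel by name, tolerant to a "KIR" prefix).
#' @param ds4_zygosity Optional character vector: "FF", "FD" or "DD" for
#'   KIR2DS4-positive individuals (full-length vs 22-bp-deleted variant),
#'   "unknown" when untyped, NA when KIR2DS4 is absent.
#' @param panel A [kir_panel()].
#' @return A data.frame of class `kir_genotypes`: `individual_id`, one
#'   logical column per panel gene, and `ds4_zygosity`.
#' @export
kir_genotypes <- function(individual_id, present, ds4_zygosity = NULL,
                          panel = kir_panel()) {
  individual_id <- as.character(individual_id)
  if (anyDuplicated(individual_id)) {
    stop("duplicate individual_id: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "))
  }
  present <- as.matrix(present)
  colnames(present) <- normalize_gene_names(colnames(present), panel)
  if (anyNA(colnames(present))) stop("unknown gene column in presence matrix")
  missing <- setdiff(panel$genes, colnames(present))
  if (length(missing) > 0L) {
    stop("presence matrix lacks panel gene(s): ", paste(missing, collapse = ", "))
  }
  present <- present[, panel$genes, drop = FALSE]
  storage.mode(present) <- "logical"
  if (anyNA(present)) stop("presence calls must not be NA")
  if (is.null(ds4_zygosity)) {
    ds4_zygosity <- ifelse(present[, "KIR2DS4"], "unknown", NA_character_)
  }
  ds4_zygosity <- as.character(ds4_zygosity)
  check_ds4_zygosity(ds4_zygosity, present[, "KIR2DS4"])
  out <- data.frame(individual_id = individual_id, present,
                    ds4_zygosity = ds4_zygosity,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("kir_genotypes", "data.frame"), panel = panel)
}

check_ds4_zygosity <- function(z, ds4_present) {
  ok_pos <- c("FF", "FD", "DD", "unknown")
  bad <- which(ds4_present & !(z %in% ok_pos))
  if (length(bad) > 0L) {
    stop("invalid ds4_zygosity for KIR2DS4-positive row(s) ",
         paste(bad, collapse = ", "), " (expected FF, FD, DD or unknown)")
  }
  bad <- which(!ds4_present & !(is.na(z) | z == "unknown"))
  if (length(bad) > 0L) {
    stop("ds4_zygosity given for KIR2DS4-negative row(s) ",
         paste(bad, collapse = ", "))
  }
  invisible(z)
}

#' Presence/absence matrix of a genotype table
#'
#' @param profiles A [kir_genotypes()] table.
#' @param panel A [kir_panel()].
#' @return Logical matrix, individuals x panel genes, rownames set to
#'   `individual_id`.
#' @export
presence_matrix <- function(profiles, panel = attr(profiles, "panel") %||% kir_panel()) {
  m <- as.matrix(profiles[, panel$genes, drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- profiles$individual_id
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Delimiter sniffing for the small delimited-text formats used throughout:
# tab wins if the header contains one, otherwise comma.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a KIR presence/absence genotype table
#'
#' Expects delimited text (comma or tab, sniffed from the header) with an
#' identifier column and one column per panel gene. Presence may be encoded
#' as `1`/`0` or `POS`/`NEG` (case-insensitive). An optional `ds4_zygosity`
#' column carries the KIR2DS4 full-length/deleted variant call.
#'
#' @param path Path to the file.
#' @param panel A [kir_panel()].
#' @param id_col Name of the identifier column (default `"individual_id"`).
#' @return A [kir_genotypes()] table, one row per individual in file order.
#' @export
read_genotype_table <- function(path, panel = kir_panel(),
                                id_col = "individual_id") {
  raw <- utils::read.csv(path, sep = sniff_sep(path), colClasses = "character",
                         check.names = FALSE, comment.char = "#",
                         strip.white = TRUE)
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  if (!id_col %in% names(raw)) {
    stop("identifier column '", id_col, "' not found in ", path)
  }
  norm <- normalize_gene_names(names(raw), panel)
  gene_cols <- match(panel$genes, norm)
  if (anyNA(gene_cols)) {
    stop("missing panel gene column(s): ",
         paste(panel$genes[is.na(gene_cols)], collapse = ", "), " in ", path)
  }
  present <- matrix(NA, nrow(raw), length(panel$genes),
                    dimnames = list(NULL, panel$genes))
  for (j in seq_along(panel$genes)) {
    v <- toupper(trimws(raw[[gene_cols[j]]]))
    parsed <- ifelse(v %in% c("1", "POS"), TRUE,
                     ifelse(v %in% c("0", "NEG"), FALSE, NA))
    if (anyNA(parsed)) {
      bad <- which(is.na(parsed))[1L]
      stop("unparseable presence value '", raw[[gene_cols[j]]][bad],
           "' at row ", bad, ", column ", names(raw)[gene_cols[j]],
           " (expected 1/0 or POS/NEG)")
    }
    present[, j] <- parsed
  }
  z <- if ("ds4_zygosity" %in% names(raw)) {
    z0 <- trimws(raw$ds4_zygosity)
    ifelse(z0 == "" | is.na(z0), ifelse(present[, "KIR2DS4"], "unknown", NA), z0)
  } else NULL
  kir_genotypes(raw[[id_col]], present, z, panel)
}

#' Validate genotype profiles against panel expectations
#'
#' Framework genes are present in almost all individuals, so their absence is
#' reported as a warning-level finding rather than an error: real data may
#' legitimately contain such profiles, but they usually indicate a typing
#' failure or a rare deletion haplotype.
#'
#' @param profiles A [kir_genotypes()] table.
#' @param panel A [kir_panel()].
#' @return A data.frame of findings with columns `individual_id`, `gene`,
#'   `rule` and `message`; zero rows when nothing is flagged.
#' @export
validate_profiles <- function(profiles, panel = attr(profiles, "panel") %||% kir_panel()) {
  m <- presence_matrix(profiles, panel)
  findings <- list()
  for (g in panel$framework) {
    absent <- which(!m[, g])
    if (length(absent) > 0L) {
      findings[[g]] <- data.frame(
        individual_id = profiles$individual_id[absent],
        gene = g, rule = "framework_absent",
        message = paste0("framework gene ", g, " absent"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(individual_id = character(), gene = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, findings)
  out <- out[order(match(out$individual_id, profiles$individual_id)), ]
  rownames(out) <- NULL
  out
}

#' Classify genotypes as AA or Bx
#'
#' A genotype is AA when no B-specific gene is present; otherwise Bx.
#' Gene content alone cannot distinguish A/B heterozygotes from B/B
#' homozygotes, hence the two-way labelling.
#'
#' @param profiles A [kir_genotypes()] table.
#' @param panel A [kir_panel()].
#' @return Character vector of `"AA"`/`"Bx"`, one per individual.
#' @export
classify_ab <- function(profiles, panel = attr(profiles, "panel") %||% kir_panel()) {
  m <- presence_matrix(profiles, panel)
  any_b <- rowSums(m[, panel$b_specific, drop = FALSE]) > 0L
  unname(ifelse(any_b, "Bx", "AA"))
}

# Canonical string key for a gene-content set (panel order).
content_key <- function(m, panel) {
  apply(m[, panel$genes, drop = FALSE], 1L,
        function(r) paste(panel$genes[r], collapse = "|"))
}

#' Read a genotype catalog
#'
#' A catalog maps genotype IDs (e.g. AFND genotype numbers) to gene-content
#' sets: a CSV with a `genotype_id` column and one 0/1 column per panel gene.
#' Lines starting with `#` are treated as provenance comments.
#'
#' @param path Path to the catalog CSV.
#' @param panel A [kir_panel()].
#' @return A data.frame with `genotype_id` and one logical column per gene.
#' @export
read_genotype_catalog <- function(path, panel = kir_panel()) {
  raw <- utils::read.csv(path, sep = sniff_sep(path), check.names = FALSE,
                         colClasses = "character", comment.char = "#",
                         strip.white = TRUE)
  if (!"genotype_id" %in% names(raw)) stop("catalog lacks a genotype_id column")
  norm <- normalize_gene_names(names(raw), panel)
  gene_cols <- match(panel$genes, norm)
  if (anyNA(gene_cols)) {
    stop("catalog lacks panel gene column(s): ",
         paste(panel$genes[is.na(gene_cols)], collapse = ", "))
  }
  m <- sapply(gene_cols, function(j) raw[[j]] %in% "1")
  if (nrow(raw) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- panel$genes
  out <- data.frame(genotype_id = raw$genotype_id, m,
                    stringsAsFactors = FALSE, check.names = FALSE)
  check_catalog(out, panel)
  out
}

check_catalog <- function(catalog, panel) {
  if (anyDuplicated(catalog$genotype_id)) stop("duplicate genotype IDs in catalog")
  keys <- content_key(as.matrix(catalog[, panel$genes, drop = FALSE]), panel)
  if (anyDuplicated(keys)) {
    dup <- catalog$genotype_id[duplicated(keys) | duplicated(keys, fromLast = TRUE)]
    stop("catalog entries with identical gene content: ",
         paste(dup, collapse = ", "))
  }
  invisible(catalog)
}

#' The bundled (synthetic) genotype catalog
#'
#' Gene-content sets formed by the pairwise unions of the seven bundled
#' reference haplotypes. The IDs are synthetic stand-ins except where a
#' content is unambiguously identifiable (the canonical nine-gene AA
#' genotype "1" and the full 16-locus genotype "6"); replace with a real
#' AFND-derived catalog for production genotyping.
#'
#' @param panel A [kir_panel()].
#' @return A catalog data.frame (see [read_genotype_catalog()]).
#' @export
default_genotype_catalog <- function(panel = kir_panel()) {
  path <- system.file("extdata", "genotype_catalog_synthetic.csv",
                      package = "kirpop", mustWork = TRUE)
  read_genotype_catalog(path, panel)
}

#' Match profiles to catalog genotype IDs
#'
#' Looks up each individual's gene-content set in the catalog; contents not
#' present in the catalog receive sequential NPR ("not previously reported")
#' labels, assigned in first-encounter order and stable within a run.
#'
#' @param profiles A [kir_genotypes()] table.
#' @param catalog A catalog data.frame ([read_genotype_catalog()]).
#' @param panel A [kir_panel()].
#' @return Character vector of genotype IDs, one per individual.
#' @export
match_genotype_id <- function(profiles, catalog = default_genotype_catalog(),
                              panel = attr(profiles, "panel") %||% kir_panel()) {
  check_catalog(catalog, panel)
  cat_keys <- content_key(as.matrix(catalog[, panel$genes, drop = FALSE]), panel)
  keys <- content_key(presence_matrix(profiles, panel), panel)
  ids <- catalog$genotype_id[match(keys, cat_keys)]
  novel <- unique(keys[is.na(ids)])
  if (length(novel) > 0L) {
    npr <- paste0("NPR", seq_along(novel))
    ids[is.na(ids)] <- npr[match(keys[is.na(ids)], novel)]
  }
  ids
}

#' Genotype frequency table by direct count
#'
#' Groups individuals by identical gene content and tabulates counts and
#' percentages, ordered by descending count and then genotype ID
#' (numeric-aware, NPR labels last among ties).
#'
#' @param profiles A [kir_genotypes()] table.
#' @param catalog A genotype catalog for ID lookup.
#' @param panel A [kir_panel()].
#' @return A data.frame with columns `genotype_id`, `ab` (AA/Bx), `n_loci`,
#'   `n` and `percent`.
#' @export
genotype_frequency_table <- function(profiles,
                                     catalog = default_genotype_catalog(),
                                     panel = attr(profiles, "panel") %||% kir_panel()) {
  if (nrow(profiles) == 0L) stop("need at least one profile")
  ids <- match_genotype_id(profiles, catalog, panel)
  ab <- classify_ab(profiles, panel)
  n_loci <- rowSums(presence_matrix(profiles, panel))
  agg <- tapply(seq_len(nrow(profiles)), ids, identity)
  out <- data.frame(
    genotype_id = names(agg),
    ab = vapply(agg, function(i) ab[i[1L]], character(1)),
    n_loci = vapply(agg, function(i) as.integer(n_loci[i[1L]]), integer(1)),
    n = vapply(agg, length, integer(1)),
    stringsAsFactors = FALSE)
  out$percent <- out$n / nrow(profiles) * 100
  # numeric IDs sort numerically within equal counts; NPR/other labels follow
  num <- suppressWarnings(as.numeric(out$genotype_id))
  ord <- order(-out$n, is.na(num), num, out$genotype_id)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
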