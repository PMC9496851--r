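#' Reference KIR gene-content haplotypes
#'
#' Haplotype inference from unphased gene content rests on a small set of
#' reference haplotypes (cen~tel motif combinations in the Vierra-Green
#' nomenclature) plus four structural rules:
#' \itemize{
#'   \item I. the four framework genes are present on every haplotype;
#'   \item II. KIR2DL5 implies KIR2DS3 and/or KIR2DS5;
#'   \item III. KIR2DL2 and KIR2DL3 never co-occur on one haplotype;
#'   \item IV. KIR2DS4 implies KIR3DL1.
#' }
#' `load_reference_haplotypes()` reads a CSV with columns `name`,
#' `cen_motif`, `tel_motif` and one 0/1 column per panel gene, validating
#' every entry against rules I-IV.
#'
#' @param path Path to the haplotype definition CSV.
#' @param panel A [kir_panel()].
#' @return data.frame of class `kir_haplotypes`: `name`, `cen_motif`,
#'   `tel_motif` and one logical column per panel gene.
#' @export
load_reference_haplotypes <- function(path, panel = kir_panel()) {
  raw <- utils::read.csv(path, sep = sniff_sep(path), check.names = FALSE,
                         colClasses = "character", comment.char = "#",
                         strip.white = TRUE)
  need <- c("name", "cen_motif", "tel_motif")
  if (!all(need %in% names(raw))) {
    stop("haplotype file needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(raw$name)) stop("duplicate haplotype names")
  norm <- normalize_gene_names(names(raw), panel)
  gene_cols <- match(panel$genes, norm)
  if (anyNA(gene_cols)) {
    stop("haplotype file lacks gene column(s): ",
         paste(panel$genes[is.na(gene_cols)], collapse = ", "))
  }
  m <- sapply(gene_cols, function(j) raw[[j]] %in% "1")
  if (nrow(raw) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- panel$genes
  for (i in seq_len(nrow(m))) {
    viol <- check_haplotype_rules(m[i, ], panel)
    if (length(viol) > 0L) {
      stop("haplotype '", raw$name[i], "' violates rule ",
           paste(viol, collapse = ", "))
    }
  }
  out <- data.frame(name = raw$name, cen_motif = raw$cen_motif,
                    tel_motif = raw$tel_motif, m,
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, class = c("kir_haplotypes", "data.frame"), panel = panel)
}

#' Check one haplotype against the structural rules I-IV
#'
#' @param present Named logical vector over the panel genes.
#' @param panel A [kir_panel()].
#' @return Character vector describing the violated rules (empty when the
#'   haplotype is structurally valid).
#' @export
check_haplotype_rules <- function(present, panel = kir_panel()) {
  viol <- character()
  if (!all(present[panel$framework])) {
    viol <- c(viol, "I (framework genes always present)")
  }
  if (present["KIR2DL5"] && !(present["KIR2DS3"] || present["KIR2DS5"])) {
    viol <- c(viol, "II (KIR2DL5 requires KIR2DS3 and/or KIR2DS5)")
  }
  if (present["KIR2DL2"] && present["KIR2DL3"]) {
    viol <- c(viol, "III (KIR2DL2 and KIR2DL3 are mutually exclusive)")
  }
  if (present["KIR2DS4"] && !present["KIR3DL1"]) {
    viol <- c(viol, "IV (KIR2DS4 requires KIR3DL1)")
  }
  viol
}

#' The bundled reference haplotype set
#'
#' The seven most frequent cen~tel gene-content haplotypes of the modelled
#' study population, with motif contents per the Vierra-Green nomenclature.
#' The file is user-replaceable and extensible toward a fuller reference set.
#'
#' @param panel A [kir_panel()].
#' @return A `kir_haplotypes` data.frame (see [load_reference_haplotypes()]).
#' @export
default_reference_haplotypes <- function(panel = kir_panel()) {
  path <- system.file("extdata", "reference_haplotypes.csv",
                      package = "kirpop", mustWork = TRUE)
  load_reference_haplotypes(path, panel)
}

#' Gene-content matrix of a reference haplotype set
#'
#' @param refs A `kir_haplotypes` data.frame.
#' @param panel A [kir_panel()].
#' @return Logical matrix, haplotypes x panel genes, rownames set to names.
#' @export
hap_matrix <- function(refs, panel = attr(refs, "panel") %||% kir_panel()) {
  m <- as.matrix(refs[, panel$genes, drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- refs$name
  m
}

#' Enumerate diplotypes compatible with a gene-content genotype
#'
#' A pair of reference haplotypes explains a genotype when the union of
#' their gene sets equals the genotype's present set exactly. Returns all
#' unordered compatible pairs; an empty result means the individual cannot
#' be fully resolved against the reference set.
#'
#' @param present Present gene set: either a character vector of gene names
#'   or a named logical vector over the panel.
#' @param refs A `kir_haplotypes` reference set.
#' @param panel A [kir_panel()].
#' @return data.frame with columns `hap_a`, `hap_b` (names, `hap_a <= hap_b`).
#' @export
enumerate_compatible_diplotypes <- function(present, refs,
                                            panel = attr(refs, "panel") %||% kir_panel()) {
  if (nrow(refs) == 0L) stop("reference set is empty")
  pv <- as_present_vector(present, panel)
  pairs <- ref_pair_index(refs, panel)
  key <- paste(panel$genes[pv], collapse = "|")
  hit <- pairs[pairs$key == key, c("hap_a", "hap_b")]
  rownames(hit) <- NULL
  hit
}

as_present_vector <- function(present, panel) {
  if (is.character(present)) {
    g <- normalize_gene_names(present, panel)
    if (anyNA(g)) stop("unknown gene name(s): ",
                       paste(present[is.na(g)], collapse = ", "))
    pv <- panel$genes %in% g
  } else {
    pv <- as.logical(present[panel$genes])
    if (anyNA(pv)) stop("presence vector must cover every panel gene")
  }
  names(pv) <- panel$genes
  pv
}

# All unordered reference pairs with their union keys, ordered so that
# hap_a <= hap_b by name.
ref_pair_index <- function(refs, panel) {
  m <- hap_matrix(refs, panel)
  k <- nrow(m)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  key <- vapply(seq_len(nrow(idx)), function(r) {
    u <- m[idx[r, 1L], ] | m[idx[r, 2L], ]
    paste(panel$genes[u], collapse = "|")
  }, character(1))
  a <- refs$name[idx[, 1L]]
  b <- refs$name[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(i = idx[, 1L], j = idx[, 2L], hap_a = a, hap_b = b, key = key,
             stringsAsFactors = FALSE)
}

# Explanation sets per individual for the EM:
#   - exact: all reference pairs whose union equals the profile;
#   - half:  if no exact pair, (h, residual) for each reference h contained
#            in the profile -- one chromosome resolved, the other assigned
#            to the residual (unrepresented-haplotype) class;
#   - none:  (residual, residual).
# Index K+1 denotes the residual class.
build_explanations <- function(profiles, refs, panel) {
  m <- hap_matrix(refs, panel)
  K <- nrow(m)
  pm <- presence_matrix(profiles, panel)
  pairs <- ref_pair_index(refs, panel)
  prof_keys <- content_key(pm, panel)
  split_pairs <- split(pairs[, c("i", "j")], pairs$key)
  lapply(seq_len(nrow(pm)), function(r) {
    exact <- split_pairs[[prof_keys[r]]]
    if (!is.null(exact) && nrow(exact) > 0L) {
      return(list(kind = "both", i = exact$i, j = exact$j))
    }
    subs <- which(apply(m, 1L, function(h) all(!h | pm[r, ])))
    if (length(subs) > 0L) {
      return(list(kind = "one", i = subs, j = rep(K + 1L, length(subs))))
    }
    list(kind = "none", i = K + 1L, j = K + 1L)
  })
}

#' EM estimation of haplotype frequencies under Hardy-Weinberg equilibrium
#'
#' Maximises the multinomial HWE likelihood
#' \eqn{\prod_i \sum_{(a,b)} c\, f_a f_b} (c = 2 for heterozygous pairs)
#' over the compatible explanations of each genotype. Individuals whose
#' genotype matches no reference pair are explained through a residual
#' class: one chromosome credited to any reference haplotype contained in
#' the profile, the remainder to the residual, so that estimated reference
#' frequencies and the residual mass lie on one simplex and partially
#' resolvable individuals still inform the fit.
#'
#' @param profiles A [kir_genotypes()] table.
#' @param refs A `kir_haplotypes` reference set.
#' @param tol Convergence tolerance on the maximum absolute frequency
#'   change per iteration.
#' @param max_iter Iteration cap.
#' @param panel A [kir_panel()].
#' @return An object of class `kir_hap_freq`: list with `freqs` (named,
#'   over the references), `residual` (unexplained mass fraction),
#'   `log_likelihood` (trace), `n_iter`, `converged`, `n_individuals`,
#'   `n_chromosomes`.
#' @export
em_haplotype_frequencies <- function(profiles, refs, tol = 1e-8,
                                     max_iter = 1000L,
                                     panel = attr(refs, "panel") %||% kir_panel()) {
  if (nrow(profiles) == 0L) stop("need at least one profile")
  expl <- build_explanations(profiles, refs, panel)
  if (!any(vapply(expl, function(e) e$kind == "both", logical(1)))) {
    stop("no individual is compatible with any reference haplotype pair")
  }
  K <- nrow(refs)
  N <- nrow(profiles)
  f <- rep(1 / (K + 1), K + 1)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    counts <- numeric(K + 1)
    ll <- 0
    for (e in expl) {
      w <- f[e$i] * f[e$j] * ifelse(e$i == e$j, 1, 2)
      tot <- sum(w)
      ll <- ll + log(tot)
      w <- w / tot
      for (p in seq_along(w)) {
        counts[e$i[p]] <- counts[e$i[p]] + w[p]
        counts[e$j[p]] <- counts[e$j[p]] + w[p]
      }
    }
    loglik <- c(loglik, ll)
    f_new <- counts / (2 * N)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(freqs = stats::setNames(f[seq_len(K)], refs$name),
                 residual = f[K + 1L],
                 log_likelihood = loglik,
                 n_iter = length(loglik),
                 converged = converged,
                 n_individuals = N,
                 n_chromosomes = 2L * N),
            class = "kir_hap_freq")
}

#' @export
print.kir_hap_freq <- function(x, ...) {
  cat("Haplotype frequency estimate (2n = ", x$n_chromosomes, ")\n", sep = "")
  print(round(sort(x$freqs, decreasing = TRUE), 5))
  cat("residual (unexplained mass): ", round(x$residual, 5),
      "; EM iterations: ", x$n_iter,
      if (x$converged) " (converged)\n" else " (not converged)\n", sep = "")
  invisible(x)
}

#' Haplotype resolution summary
#'
#' Classifies individuals by how far the reference set resolves their
#' genotype: both chromosomes (an exact compatible pair exists), one
#' chromosome (no pair, but some reference haplotype is contained in the
#' profile), or neither. `explained_percent` counts resolved chromosomes
#' out of 2N.
#'
#' @param profiles A [kir_genotypes()] table.
#' @param refs A `kir_haplotypes` reference set.
#' @param panel A [kir_panel()].
#' @return List with `n_both_resolved`, `n_one_resolved`, `n_unresolved`
#'   and `explained_percent`.
#' @export
resolution_summary <- function(profiles, refs,
                               panel = attr(refs, "panel") %||% kir_panel()) {
  expl <- build_explanations(profiles, refs, panel)
  kind <- vapply(expl, function(e) e$kind, character(1))
  n_both <- sum(kind == "both")
  n_one <- sum(kind == "one")
  n_none <- sum(kind == "none")
  N <- nrow(profiles)
  list(n_both_resolved = n_both, n_one_resolved = n_one,
       n_unresolved = n_none,
       explained_percent = (2 * n_both + n_one) / (2 * N) * 100)
}

#' Haplotype frequency table
#'
#' Chromosome counts and percentages per haplotype, sorted by descending
#' count then name. Haplotypes estimated below the confidence threshold of
#' eight chromosomes are flagged rather than dropped; zero-frequency
#' haplotypes are omitted.
#'
#' @param x A `kir_hap_freq` estimate, or a named numeric vector of
#'   haplotype frequencies (fractions).
#' @param n_chromosomes Number of chromosomes (2N); taken from the estimate
#'   when `x` is one.
#' @param min_count Flag threshold in chromosomes (default 8).
#' @return data.frame with columns `name`, `count`, `percent`,
#'   `below_threshold`.
#' @export
haplotype_frequency_table <- function(x, n_chromosomes = NULL, min_count = 8L) {
  if (inherits(x, "kir_hap_freq")) {
    freqs <- x$freqs
    n_chromosomes <- n_chromosomes %||% x$n_chromosomes
  } else {
    freqs <- x
    if (is.null(n_chromosomes)) stop("n_chromosomes required for a bare frequency vector")
  }
  freqs <- freqs[freqs > 0]
  out <- data.frame(name = names(freqs),
                    count = as.integer(round(freqs * n_chromosomes)),
                    percent = 100 * unname(freqs),
                    stringsAsFactors = FALSE)
  out$below_threshold <- out$count < min_count
  out <- out[order(-out$count, out$name), ]
  rownames(out) <- NULL
  out
}
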