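#' Read a population x gene carrier-frequency table
#'
#' CSV/TSV with columns `population`, `n` (sample size), optional `region`,
#' and one column per KIR gene. AFND-style percent tables are auto-detected
#' (any value > 1 triggers division of all frequencies by 100, with a
#' message). The gene set may be the full 16-locus panel or a restriction
#' (e.g. 14 genes without the pseudogenes, as used for Amerindian
#' comparisons); all populations in one table share one gene set.
#'
#' @param path Path to the file.
#' @param panel A [kir_panel()] used to recognise gene columns.
#' @return data.frame of class `kir_pop_freq`: `population`, `n`,
#'   optionally `region`, and numeric gene columns (fractions in \[0, 1\]).
#' @export
read_population_frequencies <- function(path, panel = kir_panel()) {
  raw <- utils::read.csv(path, sep = sniff_sep(path), check.names = FALSE,
                         comment.char = "#", strip.white = TRUE)
  if (!"population" %in% names(raw)) stop("table lacks a population column")
  norm <- normalize_gene_names(names(raw), panel)
  gene_idx <- which(!is.na(norm))
  if (length(gene_idx) < 2L) stop("table needs at least two gene columns")
  genes <- norm[gene_idx]
  vals <- as.matrix(raw[, gene_idx, drop = FALSE])
  colnames(vals) <- genes
  if (anyNA(vals)) stop("missing frequency cells are not allowed")
  if (any(vals > 1)) {
    message("values > 1 detected; interpreting table as percentages (dividing by 100)")
    vals <- vals / 100
  }
  if (any(vals < 0 | vals > 1)) stop("frequencies must lie in [0, 1]")
  out <- data.frame(population = as.character(raw$population),
                    n = if ("n" %in% names(raw)) as.integer(raw$n) else NA_integer_,
                    stringsAsFactors = FALSE)
  if ("region" %in% names(raw)) out$region <- as.character(raw$region)
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  if (anyDuplicated(out$population)) stop("duplicate population names")
  structure(out, class = c("kir_pop_freq", "data.frame"), genes = genes)
}

pop_freq_matrix <- function(table) {
  genes <- attr(table, "genes") %||%
    names(table)[!is.na(normalize_gene_names(names(table), kir_panel()))]
  m <- as.matrix(table[, genes, drop = FALSE])
  rownames(m) <- table$population
  m
}

#' Nei (1972) standard genetic distance between populations
#'
#' Each KIR locus is treated as biallelic (presence/absence) with allele
#' frequencies \eqn{(p, 1-p)}, p being the carrier frequency. For
#' populations X, Y the normalised gene identity is
#' \eqn{I = J_{xy} / \sqrt{J_x J_y}} with the J terms summed over loci and
#' alleles, and \eqn{D = -\ln I}. Identity zero yields `Inf`, reported
#' explicitly.
#'
#' @param table A `kir_pop_freq` table (or any data.frame with
#'   `population` and gene columns in \[0, 1\]).
#' @param genes Optional restriction of the gene set used.
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
nei_distance <- function(table, genes = NULL) {
  m <- pop_freq_matrix(table)
  if (!is.null(genes)) {
    genes <- normalize_gene_names(genes, kir_panel())
    if (!all(genes %in% colnames(m))) stop("requested gene absent from the table")
    m <- m[, genes, drop = FALSE]
  }
  k <- nrow(m)
  d <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  jx <- rowSums(m^2 + (1 - m)^2)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      jxy <- sum(m[i, ] * m[j, ] + (1 - m[i, ]) * (1 - m[j, ]))
      ident <- jxy / sqrt(jx[i] * jx[j])
      d[i, j] <- d[j, i] <- if (ident <= 0) Inf else max(0, -log(ident))
    }
  }
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance input must be a square matrix")
  if (any(is.na(d))) stop("distance matrix contains NA")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  invisible(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths,
#' which NJ can produce on non-additive inputs, are clamped to zero with
#' the deficit transferred to the adjacent sibling branch so path lengths
#' are approximately preserved. Two taxa yield the trivial two-leaf tree
#' with the distance split evenly.
#'
#' @param d Symmetric distance matrix with labelled rows/columns.
#' @return Newick string (with trailing newline stripped); the `phylo`
#'   object is attached as attribute `"phylo"`.
#' @export
neighbor_joining <- function(d) {
  check_distance_matrix(d)
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  if (nrow(d) < 2L) stop("need at least two taxa")
  if (nrow(d) == 2L) {
    half <- d[1, 2] / 2
    nwk <- sprintf("(%s:%g,%s:%g);", labels[1], half, labels[2], half)
    tree <- ape::read.tree(text = nwk)
  } else {
    tree <- ape::nj(stats::as.dist(d))
    tree <- clamp_negative_branches(tree)
  }
  nwk <- ape::write.tree(tree)
  attr(nwk, "phylo") <- tree
  nwk
}

# Set negative edge lengths to zero, moving the deficit onto a sibling
# edge (same parent node) so that root-to-tip spans change as little as
# possible. Choice among siblings is deterministic (lowest edge index).
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sibs) > 0L) {
      tree$edge.length[sibs[1L]] <- tree$edge.length[sibs[1L]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Principal component analysis of population frequencies
#'
#' Column-centred (and, by default, unit-scaled: a correlation PCA, the
#' convention behind correlation-circle biplots) singular value
#' decomposition of the population x gene frequency matrix. Sign
#' convention: each component is flipped so its largest-magnitude gene
#' loading is positive. Genes with zero variance are dropped with a
#' warning when standardising.
#'
#' @param table A `kir_pop_freq` table.
#' @param standardize Scale genes to unit variance (default TRUE).
#' @return List with `scores` (populations x components), `loadings`
#'   (genes x components), `explained_variance` (fractions summing to 1),
#'   and `genes_used`.
#' @export
pca_frequencies <- function(table, standardize = TRUE) {
  m <- pop_freq_matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need at least 2 populations and 2 genes")
  if (standardize) {
    v <- apply(m, 2L, stats::var)
    if (any(v == 0)) {
      warning("dropping zero-variance gene(s): ",
              paste(colnames(m)[v == 0], collapse = ", "))
      m <- m[, v > 0, drop = FALSE]
    }
  }
  p <- stats::prcomp(m, center = TRUE, scale. = standardize)
  for (k in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, k]))
    if (p$rotation[i, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  list(scores = p$x, loadings = p$rotation,
       explained_variance = p$sdev^2 / sum(p$sdev^2),
       genes_used = colnames(m))
}

#' Hierarchical clustering of populations
#'
#' Agglomerative clustering of population rows on Euclidean distance
#' (complete linkage by default, the usual heatmap setting); returns the
#' pieces needed to render a clustered heatmap.
#'
#' @param table A `kir_pop_freq` table.
#' @param method Linkage passed to [stats::hclust()].
#' @return List with `hclust` (the fitted object), `leaf_order`
#'   (population names in dendrogram order) and `merge_heights`.
#' @export
hierarchical_clustering <- function(table, method = "complete") {
  m <- pop_freq_matrix(table)
  h <- stats::hclust(stats::dist(m, method = "euclidean"), method = method)
  list(hclust = h, leaf_order = rownames(m)[h$order], merge_heights = h$height)
}

#' Write a distance matrix as square CSV and PHYLIP lower-triangular text
#'
#' @param d Symmetric distance matrix.
#' @param csv_path,phylip_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_distance_matrix <- function(d, csv_path = NULL, phylip_path = NULL) {
  check_distance_matrix(d)
  written <- character()
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(d), csv_path, row.names = TRUE)
    written <- c(written, csv_path)
  }
  if (!is.null(phylip_path)) {
    lines <- c(sprintf("%5d", nrow(d)))
    for (i in seq_len(nrow(d))) {
      vals <- if (i > 1) paste(sprintf("%.6f", d[i, seq_len(i - 1)]),
                               collapse = " ") else ""
      lines <- c(lines, trimws(paste(formatC(rownames(d)[i], width = -10), vals)))
    }
    writeLines(lines, phylip_path)
    written <- c(written, phylip_path)
  }
  invisible(written)
}
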