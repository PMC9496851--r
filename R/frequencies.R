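#' Carrier frequency by direct count
#'
#' @param k Number of carrier individuals (vectorised).
#' @param n Cohort size.
#' @return `k / n` as a fraction.
#' @examples
#' carrier_frequency(153, 161)  # 0.9503...
#' @export
carrier_frequency <- function(k, n) {
  if (any(n <= 0)) stop("cohort size n must be positive")
  if (any(k < 0 | k > n)) stop("carrier count k must satisfy 0 <= k <= n")
  k / n
}

#' Bernstein gene frequency from a carrier frequency
#'
#' Under Hardy-Weinberg equilibrium a presence/absence locus with gene
#' frequency GF has carrier frequency \eqn{CF = 1 - (1 - GF)^2}; inverting
#' gives Bernstein's estimator \eqn{GF = 1 - \sqrt{1 - CF}}.
#'
#' @param cf Carrier frequency (fraction in \[0, 1\], vectorised).
#' @return Gene frequency as a fraction.
#' @examples
#' bernstein_gene_frequency(153 / 161)  # 0.777...
#' @export
bernstein_gene_frequency <- function(cf) {
  if (any(cf < 0 | cf > 1)) stop("carrier frequency must lie in [0, 1]")
  1 - sqrt(1 - cf)
}

#' Wald-type confidence interval for a Bernstein gene frequency
#'
#' Normal-approximation interval \eqn{GF \pm z \sqrt{GF(1-GF)/(2N)}} with
#' the denominator counted in gene copies (2N chromosomes); bounds are
#' clipped to \[0, 1\]. Degenerate frequencies (0 or 1) give a zero-width
#' interval, so fixed framework genes print as 100-100.
#'
#' @param gf Gene frequency (fraction, vectorised).
#' @param n Number of diploid individuals (the denominator is `2 * n`).
#' @param level Confidence level in (0, 1), default 0.95 (z = 1.96).
#' @return data.frame with columns `lower` and `upper` (fractions).
#' @export
gene_frequency_ci <- function(gf, n, level = 0.95) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1) {
    stop("confidence level must be a single value in (0, 1)")
  }
  if (any(gf < 0 | gf > 1)) stop("gene frequency must lie in [0, 1]")
  if (any(n <= 0)) stop("cohort size n must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(gf * (1 - gf) / (2 * n))
  data.frame(lower = pmax(0, gf - half), upper = pmin(1, gf + half))
}

#' Per-gene frequency records from carrier counts
#'
#' The chain direct count -> carrier frequency -> Bernstein gene frequency
#' -> confidence interval, applied per locus.
#'
#' @param carriers Integer vector of carrier counts (optionally named by gene).
#' @param n Cohort size (diploid individuals).
#' @param genes Gene names (defaults to `names(carriers)`).
#' @param level Confidence level.
#' @return data.frame with columns `gene`, `carriers`, `n`, `cf`, `gf`,
#'   `ci_lower`, `ci_upper`, `level` (frequencies as fractions).
#' @export
kir_frequency_records <- function(carriers, n, genes = names(carriers),
                                  level = 0.95) {
  if (is.null(genes)) genes <- paste0("locus", seq_along(carriers))
  cf <- carrier_frequency(carriers, n)
  gf <- bernstein_gene_frequency(cf)
  ci <- gene_frequency_ci(gf, n, level)
  data.frame(gene = genes, carriers = as.integer(carriers), n = as.integer(n),
             cf = cf, gf = gf, ci_lower = ci$lower, ci_upper = ci$upper,
             level = level, stringsAsFactors = FALSE)
}

#' Population gene-frequency summary from genotype profiles
#'
#' @param profiles A [kir_genotypes()] table.
#' @param panel A [kir_panel()].
#' @param level Confidence level.
#' @return One frequency record per panel gene (see [kir_frequency_records()]).
#' @export
population_summary <- function(profiles,
                               panel = attr(profiles, "panel") %||% kir_panel(),
                               level = 0.95) {
  if (nrow(profiles) == 0L) stop("need at least one profile")
  counts <- colSums(presence_matrix(profiles, panel))
  kir_frequency_records(counts, nrow(profiles), panel$genes, level)
}

#' KIR2DS4 full-length / deleted variant frequencies
#'
#' Tabulates the three typing categories (FF: only the full-length variant
#' detected, FD: both, DD: only the 22-bp-deleted variant) as percentages of
#' the whole cohort, and converts each category's carrier rate with
#' Bernstein's equation. Applying the equation per category (rather than per
#' allele count) mirrors the arithmetic of the study this package models;
#' it is not a standard allele-frequency estimator.
#'
#' @param profiles A [kir_genotypes()] table with `ds4_zygosity` calls.
#' @return data.frame with columns `category`, `n`, `carrier_pct`,
#'   `gene_pct`; individuals with unknown zygosity are excluded from the
#'   category counts but retained in the denominator.
#' @export
ds4_variant_frequencies <- function(profiles) {
  n_total <- nrow(profiles)
  if (n_total == 0L) stop("need at least one profile")
  z <- profiles$ds4_zygosity
  cats <- c("FF", "FD", "DD")
  counts <- vapply(cats, function(cc) sum(z == cc, na.rm = TRUE), integer(1))
  carrier_pct <- counts / n_total * 100
  gene_pct <- 100 * bernstein_gene_frequency(carrier_pct / 100)
  data.frame(category = cats, n = counts, carrier_pct = carrier_pct,
             gene_pct = gene_pct, stringsAsFactors = FALSE, row.names = NULL)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' printed percentage tables; base `round()` rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
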