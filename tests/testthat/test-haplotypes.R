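write_hap_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  header <- paste(c("name,cen_motif,tel_motif", PANEL$genes), collapse = ",")
  writeLines(c(header, rows), path)
  path
}

hap_row <- function(name, genes) {
  paste(c(name, "c", "t", as.integer(PANEL$genes %in% genes)), collapse = ",")
}

test_that("reference haplotypes load and violate structural rules loudly", {
  refs <- default_reference_haplotypes()
  expect_equal(nrow(refs), 7L)
  expect_setequal(ref_gene_set(refs, "cA01~tA01"), A_BACKGROUND)

  fw <- c("KIR3DL3", "KIR3DP1", "KIR2DL4", "KIR3DL2")
  # rule II: 2DL5 without 2DS3/2DS5
  p <- write_hap_csv(hap_row("bad", c(fw, "KIR2DL5", "KIR2DL3")))
  expect_error(load_reference_haplotypes(p), "rule II")
  # rule III: 2DL2 and 2DL3 together
  p <- write_hap_csv(hap_row("bad", c(fw, "KIR2DL2", "KIR2DL3")))
  expect_error(load_reference_haplotypes(p), "rule III")
  # rule IV: 2DS4 without 3DL1
  p <- write_hap_csv(hap_row("bad", c(fw, "KIR2DL3", "KIR2DS4")))
  expect_error(load_reference_haplotypes(p), "rule IV")
  # rule I: missing a framework gene
  p <- write_hap_csv(hap_row("bad", setdiff(A_BACKGROUND, "KIR3DL3")))
  expect_error(load_reference_haplotypes(p), "rule I")

  p <- write_hap_csv(hap_row("cA01~tA01", A_BACKGROUND))
  expect_silent(load_reference_haplotypes(p))
})

test_that("diplotype enumeration returns exactly the union-matching pairs", {
  refs <- default_reference_haplotypes()
  hits <- enumerate_compatible_diplotypes(A_BACKGROUND, refs)
  expect_equal(nrow(hits), 1L)
  expect_equal(unlist(hits), c(hap_a = "cA01~tA01", hap_b = "cA01~tA01"))

  u <- union(ref_gene_set(refs, "cA01~tA01"), ref_gene_set(refs, "cB02~tB01"))
  hits2 <- enumerate_compatible_diplotypes(u, refs)
  expect_true(any(hits2$hap_a == "cA01~tA01" & hits2$hap_b == "cB02~tB01"))
  expect_true(all(hits2$hap_a <= hits2$hap_b))

  # missing framework gene: rule I makes every pair union contain them
  expect_equal(nrow(enumerate_compatible_diplotypes(
    setdiff(A_BACKGROUND, "KIR2DL4"), refs)), 0L)
})

test_that("enumeration equals the brute-force oracle on random inputs", {
  set.seed(421)
  for (rep in 1:60) {
    refs <- random_reference_set(6L)
    # mix of true pair unions and arbitrary profiles
    if (rep %% 2 == 0) {
      ij <- sample(6L, 2L, replace = TRUE)
      genes <- union(ref_gene_set(refs, refs$name[ij[1]]),
                     ref_gene_set(refs, refs$name[ij[2]]))
    } else {
      genes <- union(PANEL$framework,
                     sample(PANEL$genes, sample(3:12, 1)))
    }
    got <- enumerate_compatible_diplotypes(genes, refs)
    want <- brute_force_diplotypes(genes, refs)
    ord <- function(d) d[order(d$hap_a, d$hap_b), , drop = FALSE]
    expect_equal(unname(as.matrix(ord(got))), unname(as.matrix(ord(want))))
  }
})

test_that("EM solves the closed-form cases exactly", {
  refs <- default_reference_haplotypes()
  # AA-only cohort: single compatible pair, converges immediately
  g <- make_profiles(rep(list(A_BACKGROUND), 5))
  est <- em_haplotype_frequencies(g, refs)
  expect_equal(unname(est$freqs["cA01~tA01"]), 1)
  expect_equal(est$residual, 0)
  expect_equal(sum(est$freqs) + est$residual, 1, tolerance = 1e-12)

  # allele counting: one (H1,H1) homozygote plus one (H1,H2) heterozygote
  two <- refs[refs$name %in% c("cA01~tA01", "cB02~tB01"), ]
  u <- union(ref_gene_set(refs, "cA01~tA01"), ref_gene_set(refs, "cB02~tB01"))
  g2 <- make_profiles(list(A_BACKGROUND, u))
  est2 <- em_haplotype_frequencies(g2, two)
  expect_equal(unname(est2$freqs["cA01~tA01"]), 0.75, tolerance = 1e-7)
  expect_equal(unname(est2$freqs["cB02~tB01"]), 0.25, tolerance = 1e-7)
})

test_that("EM log-likelihood is nondecreasing and estimates are order-invariant", {
  refs <- default_reference_haplotypes()
  g <- simulate_kir_population(sim_config(n = 300, seed = 11), refs)
  est <- em_haplotype_frequencies(g, refs)
  expect_true(all(diff(est$log_likelihood) > -1e-9))
  expect_true(all(est$freqs >= 0))
  expect_equal(sum(est$freqs) + est$residual, 1, tolerance = 1e-9)

  perm <- sample(nrow(g))
  g_shuf <- kir_genotypes(g$individual_id[perm],
                          presence_matrix(g)[perm, ],
                          g$ds4_zygosity[perm])
  est2 <- em_haplotype_frequencies(g_shuf, refs)
  expect_equal(est2$freqs, est$freqs, tolerance = 1e-9)
})

test_that("EM errors when nothing is explainable", {
  refs <- default_reference_haplotypes()
  g <- make_profiles(list(setdiff(A_BACKGROUND, "KIR2DL4")))
  expect_error(em_haplotype_frequencies(g, refs), "no individual")
})

test_that("resolution summary distinguishes both/one/none", {
  refs <- default_reference_haplotypes()
  g <- make_profiles(rep(list(A_BACKGROUND), 4))
  expect_equal(resolution_summary(g, refs),
               list(n_both_resolved = 4L, n_one_resolved = 0L,
                    n_unresolved = 0L, explained_percent = 100))

  # strict superset of one haplotype with an unexplained remainder
  g2 <- make_profiles(list(c(A_BACKGROUND, "KIR2DS3")))
  expect_equal(resolution_summary(g2, refs),
               list(n_both_resolved = 0L, n_one_resolved = 1L,
                    n_unresolved = 0L, explained_percent = 50))

  g3 <- make_profiles(list(setdiff(A_BACKGROUND, "KIR3DL3")))
  expect_equal(resolution_summary(g3, refs)$n_unresolved, 1L)
})

test_that("frequency table converts counts, flags rarity and orders stably", {
  counts <- c("cA01~tA01" = 134, "cA01~tB01 2DS5" = 53, "cB02~tB01" = 35,
              "cB02~tA01" = 32, "cA01~tB05" = 19, "cB01~tA01 2DS3" = 16,
              "cB01~tB01 2DS3" = 8)
  tab <- haplotype_frequency_table(counts / 322, n_chromosomes = 322)
  expect_equal(tab$count, unname(sort(counts, decreasing = TRUE)))
  expect_equal(round_half_up(tab$percent, 3),
               c(41.615, 16.460, 10.870, 9.938, 5.901, 4.969, 2.484))
  expect_equal(tab$below_threshold, c(rep(FALSE, 7)))

  # zero-frequency haplotypes omitted; ties ordered by name; rarity flagged
  tab2 <- haplotype_frequency_table(c(B = 0.4, A = 0.4, Z = 0, C = 0.2),
                                    n_chromosomes = 20)
  expect_equal(tab2$name, c("A", "B", "C"))
  expect_true(tab2$below_threshold[tab2$name == "C"])
})
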