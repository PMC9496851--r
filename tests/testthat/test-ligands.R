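test_that("allele classification unions epitopes with Bw4 provenance", {
  f <- classify_ligand_alleles(c("C*04", "C*07"))
  expect_true(f[["C1"]] && f[["C2"]])
  expect_false(any(f[c("Bw4", "A3", "A11")]))

  f2 <- classify_ligand_alleles("A*24")
  expect_true(f2[["Bw4"]] && f2[["Bw4_from_A"]])
  expect_false(f2[["Bw4_from_B"]] || f2[["Bw4_80I"]])

  f3 <- classify_ligand_alleles(character(0))
  expect_false(any(f3))

  f4 <- classify_ligand_alleles(c("B*51", "C*16"))
  expect_true(all(f4[c("Bw4", "Bw4_80I", "Bw4_from_B", "C1", "C16")]))
})

test_that("table classification flags untyped HLA-C and unknown groups", {
  hla <- data.frame(individual_id = c("a", "b"),
                    A_1 = c("A*03", "A*01"), A_2 = c("A*24", "A*02"),
                    B_1 = c("B*51", "B*07"), B_2 = c("B*07", "B*35"),
                    C_1 = c("C*04", NA), C_2 = c("C*07", NA),
                    stringsAsFactors = FALSE)
  lg <- classify_ligands(hla)
  expect_equal(lg$c_typed, c(TRUE, FALSE))
  expect_true(lg$A3[1] && lg$A3_A11[1] && lg$Bw4_80I[1])
  expect_false(any(unlist(lg[2, c("C1", "C2", "Bw4", "A3", "A11")])))

  hla$B_1[2] <- "B*9999"
  expect_warning(lg2 <- classify_ligands(hla), "B\\*9999")
  expect_equal(attr(lg2, "unknown_alleles")$individual_id, "b")
})

test_that("adding alleles can only switch flags on (monotonicity)", {
  lookup <- default_ligand_lookup()
  set.seed(77)
  pool <- lookup$allele_group
  for (i in 1:40) {
    base <- sample(pool, sample(1:4, 1))
    extra <- sample(pool, 1)
    f1 <- classify_ligand_alleles(base, lookup)
    f2 <- classify_ligand_alleles(c(base, extra), lookup)
    expect_true(all(f2[f1]))  # every flag set before stays set
  }
})

test_that("four-state pair tables partition the evaluated cohort", {
  ids <- paste0("i", 1:8)
  g <- make_profiles(c(rep(list(A_BACKGROUND), 5), rep(list(PANEL$genes), 3)),
                     ids = ids)
  lg <- make_ligand_flags(ids, C2 = c(TRUE, FALSE), C1 = TRUE, Bw4 = TRUE,
                          A3 = c(TRUE, TRUE, FALSE, FALSE))
  tab <- kir_hla_pair_table(g, lg)
  expect_true(all(tab$pp + tab$pa + tab$ap + tab$aa == tab$n))
  expect_equal(tab$n + tab$n_excluded, rep(8L, nrow(tab)))
  pcts <- tab$pp_pct + tab$pa_pct + tab$ap_pct + tab$aa_pct
  expect_equal(pcts, rep(100, nrow(tab)))

  # untyped HLA-C drops individuals from C pairs only
  lg2 <- make_ligand_flags(ids, C2 = TRUE, Bw4 = TRUE,
                           c_typed = c(rep(TRUE, 6), FALSE, FALSE))
  tab2 <- kir_hla_pair_table(g, lg2)
  expect_equal(tab2$n[tab2$pair == "2DL1/C2"], 6L)
  expect_equal(tab2$n[tab2$pair == "3DL1/Bw4"], 8L)

  # unmatched ids across tables are a hard error
  lg3 <- make_ligand_flags(c(ids[-1], "stranger"))
  expect_error(kir_hla_pair_table(g, lg3), "unmatched individual_id")
})

test_that("2DS4F pairs require a full-length copy", {
  ids <- c("ff", "fd", "dd", "neg")
  g <- make_profiles(c(rep(list(A_BACKGROUND), 3),
                       list(setdiff(A_BACKGROUND, "KIR2DS4"))),
                     ids = ids, ds4 = c("FF", "FD", "DD", NA))
  lg <- make_ligand_flags(ids, A3 = TRUE)
  tab <- kir_hla_pair_table(g, lg)
  row <- tab[tab$pair == "2DS4F/A3 A11", ]
  expect_equal(row$pp, 2L)   # FF and FD count as KIR-present
  expect_equal(row$ap, 2L)   # DD and 2DS4-negative do not
})

test_that("independent carriage reproduces product-expected cell fractions", {
  set.seed(90210)
  n <- 10000L
  kir_present <- stats::runif(n) < 0.6
  lig_present <- stats::runif(n) < 0.5
  ids <- sprintf("x%05d", 1:n)
  contents <- lapply(kir_present, function(p) {
    if (p) A_BACKGROUND else setdiff(A_BACKGROUND, "KIR2DL1")
  })
  g <- make_profiles(contents, ids = ids)
  lg <- make_ligand_flags(ids, C2 = lig_present)
  row <- kir_hla_pair_table(g, lg)
  row <- row[row$pair == "2DL1/C2", ]
  got <- unlist(row[, c("pp", "pa", "ap", "aa")]) / n
  want <- c(0.30, 0.30, 0.20, 0.20)
  se <- sqrt(want * (1 - want) / n)
  expect_true(all(abs(got - want) < 3 * se))
})

test_that("inhibitory multiplicity groups by exact satisfied pair sets", {
  ids <- paste0("i", 1:6)
  g <- make_profiles(rep(list(PANEL$genes), 6), ids = ids)
  lg <- make_ligand_flags(ids, C1 = TRUE, Bw4 = TRUE)
  m <- inhibitory_pair_multiplicity(g, lg)
  expect_equal(nrow(m), 1L)
  expect_equal(m$cardinality, 2L)
  expect_equal(m$combination, "2DL2/3+C1 + 3DL1+Bw4")
  expect_equal(m$percent, 100)

  # all four satisfied vs none
  lg2 <- make_ligand_flags(ids, C1 = TRUE, C2 = TRUE, Bw4 = TRUE, A3 = TRUE)
  m2 <- inhibitory_pair_multiplicity(g, lg2)
  expect_equal(m2$cardinality, 4L)

  g0 <- make_profiles(rep(list(setdiff(PANEL$genes,
                                       c("KIR2DL1", "KIR2DL2", "KIR2DL3",
                                         "KIR3DL1", "KIR3DL2"))), 2),
                      ids = ids[1:2])
  m0 <- inhibitory_pair_multiplicity(g0, make_ligand_flags(ids[1:2], C1 = TRUE))
  expect_equal(m0$cardinality, 0L)
  expect_equal(m0$combination, "none")

  # marginals: per-combination counts within a cardinality sum to its total
  set.seed(5)
  idsr <- sprintf("r%03d", 1:120)
  gr <- make_profiles(lapply(1:120, function(i) {
    union(PANEL$framework, sample(PANEL$genes, 8))
  }), ids = idsr)
  lgr <- make_ligand_flags(idsr, C1 = stats::runif(120) < .8,
                           C2 = stats::runif(120) < .6,
                           Bw4 = stats::runif(120) < .85,
                           A3 = stats::runif(120) < .2)
  mr <- inhibitory_pair_multiplicity(gr, lgr)
  expect_equal(sum(mr$n), 120L)
  totals <- attr(mr, "cardinality_totals")
  agg <- tapply(mr$n, mr$cardinality, sum)
  expect_equal(as.vector(agg), as.vector(totals))
})

test_that("ligand carriage summary reports the study-style percentages", {
  ids <- sprintf("c%03d", 1:161)
  lg <- make_ligand_flags(ids, C2 = c(rep(TRUE, 94), rep(FALSE, 67)),
                          A3 = c(rep(TRUE, 26), rep(FALSE, 135)),
                          A11 = c(rep(FALSE, 26), rep(TRUE, 10),
                                  rep(FALSE, 125)))
  s <- ligand_carriage_summary(lg)
  expect_equal(round_half_up(s$percent[s$flag == "C2"], 2), 58.39)
  expect_equal(round_half_up(s$percent[s$flag == "A3_A11"], 2), 22.36)
  expect_equal(s$percent[s$flag == "Bw4"], 0)
})
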