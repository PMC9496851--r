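test_that("Nei distance matches its closed form and the summation oracle", {
  m <- rbind(X = c(0.8, 0.5), Y = c(0.6, 0.5))
  colnames(m) <- c("KIR2DL1", "KIR2DL2")
  d <- nei_distance(make_pop_table(m))
  jxy <- 0.8 * 0.6 + 0.2 * 0.4 + 0.5 * 0.5 + 0.5 * 0.5
  jx <- 0.8^2 + 0.2^2 + 0.5
  jy <- 0.6^2 + 0.4^2 + 0.5
  expect_equal(d["X", "Y"], -log(jxy / sqrt(jx * jy)), tolerance = 1e-12)
  expect_equal(diag(d), c(X = 0, Y = 0))

  # identical frequencies (including fixed loci) give zero distance
  m2 <- rbind(A = c(1, 0.5, 0), B = c(1, 0.5, 0))
  colnames(m2) <- c("KIR2DL1", "KIR2DL2", "KIR2DL3")
  expect_equal(max(nei_distance(make_pop_table(m2))), 0)

  # opposite fixation at a single locus: identity zero, infinite distance
  m3 <- rbind(A = 1, B = 0)
  colnames(m3) <- "KIR2DL1"
  m3 <- cbind(m3, KIR2DL2 = c(1, 0))
  expect_equal(nei_distance(make_pop_table(m3))["A", "B"], Inf)
})

test_that("Nei distance agrees with the oracle on random tables and is invariant to gene order", {
  set.seed(314)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    m <- matrix(stats::runif(k * 8), k, 8,
                dimnames = list(paste0("P", 1:k), PANEL$genes[1:8]))
    d <- nei_distance(make_pop_table(m))
    expect_equal(d, t(d))
    expect_equal(diag(d), stats::setNames(rep(0, k), rownames(m)))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      expect_equal(d[i, j], nei_oracle(m[i, ], m[j, ]), tolerance = 1e-12)
    }
    shuf <- sample(ncol(m))
    d2 <- nei_distance(make_pop_table(m[, shuf]))
    expect_equal(d2, d, tolerance = 1e-12)
  }
})

test_that("three-taxon neighbor joining matches the closed-form branch lengths", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.4
  d["A", "C"] <- d["C", "A"] <- 0.6
  d["B", "C"] <- d["C", "B"] <- 0.8
  nwk <- neighbor_joining(d)
  tree <- attr(nwk, "phylo")
  tip_len <- tree$edge.length[match(1:3, tree$edge[, 2])]
  names(tip_len) <- tree$tip.label
  expect_equal(tip_len[["A"]], (0.4 + 0.6 - 0.8) / 2, tolerance = 1e-12)
  expect_equal(tip_len[["B"]], (0.4 + 0.8 - 0.6) / 2, tolerance = 1e-12)
  expect_equal(tip_len[["C"]], (0.6 + 0.8 - 0.4) / 2, tolerance = 1e-12)
})

test_that("neighbor joining recovers additive trees exactly and round-trips Newick", {
  set.seed(2718)
  for (rep in 1:20) {
    k <- sample(5:8, 1)
    true_tree <- ape::rtree(k, br = stats::runif)
    true_tree$edge.length <- true_tree$edge.length + 0.05
    dm <- ape::cophenetic.phylo(true_tree)
    dm <- dm[order(rownames(dm)), order(colnames(dm))]
    nwk <- neighbor_joining(dm)
    fitted <- attr(nwk, "phylo")
    back <- ape::cophenetic.phylo(fitted)[rownames(dm), colnames(dm)]
    expect_equal(back, dm, tolerance = 1e-9)
    reparsed <- ape::read.tree(text = as.character(nwk))
    expect_equal(ape::cophenetic.phylo(reparsed)[rownames(dm), colnames(dm)],
                 dm, tolerance = 1e-9)
  }
})

test_that("degenerate and invalid distance inputs are handled", {
  d <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  nwk <- neighbor_joining(d)
  tree <- attr(nwk, "phylo")
  expect_setequal(tree$tip.label, letters[1:4])
  expect_true(all(tree$edge.length >= 0))
  # deterministic: same input, same tree text
  expect_equal(as.character(neighbor_joining(d)), as.character(nwk))

  d2 <- d; d2[1, 2] <- 0.9
  expect_error(neighbor_joining(d2), "symmetric")
  d3 <- d; d3[1, 2] <- d3[2, 1] <- -0.1
  expect_error(neighbor_joining(d3), "nonnegative")

  two <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  t2 <- attr(neighbor_joining(two), "phylo")
  expect_equal(sum(t2$edge.length), 0.5)
})

test_that("PCA reconstructs the matrix, orders variance and fixes signs", {
  set.seed(99)
  m <- matrix(stats::runif(5 * 6, 0.2, 0.9), 5, 6,
              dimnames = list(paste0("P", 1:5), PANEL$genes[1:6]))
  p <- pca_frequencies(make_pop_table(m), standardize = FALSE)
  centred <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(p$scores %*% t(p$loadings), centred,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_equal(sum(p$explained_variance), 1)
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # sign convention: dominant loading of each component is positive
  for (k in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }

  # identical populations project to the origin
  m2 <- rbind(A = c(0.5, 0.7, 0.2), B = c(0.5, 0.7, 0.2))
  colnames(m2) <- PANEL$genes[1:3]
  p2 <- pca_frequencies(make_pop_table(m2), standardize = FALSE)
  expect_equal(max(abs(p2$scores)), 0)

  # variation confined to one gene loads PC1 entirely on it
  m3 <- rbind(A = c(0.9, 0.5, 0.5), B = c(0.5, 0.5, 0.5), C = c(0.1, 0.5, 0.5))
  colnames(m3) <- PANEL$genes[1:3]
  p3 <- pca_frequencies(make_pop_table(m3), standardize = FALSE)
  expect_equal(abs(p3$loadings["KIR2DL1", 1]), 1, tolerance = 1e-12)

  # zero-variance genes are dropped under standardisation
  expect_warning(p4 <- pca_frequencies(make_pop_table(m3), standardize = TRUE),
                 "zero-variance")
  expect_equal(p4$genes_used, "KIR2DL1")
})

test_that("hierarchical clustering merges by Euclidean distance", {
  m <- rbind(A = c(0.1, 0.1), B = c(0.1, 0.4), C = c(0.9, 0.9))
  colnames(m) <- PANEL$genes[1:2]
  cl <- hierarchical_clustering(make_pop_table(m))
  expect_equal(cl$merge_heights[1], 0.3, tolerance = 1e-12)
  # A and B merge first, so they are adjacent leaves; the outlier joins last
  expect_equal(abs(diff(match(c("A", "B"), cl$leaf_order))), 1L)
  expect_equal(cl$merge_heights[2], max(cl$merge_heights))

  two <- make_pop_table(m[1:2, ])
  cl2 <- hierarchical_clustering(two)
  expect_equal(cl2$merge_heights, 0.3, tolerance = 1e-12)

  same_m <- rbind(A = c(0.2, 0.2), B = c(0.2, 0.2))
  colnames(same_m) <- PANEL$genes[1:2]
  expect_equal(hierarchical_clustering(make_pop_table(same_m))$merge_heights, 0)
})

test_that("population tables read with percent auto-detection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("population,n,KIR2DL1,KIR2DL2",
               "P1,100,95,54", "P2,200,80,40"), path)
  expect_message(tab <- read_population_frequencies(path), "percent")
  expect_equal(tab$KIR2DL1, c(0.95, 0.80))
  d <- nei_distance(tab)
  expect_equal(dim(d), c(2L, 2L))

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("population,n,KIR2DL1,KIR2DL2",
               "P1,100,0.95,", "P2,200,0.8,0.4"), path2)
  expect_error(read_population_frequencies(path2), "missing")
})
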