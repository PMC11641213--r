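test_that("Nei distance reproduces hand-evaluated identities", {
  # identical units -> D = 0
  gm <- gm_from_calls(cbind(c("1/2", "1/2")), ids = c("x", "y"))
  D <- nei_distance(allele_frequencies(gm, by = "individual"))
  expect_equal(D["x", "y"], 0, tolerance = 1e-12)
  # x = (0.5, 0.5) vs y = (1, 0): D = -ln(0.5 / sqrt(0.5)) = 0.34657
  gm2 <- gm_from_calls(cbind(c("1/2", "1/1")), ids = c("x", "y"))
  D2 <- nei_distance(allele_frequencies(gm2, by = "individual"))
  expect_equal(D2["x", "y"], -log(0.5 / sqrt(0.5 * 1)), tolerance = 1e-12)
  expect_equal(D2["x", "y"], 0.3466, tolerance = 1e-4)
  # disjoint alleles -> J_xy = 0 -> capped ceiling
  gm3 <- gm_from_calls(cbind(c("1/1", "2/2")), ids = c("x", "y"))
  D3 <- nei_distance(allele_frequencies(gm3, by = "individual"))
  expect_equal(D3["x", "y"], 10)
  expect_equal(unname(diag(D3)), c(0, 0))
})

test_that("Nei distance pools identities over loci before the ratio", {
  # locus 1 disjoint, locus 2 identical: J sums keep the distance finite
  gm <- gm_from_calls(cbind(c("1/1", "2/2"), c("5/5", "5/5")),
                      ids = c("x", "y"))
  D <- nei_distance(allele_frequencies(gm, by = "individual"))
  expect_equal(D["x", "y"], -log(1 / 2), tolerance = 1e-12)
})

test_that("Nei distance is permutation-equivariant and NA-flags empty pairs", {
  set.seed(23)
  gm <- rand_gm(n_per = 6, L = 3, k = 1, A = 3)
  fr <- allele_frequencies(gm, by = "individual")
  D <- nei_distance(fr)
  perm <- sample(n_ind(gm))
  gm_p <- subset_accessions(gm, gm$ids[perm])
  D_p <- nei_distance(allele_frequencies(gm_p, by = "individual"))
  expect_equal(unclass(D_p), unclass(D)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
  # pair sharing no scored locus
  gm2 <- gm_from_calls(cbind(c("1/1", "."), c(".", "2/2")),
                       ids = c("x", "y"))
  expect_warning(D2 <- nei_distance(allele_frequencies(gm2,
                                                       by = "individual")),
                 "no scored locus")
  expect_true(is.na(D2["x", "y"]))
})

test_that("UPGMA reproduces the worked 3-leaf example and its cut", {
  d <- structure(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
                        dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
                 class = "dist_matrix")
  tr <- upgma(d)
  expect_equal(tr$height, c(1, 2))
  nwk <- to_newick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("A", "B", "C"))
  cop <- ape::cophenetic.phylo(ph)
  expect_equal(cop["A", "B"], 2)
  expect_equal(cop["A", "C"], 4)
  expect_equal(cop["B", "C"], 4)
  cl <- cut_clusters(tr, 2)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_false(cl[["A"]] == cl[["C"]])
  expect_equal(unname(cut_clusters(tr, 1)), rep(1L, 3), ignore_attr = TRUE)
  expect_equal(length(unique(cut_clusters(tr, 3))), 3L)
  expect_error(cut_clusters(tr, 4), "between 1 and")
})

test_that("all-zero distances give a height-zero tree in tie-break order", {
  d <- structure(matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4])),
                 class = "dist_matrix")
  tr <- upgma(d)
  expect_equal(tr$height, rep(0, 3))
  expect_equal(tr$merge[1L, ], c(-2L, -1L))  # a,b merge first (lexicographic)
})

test_that("UPGMA output is ultrametric and matches average-linkage hclust", {
  set.seed(24)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    X <- matrix(rnorm(n * 3), n)
    rownames(X) <- paste0("u", seq_len(n))
    D <- as.matrix(dist(X))
    d <- structure(D, class = "dist_matrix")
    tr <- upgma(d)
    # ultrametric: every leaf equidistant from the root
    ph <- as_phylo_tree(tr)
    depths <- ape::node.depth.edgelength(ph)[seq_len(n)]
    expect_lt(max(abs(depths - mean(depths))), 1e-9)
    # independent oracle: stats::hclust average linkage
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(sort(tr$height * 2), sort(hc$height), tolerance = 1e-12)
    expect_equal(stats::cophenetic(stats::as.hclust(tr)) * 2,
                 stats::cophenetic(hc), tolerance = 1e-12)
  }
})

test_that("cophenetic distances reproduce an ultrametric input exactly", {
  set.seed(25)
  X <- matrix(rnorm(8 * 2), 8)
  rownames(X) <- paste0("u", 1:8)
  d0 <- structure(as.matrix(dist(X)), class = "dist_matrix")
  ultra <- as.matrix(stats::cophenetic(stats::as.hclust(upgma(d0)))) * 2
  tr <- upgma(structure(ultra, class = "dist_matrix"))
  cop <- as.matrix(stats::cophenetic(stats::as.hclust(tr))) * 2
  expect_equal(cop[rownames(ultra), colnames(ultra)], ultra,
               tolerance = 1e-12)
})

test_that("UPGMA refuses undefined distances", {
  d <- structure(matrix(c(0, NA, NA, 0), 2, 2,
                        dimnames = list(c("a", "b"), c("a", "b"))),
                 class = "dist_matrix")
  expect_error(upgma(d), "undefined")
})

test_that("PCoA handles the two-point and degenerate cases in closed form", {
  d <- structure(matrix(c(0, 3, 3, 0), 2, 2,
                        dimnames = list(c("x", "y"), c("x", "y"))),
                 class = "dist_matrix")
  p <- pcoa(d, axes = 1)
  expect_equal(sort(unname(p$coordinates[, 1L])), c(-1.5, 1.5))
  expect_equal(p$eigenvalues[1L], 3^2 / 2)
  d0 <- structure(matrix(0, 3, 3, dimnames = list(letters[1:3],
                                                  letters[1:3])),
                  class = "dist_matrix")
  expect_warning(p0 <- pcoa(d0, axes = 2), "truncated")
  expect_true(all(abs(p0$eigenvalues) < 1e-12))
})

test_that("PCoA is exact for Euclidean distances and matches cmdscale", {
  set.seed(26)
  X <- matrix(rnorm(10 * 3), 10)
  rownames(X) <- paste0("u", 1:10)
  D <- as.matrix(dist(X))
  p <- pcoa(structure(D, class = "dist_matrix"), axes = 3)
  rec <- as.matrix(dist(p$coordinates))
  expect_lt(max(abs(rec - D)), 1e-9)
  # eigenvalue sum equals the trace of the centered matrix
  J <- diag(10) - matrix(1 / 10, 10, 10)
  B <- J %*% (-0.5 * D^2) %*% J
  expect_equal(sum(p$eigenvalues), sum(diag(B)), tolerance = 1e-9)
  # cross-check against classical scaling in stats
  cmd <- stats::cmdscale(stats::as.dist(D), k = 3, eig = TRUE)
  expect_equal(abs(unname(p$coordinates)), abs(unname(cmd$points)),
               tolerance = 1e-9)
  expect_equal(p$eigenvalues[1:3], cmd$eig[1:3], tolerance = 1e-9)
  expect_equal(sum(p$percent), 100 * sum(p$eigenvalues[1:3]) /
                 sum(p$eigenvalues[p$eigenvalues > 0]), tolerance = 1e-9)
})

test_that("shared-allele distance counts multiset overlap correctly", {
  gm <- gm_from_calls(cbind(c("1/1", "1/2", "3/4", "1/1")),
                      ids = c("w", "x", "y", "z"))
  D <- shared_allele_distance(gm)
  expect_equal(D["w", "x"], 0.5)   # share one of two alleles
  expect_equal(D["w", "y"], 1.0)   # disjoint
  expect_equal(D["w", "z"], 0.0)   # identical homozygotes
  expect_equal(D["x", "y"], 1.0)
})
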