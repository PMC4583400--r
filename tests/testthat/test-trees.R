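test_that("NJ exactly recovers additive trees of 4 to 8 taxa", {
  for (n in 4:8) {
    set.seed(n * 11)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- stats::runif(nrow(true$edge), 0.5, 3)
    Dm <- ape::cophenetic.phylo(true)
    nj <- nj_tree(dist_from_matrix(Dm))
    # additive matrices are reproduced exactly (topology + lengths)
    got <- ape::cophenetic.phylo(nj)[rownames(Dm), colnames(Dm)]
    expect_equal(got, Dm, tolerance = 1e-10)
  }
})

test_that("NJ output is invariant to taxon input order", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 8
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.1, 1)
    m <- m + t(m)
    ids <- paste0("t", 1:n)
    dimnames(m) <- list(ids, ids)
    perm <- sample(n)
    t1 <- nj_tree(dist_from_matrix(m), clamp_negative = FALSE)
    t2 <- nj_tree(dist_from_matrix(m[perm, perm]), clamp_negative = FALSE)
    expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(t2)[ids, ids],
                 ape::cophenetic.phylo(t1)[ids, ids], tolerance = 1e-8)
  }
})

test_that("three taxa give the closed-form star lengths", {
  m <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.4, 0.5, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dist_from_matrix(m))
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["A", "B"], 0.3, tolerance = 1e-12)
  expect_equal(co["A", "C"], 0.5, tolerance = 1e-12)
  expect_equal(co["B", "C"], 0.4, tolerance = 1e-12)
  # x_A = (dAB + dAC - dBC)/2 etc.
  tip_edge <- tr$edge.length[match(1:3, tr$edge[, 2L])]
  expect_equal(sort(tip_edge), sort(c(0.2, 0.1, 0.3)), tolerance = 1e-12)
})

test_that("equidistant matrices give a deterministic tree", {
  m <- matrix(0.4, 5, 5); diag(m) <- 0
  dimnames(m) <- list(paste0("t", 1:5), paste0("t", 1:5))
  t1 <- nj_tree(dist_from_matrix(m))
  t2 <- nj_tree(dist_from_matrix(m))
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("undefined or saturated distances are refused for tree building", {
  m <- matrix(0.2, 4, 4); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- NA
  expect_error(nj_tree(dist_from_matrix(m)), "prune")
  m2 <- matrix(0.2, 4, 4); diag(m2) <- 0
  m2[3, 4] <- m2[4, 3] <- Inf
  expect_error(upgma_tree(dist_from_matrix(m2)), "prune")
})

test_that("negative NJ branches are clamped with the deficit moved to the sister", {
  # a matrix known to produce a negative NJ edge
  m <- matrix(c(0.00, 0.30, 0.40, 0.59,
                0.30, 0.00, 0.91, 0.24,
                0.40, 0.91, 0.00, 0.90,
                0.59, 0.24, 0.90, 0.00), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- nj_tree(dist_from_matrix(m), clamp_negative = FALSE)
  clamped <- nj_tree(dist_from_matrix(m), clamp_negative = TRUE)
  expect_true(any(raw$edge.length < 0))
  expect_true(all(clamped$edge.length >= 0))
  # total tree length is preserved by the transfer
  expect_equal(sum(clamped$edge.length), sum(pmax(raw$edge.length, 0)) +
                 sum(pmin(raw$edge.length, 0)), tolerance = 1e-12)
})

test_that("UPGMA is rooted, ultrametric, and exact on ultrametric input", {
  true <- ape::rcoal(7)
  Dm <- ape::cophenetic.phylo(true)
  up <- upgma_tree(dist_from_matrix(Dm))
  expect_true(ape::is.rooted(up))
  expect_true(ape::is.ultrametric(up, tol = 1e-8))
  expect_equal(ape::cophenetic.phylo(up)[rownames(Dm), colnames(Dm)], Dm,
               tolerance = 1e-8)
  # two taxa at d = 0.1 -> root height 0.05
  m2 <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(tr2 <- upgma_tree(dist_from_matrix(m2)), "trivial")
  expect_equal(max(ape::node.depth.edgelength(tr2)), 0.05)
})

test_that("bootstrap support finds a clean split and is seed-reproducible", {
  # two tight groups separated by 8 transversion columns out of 40 (well
  # below K2P saturation even under column resampling): every resample
  # that keeps any separating column supports the split
  base_a <- strrep("A", 40)
  base_b <- paste0(strrep("C", 8), strrep("A", 32))
  seqs <- c(a1 = base_a, a2 = base_a, a3 = base_a,
            b1 = base_b, b2 = base_b, b3 = base_b)
  aln <- alignment_from_strings(seqs)
  tr <- bootstrap_support(aln, builder = "upgma", n_reps = 100, seed = 3)
  node_a <- ape::getMRCA(tr, c("a1", "a2", "a3"))
  ntip <- 6L
  expect_equal(tr$node.label[node_a - ntip], "100")
  # n_reps = 1 -> supports are 0 or 100
  tr1 <- bootstrap_support(aln, builder = "upgma", n_reps = 1, seed = 5)
  sup <- tr1$node.label[tr1$node.label != ""]
  expect_true(all(sup %in% c("0", "100")))
  # identical seed -> byte-identical newick
  trA <- bootstrap_support(aln, builder = "nj", n_reps = 25, seed = 11)
  trB <- bootstrap_support(aln, builder = "nj", n_reps = 25, seed = 11)
  expect_identical(ape::write.tree(trA), ape::write.tree(trB))
})
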