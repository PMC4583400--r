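test_that("K2P matches the hand-evaluated closed form", {
  expect_equal(k2p("AAAA", "AAAA")$d, 0)
  # one transition over 4 sites: P = 0.25, Q = 0, d = -log(0.5)/2
  r <- k2p("AAAA", "AAGA")
  expect_equal(r$P, 0.25)
  expect_equal(r$Q, 0)
  expect_equal(r$d, -0.5 * log(0.5), tolerance = 1e-12)
  # one transition + one transversion over 6 sites
  r2 <- k2p("AAAAAA", "AGAAAC")
  P <- 1 / 6; Q <- 1 / 6
  expect_equal(r2$d, -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
               tolerance = 1e-12)
  # pairwise deletion removes the gapped column
  r3 <- k2p("AA-A", "AAGA")
  expect_equal(r3$d, 0)
  expect_equal(r3$overlap, 3L)
  # zero overlap -> undefined, saturation -> Inf
  expect_true(is.na(k2p("--AA", "AA--")$d))
  expect_true(is.infinite(k2p("AAAA", "GGGG")$d))
  expect_true(k2p("AAAA", "GGGG")$saturated)
})

test_that("K2P is invariant under the transition relabeling A<->G, C<->T", {
  swap <- function(s) chartr("AGCT", "GATC", s)
  for (seed in 1:10) {
    set.seed(seed)
    a <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    expect_equal(k2p(a, b)$d, k2p(swap(a), swap(b))$d, tolerance = 1e-12)
  }
})

test_that("the matrix kernel agrees with per-pair K2P and with ape's K80", {
  a <- random_alignment(5, n = 8, L = 80, missing_prob = 0.15)
  D <- distance_matrix(a, "K2P")
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(D$d[i, j], k2p(a$seq[i, ], a$seq[j, ])$d, tolerance = 1e-12)
    expect_equal(D$overlap[i, j], k2p(a$seq[i, ], a$seq[j, ])$overlap)
  }
  # independent implementation: ape::dist.dna with pairwise deletion
  bin <- ape::as.DNAbin(tolower(a$seq))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  ok <- is.finite(D$d)
  expect_equal(D$d[ok], ref[rownames(D$d), colnames(D$d)][ok],
               tolerance = 1e-9)
})

test_that("K2P dominates the p-distance and both are symmetric with zero diagonal", {
  for (seed in 1:5) {
    a <- random_alignment(seed + 20, n = 6, L = 60, missing_prob = 0.1)
    K <- distance_matrix(a, "K2P")$d
    P <- distance_matrix(a, "p")$d
    expect_equal(K, t(K))
    expect_equal(P, t(P))
    expect_true(all(diag(K) == 0) && all(diag(P) == 0))
    ok <- is.finite(K) & is.finite(P)
    expect_true(all(K[ok] >= P[ok] - 1e-12))
    expect_true(all((K[ok] > P[ok]) == (K[ok] > 0)))
  }
})

test_that("estimated K2P converges to the generating distance at large length", {
  # simulate a pair with known transition/transversion proportions
  set.seed(99)
  L <- 1e5
  P_true <- 0.08; Q_true <- 0.04
  d_true <- -0.5 * log(1 - 2 * P_true - Q_true) - 0.25 * log(1 - 2 * Q_true)
  a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  b <- a
  what <- sample(c("ts", "tv", "same"), L, replace = TRUE,
                 prob = c(P_true, Q_true, 1 - P_true - Q_true))
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  b[what == "ts"] <- ts_map[a[what == "ts"]]
  b[what == "tv"] <- tv_map[a[what == "tv"]]
  est <- k2p(a, b)
  expect_lt(abs(est$d - d_true), 0.01)  # within one percentage point
})

test_that("haplotype collapse keeps first of identical records and absorbs fragments", {
  aln <- alignment_from_strings(
    c(a = "ACGT", b = "ACG-", c = "ACGT", d = "TTTT", e = "--GT"))
  hc <- collapse_haplotypes(aln)
  expect_equal(hc$alignment$info$id, c("a", "d"))
  expect_equal(hc$map$kept_id[hc$map$id == "b"], "a")
  expect_equal(hc$map$kept_id[hc$map$id == "e"], "a")
  # idempotent
  hc2 <- collapse_haplotypes(hc$alignment)
  expect_equal(hc2$alignment$info$id, hc$alignment$info$id)
  expect_equal(nrow(hc2$map), 0L)
  # a fragment that conflicts at a shared column is NOT collapsed
  aln2 <- alignment_from_strings(c(a = "ACGT", b = "AGG-"))
  expect_equal(n_records(collapse_haplotypes(aln2)$alignment), 2L)
})

test_that("distance exports round-trip the matrix", {
  a <- random_alignment(7, n = 5, L = 40)
  D <- distance_matrix(a)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(D, tsv)
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), D$d, ignore_attr = TRUE,
               tolerance = 1e-12)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_phylip(D, phy)
  first <- readLines(phy)[1]
  expect_equal(as.integer(trimws(first)), 5L)
  long <- tidy(D)
  expect_equal(nrow(long), 10L)
  expect_equal(long$d[long$id_a == D$ids[1] & long$id_b == D$ids[2]],
               D$d[1, 2])
})
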