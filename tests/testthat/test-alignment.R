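test_that("FASTA headers parse into species names and id levels", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x|Tanytarsus_mendax", "ACGT",
               ">y|Tanytarsus", "ACGA",
               ">z|Tanytarsus_sp.3XL", "AC-T",
               ">w|Tanytarsus_cf._curticornis", "ACNT"), fa)
  aln <- read_fasta(fa)
  expect_equal(n_records(aln), 4L)
  expect_equal(n_columns(aln), 4L)
  expect_equal(aln$info$species[1], "Tanytarsus mendax")
  expect_equal(aln$info$id_level, c("species", "genus_only", "group_code",
                                    "group_code"))
  expect_true(is.na(aln$info$species[2]))
})

test_that("ragged input and duplicate ids are rejected with the offender named", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|x", "ACGT", ">b|y", "ACGTT"), fa)
  expect_error(read_fasta(fa), "ragged.*b\\|y")
  expect_error(alignment_from_strings(c("a|x" = "AAAA", "a|y" = "CCCC")),
               "duplicate")
})

test_that("wrapped FASTA reads equal single-line FASTA and write round-trips", {
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|Genus_one", "ACGTAC", ">b|Genus_two", "TTGCAA"), fa1)
  writeLines(c(">a|Genus_one", "ACG", "TAC", ">b|Genus_two", "TTG", "CAA"), fa2)
  a1 <- read_fasta(fa1)
  a2 <- read_fasta(fa2)
  expect_identical(a1$seq, a2$seq)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(a1, out)
  back <- read_fasta(out)
  expect_identical(back$seq, a1$seq)
  expect_identical(back$info, a1$info)
})

test_that("a TSV label sheet overrides header parsing", {
  aln <- alignment_from_strings(c("a|Genus" = "ACGT", "b|Genus" = "ACGA"))
  sheet <- data.frame(id = "b", species = "Genus fixed", id_level = "species")
  aln2 <- set_labels(aln, sheet)
  expect_equal(aln2$info$species[2], "Genus fixed")
  expect_error(set_labels(aln, data.frame(id = "zz", species = "x",
                                          id_level = "species")), "zz")
})

test_that("ungapped_length counts non-gap non-N columns and is bounded", {
  aln <- alignment_from_strings(c(a = "AC-GN", b = "-----", c = "ACGTA"))
  expect_equal(unname(ungapped_length(aln)), c(3L, 0L, 5L))
  for (seed in 1:5) {
    a <- random_alignment(seed, n = 4, L = 30, missing_prob = 0.3)
    expect_true(all(ungapped_length(a) <= n_columns(a)))
  }
})

test_that("detect_frame minimises in-frame stop codons, smallest frame on ties", {
  # no stops anywhere -> tie across frames -> frame 1
  aln0 <- alignment_from_strings(c(a = "AAAAAA", b = "AAAAAA"))
  expect_equal(detect_frame(aln0, set_frame = FALSE), 1L)
  # brute-force oracle on random ungapped alignments (invertebrate mito
  # code: TAA and TAG are the only stops)
  stops_oracle <- function(seqs, frame) {
    start <- c(1L, 3L, 2L)[frame]
    total <- 0L
    for (s in seqs) {
      ch <- strsplit(s, "")[[1L]]
      i <- start
      while (i + 2L <= length(ch)) {
        total <- total + (paste(ch[i:(i + 2L)], collapse = "") %in%
                            c("TAA", "TAG"))
        i <- i + 3L
      }
    }
    total
  }
  for (seed in 1:10) {
    set.seed(seed)
    seqs <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), 33, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- paste0("s", 1:4, "|Genus")
    aln <- alignment_from_strings(seqs)
    counts <- vapply(1:3, function(f) stops_oracle(seqs, f), numeric(1))
    expect_equal(detect_frame(aln, set_frame = FALSE),
                 which.min(counts))
  }
})

test_that("detect_frame recovers the generating frame of simulated data", {
  for (f in 1:3) {
    cfg <- sim_config(n_species = 4, yule_rate = 10, theta = 0.005,
                      zipf_exponent = 0, min_n = 4, max_n = 4,
                      seq_length = 300, frame = f, truncation = FALSE,
                      genus_only_fraction = 0)
    sim <- simulate_barcodes(cfg, seed = 30 + f)
    expect_equal(detect_frame(sim$alignment, set_frame = FALSE), f)
  }
})
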