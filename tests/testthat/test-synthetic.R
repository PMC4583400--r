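small_cfg <- function(genus_only_fraction = 0.3) {
  sim_config(n_species = 5, yule_rate = 10, theta = 0.01, zipf_exponent = 1,
             min_n = 2, max_n = 8, seq_length = 300,
             genus_only_fraction = genus_only_fraction)
}

test_that("the same seed yields byte-identical FASTA and truth tables", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_sim_truth(simulate_barcodes(small_cfg(), seed = 77), f1, t1)
  write_sim_truth(simulate_barcodes(small_cfg(), seed = 77), f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  # a different seed changes the data
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_sim_truth(simulate_barcodes(small_cfg(), seed = 78), f3, t1)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("theta = 0 makes conspecific sequences identical and trivially clusterable", {
  cfg <- sim_config(n_species = 4, yule_rate = 8, theta = 0,
                    zipf_exponent = 0, min_n = 4, max_n = 4, seq_length = 400,
                    truncation = FALSE, genus_only_fraction = 0)
  sim <- simulate_barcodes(cfg, seed = 5)
  D <- distance_matrix(sim$alignment)
  for (s in unique(sim$species_map$species)) {
    ids <- sim$species_map$id[sim$species_map$species == s]
    expect_true(all(D$d[ids, ids] == 0))
  }
  between <- barcodegap:::finite_lower(D)
  t_small <- min(between[between > 0]) / 2
  p <- objective_cluster(D, t_small)
  expect_true(truth_eval(p, sim)$exact_match)
})

test_that("within-species divergence grows monotonically with theta", {
  mean_within <- vapply(c(0.002, 0.01, 0.04), function(th) {
    vals <- vapply(1:5, function(r) {
      cfg <- sim_config(n_species = 3, yule_rate = 8, theta = th,
                        zipf_exponent = 0, min_n = 4, max_n = 4,
                        seq_length = 400, truncation = FALSE,
                        genus_only_fraction = 0)
      sim <- simulate_barcodes(cfg, seed = 100 * th * 1000 + r)
      D <- distance_matrix(sim$alignment)
      w <- c()
      for (s in unique(sim$species_map$species)) {
        ids <- sim$species_map$id[sim$species_map$species == s]
        w <- c(w, D$d[ids, ids][lower.tri(D$d[ids, ids])])
      }
      mean(w)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_within) > 0))
})

test_that("truncation respects the minimum length; disabling it keeps full length", {
  cfg <- sim_config(n_species = 3, yule_rate = 10, theta = 0.01,
                    zipf_exponent = 0, min_n = 10, max_n = 10,
                    seq_length = 658, min_length = 507,
                    full_length_prob = 0.3, genus_only_fraction = 0)
  sim <- simulate_barcodes(cfg, seed = 3)
  lens <- ungapped_length(sim$alignment)
  expect_true(all(lens >= 507 & lens <= 658))
  expect_true(any(lens < 658))
  cfg2 <- sim_config(n_species = 3, yule_rate = 10, theta = 0.01,
                     zipf_exponent = 0, min_n = 5, max_n = 5,
                     seq_length = 658, truncation = FALSE,
                     genus_only_fraction = 0)
  expect_true(all(ungapped_length(simulate_barcodes(cfg2, 3)$alignment) == 658))
})

test_that("third-position AT bias matches the configured target", {
  cfg <- sim_config(n_species = 10, yule_rate = 15, theta = 0.01,
                    zipf_exponent = 0, min_n = 20, max_n = 20,
                    seq_length = 658, truncation = FALSE,
                    genus_only_fraction = 0)
  sim <- simulate_barcodes(cfg, seed = 9)  # 200 sequences, 658 bp
  aln <- detect_frame(sim$alignment)
  bc <- base_composition(aln)
  at3_target <- 100 * sum(cfg$base_freqs[c("A", "T"), 3])
  expect_lt(abs(bc$pct_AT[bc$position == "3rd"] - at3_target), 3)
})

test_that("truth_eval counts groups, splits and lumps correctly", {
  sim <- simulate_barcodes(small_cfg(), seed = 44)
  truth_part <- otu_partition(sim$species_map$id, sim$species_map$species)
  ev <- truth_eval(truth_part, sim)
  expect_equal(ev$adjusted_agreement, 1)
  expect_equal(ev$split_count, 0)
  expect_equal(ev$lump_count, 0)
  expect_true(ev$exact_match)
  # every sequence its own group
  n <- nrow(sim$species_map)
  singles <- otu_partition(sim$species_map$id, seq_len(n))
  sizes <- table(sim$species_map$species)
  expect_equal(truth_eval(singles, sim)$split_count, sum(sizes - 1L))
  # everything lumped
  onebig <- otu_partition(sim$species_map$id, rep(1L, n))
  expect_equal(truth_eval(onebig, sim)$lump_count,
               length(unique(sim$species_map$species)) - 1L)
  # id mismatch is an error
  expect_error(truth_eval(otu_partition("zz", 1L), sim), "ids")
})

test_that("generated labels respect the genus-only fraction and parse back", {
  sim <- simulate_barcodes(small_cfg(genus_only_fraction = 0.5), seed = 21)
  info <- sim$alignment$info
  expect_true(any(info$id_level == "genus_only"))
  expect_true(any(info$id_level == "species"))
  named <- info[info$id_level == "species", ]
  truth <- sim$species_map$species[match(named$id, sim$species_map$id)]
  expect_equal(named$species, truth)
})
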