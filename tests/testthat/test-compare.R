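make_labelled_alignment <- function(species) {
  # species: named character vector id -> species name or NA (genus only)
  n <- length(species)
  seqs <- rep(strrep("A", 8), n)
  labels <- ifelse(is.na(species), paste0(names(species), "|Genus"),
                   paste0(names(species), "|Genus_", gsub(" ", "_", species)))
  names(seqs) <- labels
  alignment_from_strings(seqs)
}

test_that("name propagation follows the one-name / no-name / conflict rules", {
  sp <- c(m1 = "mendax", u1 = NA, u2 = NA,       # one named species
          v1 = NA, v2 = NA,                      # no named species
          g1 = "glabrescens", b1 = "buckleyi", u3 = NA)  # conflict
  aln <- make_labelled_alignment(sp)
  part <- otu_partition(names(sp), c(1, 1, 1, 2, 2, 3, 3, 3))
  res <- propagate_names(part, aln)
  lab <- res$labels
  expect_equal(lab$species[lab$id %in% c("u1", "u2")],
               rep("Genus mendax", 2))
  expect_equal(lab$id_level[lab$id == "u1"], "species")
  # fresh group code for the nameless cluster
  expect_match(lab$species[lab$id == "v1"], "^cluster_")
  expect_equal(lab$species[lab$id == "v1"], lab$species[lab$id == "v2"])
  # conflict: named members keep their names, the unknown stays unnamed
  expect_equal(nrow(res$conflicts), 1L)
  expect_true(is.na(lab$species[lab$id == "u3"]))
  expect_equal(lab$species[lab$id == "g1"], "Genus glabrescens")
})

test_that("propagation never renames a species-level identification", {
  sp <- c(a = "alpha", b = "beta", u = NA)
  aln <- make_labelled_alignment(sp)
  # force all into one group: a and b keep their names despite the conflict
  part <- otu_partition(names(sp), c(1, 1, 1))
  res <- propagate_names(part, aln)
  expect_equal(res$labels$species[res$labels$id == "a"], "Genus alpha")
  expect_equal(res$labels$species[res$labels$id == "b"], "Genus beta")
})

test_that("discrimination rate counts species not sharing any group", {
  labels <- tibble::tibble(
    id = c("a1", "a2", "b1", "c1"),
    species = c("A", "A", "B", "C"),
    id_level = "species")
  # every species its own group
  p1 <- otu_partition(labels$id, c(1, 1, 2, 3))
  expect_equal(discrimination_rate(p1, labels)$rate, 1.0)
  # A and B share a group; C pure -> 1/3
  p2 <- otu_partition(labels$id, c(1, 1, 1, 2))
  r2 <- discrimination_rate(p2, labels)
  expect_equal(r2$rate, 1 / 3)
  expect_equal(r2$n_discriminated, 1L)
  # a species split across several pure groups still counts
  p3 <- otu_partition(labels$id, c(1, 2, 3, 4))
  expect_equal(discrimination_rate(p3, labels)$rate, 1.0)
  # the label partition itself always discriminates perfectly
  p4 <- otu_partition(labels$id, labels$species)
  expect_equal(discrimination_rate(p4, labels)$rate, 1.0)
})

test_that("divergence summaries report attained extremes and coherent means", {
  sim <- planted_gap_sim(17, S = 4, n_per = 4)
  D <- distance_matrix(sim$alignment)
  labels <- dplyr::mutate(sim$species_map, id_level = "species")
  ds <- divergence_summary(D, labels)
  g <- ds$global
  expect_lte(g$mean_intraspecific, g$max_intraspecific)
  expect_lte(g$min_interspecific, g$max_interspecific)
  # extremes are attained entries of the matrix
  expect_true(any(abs(D$d - g$max_interspecific) < 1e-12))
  expect_true(any(abs(D$d - g$max_intraspecific) < 1e-12))
  expect_equal(nrow(ds$within), 4L)
  expect_equal(nrow(ds$between), 6L)
  # two identical sequences of one species: zero within-divergence
  a0 <- make_labelled_alignment(c(x1 = "solo", x2 = "solo"))
  D0 <- distance_matrix(a0)
  expect_error(divergence_summary(D0, tibble::tibble(id = "x1", species = "solo")),
               ">= 2")
  ds0 <- divergence_summary(D0, tibble::tibble(id = c("x1", "x2"),
                                               species = "solo"))
  expect_equal(ds0$within$mean_within, 0)
  expect_equal(ds0$within$max_within, 0)
})

test_that("singleton species are excluded from the within table but listed", {
  sim <- planted_gap_sim(19, S = 3, n_per = 3)
  D <- distance_matrix(sim$alignment)
  labels <- sim$species_map
  labels$species[labels$id == labels$id[1]] <- "Loner unique"
  ds <- divergence_summary(D, labels)
  expect_true("Loner unique" %in% ds$singletons$species)
  expect_false("Loner unique" %in% ds$within$species)
})
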