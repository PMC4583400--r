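# Shared fixture generators.  Everything is built in code and seeded.

# Alignment with a planted barcode gap: star species tree of fixed depth,
# homogeneous substitution process (so K2P tracks the true distances),
# shallow within-species coalescent.  True between-species divergence
# 2 * depth; within-species pairwise distances ~ theta.
planted_gap_sim <- function(seed, S = 6, n_per = 6, theta = 0.002,
                            depth = 0.09, seq_length = 658) {
  st <- ape::read.tree(text = paste0(
    "(", paste0(sprintf("t%d:%f", seq_len(S), depth), collapse = ","), ");"))
  bf <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  cfg <- sim_config(n_species = S, theta = theta, stem_floor = 0,
                    min_n = n_per, max_n = n_per, seq_length = seq_length,
                    zipf_exponent = 0,
                    kappa = 4, codon_rates = c(1, 1, 1), base_freqs = bf,
                    truncation = FALSE, genus_only_fraction = 0)
  simulate_barcodes(cfg, seed = seed, species_tree = st)
}

# Ultrametric tree with deep interspecific stems and shallow species
# crowns (species depth << stem length): the GMYC strong-gap regime.
strong_gap_tree <- function(seed, S = 10, ntip_per = 5, crown = 0.02) {
  set.seed(seed)
  crown <- rep(crown, length.out = S)
  sp <- ape::rphylo(S, birth = 0.3, death = 0)
  sp$edge.length <- sp$edge.length + ifelse(sp$edge[, 2L] <= S, 1, 0)
  subs <- lapply(seq_len(S), function(s) {
    g <- ape::rcoal(ntip_per, tip.label = sprintf("s%02d_%d", s, seq_len(ntip_per)))
    g$edge.length <- g$edge.length * crown[s] / 2
    g
  })
  term <- match(seq_len(S), sp$edge[, 2L])
  for (s in seq_len(S)) {
    h <- max(ape::node.depth.edgelength(subs[[s]]))
    sp$edge.length[term[s]] <- sp$edge.length[term[s]] - h
  }
  nwk <- sub(";$", "", ape::write.tree(sp))
  for (s in seq_len(S)) {
    subnwk <- sub(";$", "", ape::write.tree(subs[[s]]))
    nwk <- sub(paste0("t", s, ":"), paste0(subnwk, ":"), nwk, fixed = TRUE)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

# Rooted tree whose within-species and between-species branch lengths are
# drawn from two exponential classes: the PTP generating model.
two_rate_tree <- function(seed, S = 8, ntip_per = 5, rate_within = 100,
                          rate_between = 5) {
  set.seed(seed)
  sp <- ape::rtree(S, rooted = TRUE)
  sp$edge.length <- stats::rexp(nrow(sp$edge), rate_between)
  subs <- lapply(seq_len(S), function(s) {
    g <- ape::rtree(ntip_per, rooted = TRUE)
    g$edge.length <- stats::rexp(nrow(g$edge), rate_within)
    g$tip.label <- sprintf("s%02d_%d", s, seq_len(ntip_per))
    g
  })
  nwk <- sub(";$", "", ape::write.tree(sp))
  for (s in seq_len(S)) {
    subnwk <- sub(";$", "", ape::write.tree(subs[[s]]))
    nwk <- sub(paste0("t", s, ":"), paste0(subnwk, ":"), nwk, fixed = TRUE)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

# Random aligned sequences over ACGT plus optional missing characters.
random_alignment <- function(seed, n = 6, L = 60, missing_prob = 0) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (missing_prob > 0) {
    mask <- matrix(stats::runif(n * L) < missing_prob, n, L)
    m[mask] <- sample(c("-", "N"), sum(mask), replace = TRUE)
  }
  alignment_from_strings(apply(m, 1L, paste, collapse = ""), frame = 1L)
}

# barcode_dist wrapper around a plain numeric matrix (for tree tests).
dist_from_matrix <- function(m, ids = rownames(m)) {
  if (is.null(ids)) ids <- paste0("x", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  structure(list(d = m, overlap = matrix(1000L, nrow(m), ncol(m)),
                 model = "K2P", ids = ids),
            class = "barcode_dist")
}

# Independent oracle for single-linkage clustering: transitive closure of
# the <= t adjacency by repeated boolean matrix multiplication.
brute_components <- function(d, t) {
  adj <- !is.na(d) & is.finite(d) & d <= t
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  match(apply(adj, 1L, function(r) paste(which(r), collapse = ",")),
        unique(apply(adj, 1L, function(r) paste(which(r), collapse = ","))))
}

# Location of the full study alignment, if the user has downloaded it.
# The 2790-sequence supplementary alignment is not redistributable inside
# the package; tests that replicate the published figures look for it at
# these locations and fail (not skip) when it is absent.
study_alignment_path <- function() {
  opt <- getOption("barcodegap.study_alignment", NULL)
  if (!is.null(opt)) return(opt)
  system.file("extdata", "DS-TABAC_alignment.fasta", package = "barcodegap")
}

load_study_alignment <- function() {
  path <- study_alignment_path()
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    testthat::fail(paste(
      "study alignment not available: place the 2790-sequence supplementary",
      "COI alignment at inst/extdata/DS-TABAC_alignment.fasta or set",
      "options(barcodegap.study_alignment = <path>)"))
    return(NULL)
  }
  detect_frame(read_fasta(path))
}
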