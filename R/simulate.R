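#' Simulation configuration for species-structured barcode datasets
#'
#' Defaults emulate the statistical structure of a large genus-wide COI
#' barcode survey: a Yule species tree with branch lengths in expected
#' substitutions/site, shallow within-species coalescent variation
#' (`theta` is directly the expected within-species pairwise distance),
#' highly skewed per-species sample sizes (bounded zipf, 1 to 430),
#' 658 bp sequences with strong third-position AT bias and
#' codon-position rate heterogeneity, and random end-truncation down to
#' at least 507 retained positions for the fraction of records that are
#' not full length.
#'
#' @param n_species number of species on the species tree.
#' @param yule_rate species-tree birth rate (per substitutions/site of
#'   depth): larger means shallower interspecific divergences.
#' @param stem_floor extra length added to every terminal branch of the
#'   species tree (substitutions/site).  A pure birth process produces
#'   arbitrarily recent splits; morphologically recognised species are
#'   not that young, so the floor guarantees every species pair at least
#'   `2 * stem_floor` of true divergence.
#' @param theta expected within-species pairwise distance
#'   (substitutions/site).
#' @param zipf_exponent,min_n,max_n per-species sample-size law:
#'   `P(n = k)` proportional to `k^-zipf_exponent` on `[min_n, max_n]`.
#' @param seq_length alignment length in bp.
#' @param kappa transition/transversion rate ratio of the HKY-like
#'   substitution process.
#' @param codon_rates relative rate multipliers of codon positions 1-3
#'   (rescaled to mean 1).
#' @param base_freqs 4 x 3 matrix of equilibrium frequencies (rows A, C,
#'   G, T; columns codon positions 1-3); the default reproduces observed
#'   COI composition with ~87.6% AT at third positions.
#' @param frame codon position of alignment column 1.
#' @param truncation enable random end-truncation.
#' @param min_length minimum retained (ungapped) length under truncation.
#' @param full_length_prob probability a record keeps full length.
#' @param genus_only_fraction fraction of records whose labels are
#'   downgraded to genus-level identifications (truth retains the map).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 121, yule_rate = 35, theta = 0.023,
                       stem_floor = 0.05,
                       zipf_exponent = 1.4, min_n = 1, max_n = 430,
                       seq_length = 658, kappa = 8,
                       codon_rates = c(0.35, 0.08, 2.57),
                       base_freqs = default_base_freqs(),
                       frame = 1L, truncation = TRUE,
                       min_length = min(507L, seq_length),
                       full_length_prob = 798 / 2790,
                       genus_only_fraction = 1242 / 2790) {
  stopifnot(n_species >= 1, theta >= 0, yule_rate > 0, all(codon_rates > 0),
            min_n >= 1, max_n >= min_n, min_length <= seq_length,
            frame %in% 1:3, full_length_prob >= 0, full_length_prob <= 1,
            genus_only_fraction >= 0, genus_only_fraction <= 1)
  if (!all(abs(colSums(base_freqs) - 1) < 1e-8)) {
    stop("base_freqs columns must each sum to 1")
  }
  stopifnot(stem_floor >= 0)
  structure(list(
    n_species = as.integer(n_species), yule_rate = yule_rate, theta = theta,
    stem_floor = stem_floor,
    zipf_exponent = zipf_exponent, min_n = as.integer(min_n),
    max_n = as.integer(max_n), seq_length = as.integer(seq_length),
    kappa = kappa, codon_rates = codon_rates / mean(codon_rates),
    base_freqs = base_freqs, frame = as.integer(frame),
    truncation = truncation, min_length = as.integer(min_length),
    full_length_prob = full_length_prob,
    genus_only_fraction = genus_only_fraction
  ), class = "sim_config")
}

#' Default codon-position equilibrium base frequencies
#'
#' Taken from observed per-position COI composition in barcode surveys
#' (third position heavily AT-biased).
#' @return A 4 x 3 matrix (rows A, C, G, T).
#' @export
default_base_freqs <- function() {
  m <- cbind(
    c(0.292, 0.173, 0.274, 0.260),  # position 1
    c(0.133, 0.272, 0.165, 0.430),  # position 2
    c(0.426, 0.089, 0.031, 0.450)   # position 3  (AT ~ 87.6%)
  )
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  colnames(m) <- paste0("pos", 1:3)
  m
}

# HKY eigendecomposition for one position class; returns a function P(t).
hky_transition <- function(pi, kappa, rate) {
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  purine <- c("A", "G"); pyrimidine <- c("C", "T")
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- (rownames(Q)[i] %in% purine) == (rownames(Q)[j] %in% purine)
    Q[i, j] <- pi[j] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))  # rescale: 1 expected substitution per unit
  Q <- Q * rate / mu
  # symmetrize with sqrt(pi) for a numerically stable eigendecomposition
  s <- sqrt(pi)
  B <- diag(s) %*% Q %*% diag(1 / s)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- diag(1 / s) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(s)
  function(t) {
    P <- U %*% diag(exp(eig$values * t)) %*% Uinv
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

# Bounded zipf sample-size draw.
rzipf <- function(n, exponent, min_n, max_n) {
  if (min_n == max_n) return(rep(min_n, n))
  k <- min_n:max_n
  p <- k^(-exponent)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

#' Simulate a species-structured barcode dataset with known truth
#'
#' Draws a Yule species tree, grafts a scaled within-species coalescent
#' genealogy onto each terminal branch (rescaled to fit when its depth
#' would exceed the branch), evolves sequences along the composite tree
#' under an HKY-like process with codon-position rate multipliers and
#' position-specific base frequencies, and applies random end-truncation.
#' Everything is driven by `seed`: the same seed yields byte-identical
#' output.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @param species_tree optional fixed ultrametric species tree with `S`
#'   tips labelled `t1..tS` and branch lengths in substitutions/site;
#'   overrides the Yule draw (useful for planting a guaranteed barcode
#'   gap).
#' @return A `sim_truth` list: `alignment` ([barcode_alignment()] whose
#'   labels reflect `genus_only_fraction`), `species_map` (tibble `id`,
#'   `species` — the truth), `gene_tree` ([ape::phylo], ultrametric,
#'   branch lengths in substitutions/site), `config`, `seed`.
#' @export
simulate_barcodes <- function(config = sim_config(), seed = 1L,
                              species_tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  S <- config$n_species
  sp_names <- sprintf("Simulatus species%03d", seq_len(S))
  n_per <- rzipf(S, config$zipf_exponent, config$min_n, config$max_n)

  # species tree (ultrametric, depths in substitutions/site)
  sp_tree <- if (!is.null(species_tree)) {
    stopifnot(length(species_tree$tip.label) == S)
    species_tree
  } else if (S == 1L) NULL else if (S == 2L) {
    h <- stats::rexp(1L, config$yule_rate)
    ape::read.tree(text = sprintf("(t1:%.10f,t2:%.10f);", h, h))
  } else {
    ape::rphylo(S, birth = config$yule_rate, death = 0)
  }

  # graft within-species coalescent genealogies onto terminal branches
  tip_ids <- lapply(seq_len(S), function(s)
    sprintf("S%03d_%04d", s, seq_len(n_per[s])))
  if (!is.null(sp_tree) && config$stem_floor > 0) {
    term <- match(seq_len(S), sp_tree$edge[, 2L])
    sp_tree$edge.length[term] <- sp_tree$edge.length[term] + config$stem_floor
  }
  gene_tree <- build_gene_tree(sp_tree, tip_ids, n_per, config$theta, S)

  aln_mat <- evolve_sequences(gene_tree, config)
  ids <- gene_tree$tip.label
  aln_mat <- aln_mat[ids, , drop = FALSE]
  aln_mat <- purge_stop_codons(aln_mat, config$frame)

  sp_of_tip <- as.integer(sub("^S([0-9]+)_.*$", "\\1", ids))
  species_map <- tibble(id = ids, species = sp_names[sp_of_tip])

  if (config$truncation) aln_mat <- truncate_ends(aln_mat, config)

  genus_only <- stats::runif(length(ids)) < config$genus_only_fraction
  info <- tibble(
    id = ids,
    label = ifelse(genus_only, paste0(ids, "|Simulatus"),
                   paste0(ids, "|", gsub(" ", "_", species_map$species))),
    species = ifelse(genus_only, NA_character_, species_map$species),
    id_level = ifelse(genus_only, "genus_only", "species")
  )
  aln <- barcode_alignment(aln_mat, info, frame = config$frame)
  structure(list(alignment = aln, species_map = species_map,
                 gene_tree = gene_tree, config = config, seed = seed),
            class = "sim_truth")
}

build_gene_tree <- function(sp_tree, tip_ids, n_per, theta, S) {
  subtree_newick <- function(s) {
    n <- n_per[s]
    if (n == 1L) return(list(nwk = tip_ids[[s]][1L], h = 0))
    g <- ape::rcoal(n, tip.label = tip_ids[[s]])
    g$edge.length <- g$edge.length * theta / 2
    h <- max(ape::node.depth.edgelength(g))
    list(nwk = sub(";$", "", ape::write.tree(g)), h = h)
  }
  if (S == 1L) {
    sub <- subtree_newick(1L)
    if (n_per[1L] == 1L) {
      stop("a single species with a single sequence is not a dataset")
    }
    return(ape::read.tree(text = paste0(sub$nwk, ";")))
  }
  subs <- lapply(seq_len(S), subtree_newick)
  # shorten each terminal branch by its genealogy's height so the composite
  # stays ultrametric; genealogies deeper than 95% of the branch are
  # rescaled to fit (documented bounded within-species divergence)
  term <- match(seq_len(S), sp_tree$edge[, 2L])
  for (s in seq_len(S)) {
    e <- term[s]
    len <- sp_tree$edge.length[e]
    h <- subs[[s]]$h
    if (h > 0.95 * len) {
      f <- 0.95 * len / h
      subs[[s]]$nwk <- rescale_newick(subs[[s]]$nwk, f)
      h <- 0.95 * len
    }
    sp_tree$edge.length[e] <- len - h
  }
  nwk <- sub(";$", "", ape::write.tree(sp_tree))
  for (s in seq_len(S)) {
    lab <- sp_tree$tip.label[s]
    wrapped <- if (n_per[s] == 1L) subs[[s]]$nwk else paste0(subs[[s]]$nwk)
    nwk <- sub(paste0(lab, ":"), paste0(wrapped, ":"), nwk, fixed = TRUE)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

# multiply all branch lengths inside a newick fragment by f
rescale_newick <- function(nwk, f) {
  g <- ape::read.tree(text = paste0(nwk, ";"))
  g$edge.length <- g$edge.length * f
  sub(";$", "", ape::write.tree(g))
}

evolve_sequences <- function(tree, config) {
  L <- config$seq_length
  pos <- codon_positions(L, config$frame)
  Pfun <- lapply(1:3, function(c3) {
    pi <- config$base_freqs[, c3]
    names(pi) <- rownames(config$base_freqs)
    hky_transition(pi, config$kappa, config$codon_rates[c3])
  })
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- matrix(0L, nnode, L)  # 1..4 = A C G T
  for (c3 in 1:3) {
    sel <- pos == c3
    states[root, sel] <- sample.int(4L, sum(sel), replace = TRUE,
                                    prob = config$base_freqs[, c3])
  }
  edges <- preorder_edges(tree)
  for (e in edges) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    child <- integer(L)
    for (c3 in 1:3) {
      P <- Pfun[[c3]](t)
      sel <- which(pos == c3)
      par_states <- states[p, sel]
      for (b in 1:4) {
        at <- sel[par_states == b]
        if (length(at)) {
          child[at] <- sample.int(4L, length(at), replace = TRUE, prob = P[b, ])
        }
      }
    }
    states[ch, ] <- child
  }
  m <- matrix(UNAMBIGUOUS[states[seq_len(ntip), ]], ntip, L)
  rownames(m) <- tree$tip.label
  m
}

preorder_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  out <- integer(0)
  stack <- children_of[[as.character(root)]]
  while (length(stack)) {
    e <- stack[1L]; stack <- stack[-1L]
    out <- c(out, e)
    ch <- tree$edge[e, 2L]
    kids <- children_of[[as.character(ch)]]
    if (!is.null(kids)) stack <- c(kids, stack)
  }
  out
}

# Functional COI carries no in-frame stop codons (purifying selection);
# the neutral substitution process does not know that, so in-frame TAA/TAG
# codons (invertebrate mitochondrial code) are repaired by flipping their
# middle base to C.  This is what makes the generating frame detectable,
# exactly as in real barcodes.
purge_stop_codons <- function(m, frame) {
  L <- ncol(m)
  pos <- codon_positions(L, frame)
  starts <- which(pos == 1L)
  starts <- starts[starts + 2L <= L]
  for (s in starts) {
    is_stop <- m[, s] == "T" & m[, s + 1L] == "A" &
      (m[, s + 2L] == "A" | m[, s + 2L] == "G")
    if (any(is_stop)) m[is_stop, s + 1L] <- "C"
  }
  m
}

truncate_ends <- function(m, config) {
  L <- ncol(m)
  if (config$min_length >= L) return(m)
  for (i in seq_len(nrow(m))) {
    if (stats::runif(1) < config$full_length_prob) next
    keep <- sample(config$min_length:(L - 1L), 1L)
    lead <- sample(0:(L - keep), 1L)
    if (lead > 0L) m[i, seq_len(lead)] <- "-"
    if (lead + keep < L) m[i, (lead + keep + 1L):L] <- "-"
  }
  m
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth: ", nrow(x$species_map), " sequences, ",
      length(unique(x$species_map$species)), " species (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Evaluate a partition against simulation truth
#'
#' Compares an inferred partition with the true sequence-to-species map:
#' group count, adjusted Rand index, and the number of splits (extra
#' groups cutting through true species) and lumps (species pairs fused
#' into shared groups).  Splits are counted as `sum over species of
#' (number of inferred groups intersecting it - 1)`; lumps as `sum over
#' inferred groups of (number of species intersecting it - 1)`.
#'
#' @param partition an [otu_partition()] over the truth's ids.
#' @param truth a `sim_truth` from [simulate_barcodes()] (or any list with
#'   a `species_map` tibble).
#' @return A tibble row: `n_groups`, `n_species_true`,
#'   `adjusted_agreement`, `split_count`, `lump_count`, `exact_match`.
#' @export
truth_eval <- function(partition, truth) {
  sm <- truth$species_map
  if (!setequal(partition$id, sm$id)) stop("partition ids do not match truth ids")
  ord <- match(sm$id, partition$id)
  g <- partition$group[ord]
  s <- sm$species
  tab <- table(s, g)
  splits <- sum(rowSums(tab > 0) - 1L)
  lumps <- sum(colSums(tab > 0) - 1L)
  tibble(
    n_groups = length(unique(g)),
    n_species_true = length(unique(s)),
    adjusted_agreement = mclust::adjustedRandIndex(s, g),
    split_count = splits,
    lump_count = lumps,
    exact_match = splits == 0L && lumps == 0L
  )
}

#' Write simulation truth to FASTA + TSV
#'
#' @param truth a `sim_truth`.
#' @param fasta,tsv output paths.
#' @return Invisibly, the two paths.
#' @export
write_sim_truth <- function(truth, fasta, tsv) {
  write_fasta(truth$alignment, fasta)
  utils::write.table(truth$species_map, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta, tsv))
}
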