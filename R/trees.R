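check_complete <- function(D) {
  v <- D$d[lower.tri(D$d)]
  if (anyNA(v) || any(is.infinite(v))) {
    stop("distance matrix contains undefined or saturated entries; ",
         "prune the offending sequences before tree building")
  }
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a fully defined
#' distance matrix.  Undefined or saturated entries are refused with an
#' instruction to prune; a distance is never invented.  Negative branch
#' lengths, which NJ can produce, are clamped to zero with the deficit
#' transferred to the sister branch, so path lengths through the parent
#' node are preserved.  Clamping changes branch lengths, never topology.
#'
#' @param D a `barcode_dist` from [distance_matrix()].
#' @param clamp_negative clamp negative branch lengths (default `TRUE`).
#' @return An [ape::phylo] (unrooted).
#' @export
nj_tree <- function(D, clamp_negative = TRUE) {
  check_complete(D)
  n <- length(D$ids)
  if (n < 3L) {
    warning("fewer than 3 sequences: returning trivial tree")
    return(trivial_tree(D))
  }
  tr <- ape::nj(stats::as.dist(D$d))
  if (clamp_negative) tr <- clamp_negative_branches(tr)
  tr
}

trivial_tree <- function(D) {
  n <- length(D$ids)
  if (n == 1L) stop("cannot build a tree from one sequence")
  ape::read.tree(text = sprintf("(%s:%f,%s:%f);", D$ids[1L], D$d[1, 2] / 2,
                                D$ids[2L], D$d[1, 2] / 2))
}

# Zero out negative edges; the deficit is added to the sister edge (the
# other child of the same parent) so the parent's path lengths survive.
clamp_negative_branches <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[which.min(tr$edge.length[neg])]
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs) > 0L) {
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
      if (tr$edge.length[sibs[1L]] < 0) tr$edge.length[sibs[1L]] <- 0
    }
  }
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; the height of each internal node is half
#' the between-cluster average distance, so the result is rooted and
#' ultrametric.  Ships as the package's deterministic stand-in source of
#' ultrametric trees for GMYC (any user-supplied ultrametric newick works
#' equally).
#'
#' @inheritParams nj_tree
#' @return A rooted ultrametric [ape::phylo].
#' @export
upgma_tree <- function(D) {
  check_complete(D)
  n <- length(D$ids)
  if (n < 3L) {
    warning("fewer than 3 sequences: returning trivial tree")
    return(trivial_tree(D))
  }
  hc <- stats::hclust(stats::as.dist(D$d), method = "average")
  ape::as.phylo(hc)
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree with
#' the same model and builder, and annotates each internal bipartition of
#' the reference tree with its percent occurrence (integer, 0-100) in the
#' replicates.  Replicates whose resampled distance matrix has undefined
#' or saturated entries are dropped, counted and warned about.  Fully
#' seeded: identical seeds give byte-identical newick output.
#'
#' @param aln a [barcode_alignment()].
#' @param model distance model, `"K2P"` or `"p"`.
#' @param builder `"nj"` or `"upgma"`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return The reference [ape::phylo] with `node.label` set to integer
#'   percent support (root label empty) and attribute `n_valid_reps`.
#' @export
bootstrap_support <- function(aln, model = "K2P", builder = c("nj", "upgma"),
                              n_reps = 100L, seed = 1L) {
  builder <- match.arg(builder)
  stopifnot(n_reps >= 1L)
  build <- function(a) {
    D <- distance_matrix(a, model)
    check_complete(D)
    if (builder == "nj") nj_tree(D) else upgma_tree(D)
  }
  ref <- build(aln)
  set.seed(seed)
  boots <- vector("list", n_reps)
  dropped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(n_columns(aln), replace = TRUE)
    rep_tree <- tryCatch(build(aln[, cols]), error = function(e) NULL)
    if (is.null(rep_tree)) dropped <- dropped + 1L else boots[[r]] <- rep_tree
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  if (dropped > 0L) {
    warning(dropped, " replicate(s) dropped (undefined resampled distances)")
  }
  if (length(boots) == 0L) stop("all bootstrap replicates failed")
  cnt <- ape::prop.clades(ref, boots, rooted = builder == "upgma")
  cnt[is.na(cnt)] <- 0L
  support <- as.integer(round(100 * cnt / length(boots)))
  ref$node.label <- as.character(support)
  ref$node.label[1L] <- ""  # root bipartition is trivial
  attr(ref, "n_valid_reps") <- length(boots)
  ref
}
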