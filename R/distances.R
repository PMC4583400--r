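#' Pairwise K2P distance between two sequences
#'
#' Computes the Kimura 2-parameter distance over the jointly unambiguous
#' columns of two aligned sequences (pairwise deletion): with transition
#' proportion `P` and transversion proportion `Q`,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param a,b character vectors (single residues) or strings of equal
#'   length.
#' @return A list with `d`, `P`, `Q`, `overlap` and logical `saturated`.
#'   `d` is `NA` when the overlap is zero and `Inf` when the logarithms'
#'   arguments are non-positive (saturation).
#' @examples
#' k2p("AAAA", "AAGA")$d  # -0.5 * log(0.5)
#' @export
k2p <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  ok <- a %in% UNAMBIGUOUS & b %in% UNAMBIGUOUS
  overlap <- sum(ok)
  if (overlap == 0L) {
    return(list(d = NA_real_, P = NA_real_, Q = NA_real_, overlap = 0L,
                saturated = FALSE))
  }
  aa <- a[ok]; bb <- b[ok]
  diff <- aa != bb
  purine <- c("A", "G")
  ts <- sum(diff & (aa %in% purine) == (bb %in% purine))
  tv <- sum(diff) - ts
  P <- ts / overlap; Q <- tv / overlap
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  saturated <- w1 <= 0 || w2 <= 0
  d <- if (saturated) Inf else -0.5 * log(w1) - 0.25 * log(w2)
  list(d = d, P = P, Q = Q, overlap = overlap, saturated = saturated)
}

# Pair count matrices for a whole alignment via indicator cross-products:
# overlap (jointly unambiguous columns), matches, transitions.  BLAS does
# the heavy lifting, so the full 2790-sequence study scale is fast.
pair_counts <- function(aln) {
  ind <- lapply(UNAMBIGUOUS, function(b) (aln$seq == b) * 1)
  names(ind) <- UNAMBIGUOUS
  valid <- ind$A + ind$C + ind$G + ind$T
  overlap <- tcrossprod(valid)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  ts <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  list(overlap = overlap, matches = matches, transitions = ts,
       transversions = overlap - matches - ts)
}

#' Pairwise distance matrix with pairwise deletion
#'
#' Computes all pairwise K2P or p-distances of an alignment, deleting
#' columns pairwise wherever either member carries a gap, `N` or ambiguity
#' code.  Pairs with zero overlap are stored as `NA` (undefined — never
#' invented); saturated K2P pairs (log argument non-positive) are `Inf`.
#'
#' @param aln a [barcode_alignment()].
#' @param model `"K2P"` (default) or `"p"`.
#' @return A `barcode_dist` object: list with `d` and `overlap` (square
#'   symmetric matrices with zero diagonal, dimnames = ids), `model`, and
#'   `ids`.
#' @export
distance_matrix <- function(aln, model = c("K2P", "p")) {
  model <- match.arg(model)
  if (n_records(aln) < 2L) stop("need at least 2 sequences")
  pc <- pair_counts(aln)
  V <- pc$overlap
  safeV <- ifelse(V > 0, V, NA_real_)
  if (model == "p") {
    d <- (pc$transitions + pc$transversions) / safeV
  } else {
    P <- pc$transitions / safeV
    Q <- pc$transversions / safeV
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    d <- ifelse(w1 > 0 & w2 > 0, -0.5 * log(pmax(w1, 1e-300)) -
                  0.25 * log(pmax(w2, 1e-300)), Inf)
    d[is.na(P)] <- NA_real_
  }
  diag(d) <- 0
  ids <- aln$info$id
  dimnames(d) <- list(ids, ids)
  dimnames(V) <- list(ids, ids)
  structure(list(d = d, overlap = V, model = model, ids = ids),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  n <- length(x$ids)
  v <- finite_lower(x)
  cat("barcode_dist: ", n, " sequences, model ", x$model, "\n", sep = "")
  cat("  defined pairs: ", length(v), " of ", n * (n - 1) / 2,
      "; range ", if (length(v)) paste(signif(range(v), 4), collapse = " - ")
      else "-", "\n", sep = "")
  invisible(x)
}

# Vector of defined, finite lower-triangle distances.
finite_lower <- function(D) {
  v <- D$d[lower.tri(D$d)]
  v[is.finite(v)]
}

#' Tidy a distance matrix into long format
#'
#' @param x a `barcode_dist`.
#' @param ... ignored.
#' @return A tibble with columns `id_a`, `id_b`, `d`, `overlap` (each
#'   unordered pair once).
#' @exportS3Method generics::tidy
tidy.barcode_dist <- function(x, ...) {
  lt <- which(lower.tri(x$d), arr.ind = TRUE)
  tibble(id_a = x$ids[lt[, 2L]], id_b = x$ids[lt[, 1L]],
         d = x$d[lt], overlap = as.integer(x$overlap[lt]))
}

#' Export a distance matrix
#'
#' `write_distance_tsv()` writes the square matrix as TSV (MEGA-like
#' layout, ids in the first column); `write_phylip()` writes the square
#' PHYLIP format used by tree tools.  Undefined pairs are written as `NA`
#' (TSV) or `-1` (PHYLIP, which has no missing-value convention).
#'
#' @param D a `barcode_dist`. @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(id = D$ids, D$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
write_phylip <- function(D, path) {
  n <- length(D$ids)
  m <- D$d
  m[!is.finite(m)] <- -1
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste(formatC(D$ids[i], width = 10, flag = "-"),
                     paste(sprintf("%.8f", m[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse an alignment to unique haplotypes
#'
#' A record is removed when some kept record agrees with it at every
#' column where both are unambiguous *and* covers at least its unambiguous
#' columns (so shorter fragments collapse into compatible longer
#' sequences).  Among mutually identical records the first in input order
#' is kept.  The operation is idempotent.
#'
#' @param aln a [barcode_alignment()].
#' @return A list with `alignment` (the reduced [barcode_alignment()]) and
#'   `map`, a tibble with columns `id` (removed) and `kept_id`.
#' @export
collapse_haplotypes <- function(aln) {
  n <- n_records(aln)
  if (n == 1L) {
    return(list(alignment = aln,
                map = tibble(id = character(), kept_id = character())))
  }
  pc <- pair_counts(aln)
  u <- rowSums(matrix(aln$seq %in% UNAMBIGUOUS, nrow = n))  # unambiguous count
  agree <- pc$matches == pc$overlap
  # covers[i, j]: record j covers record i (all of i's unambiguous columns
  # are unambiguous in j) with full agreement on the joint columns.
  covers <- agree & (pc$overlap == u)
  diag(covers) <- FALSE
  uj <- matrix(u, n, n, byrow = TRUE)
  ui <- matrix(u, n, n)
  order_mat <- matrix(seq_len(n), n, n, byrow = TRUE) < matrix(seq_len(n), n, n)
  dominated <- covers & (uj > ui | (uj == ui & order_mat))
  removed <- rowSums(dominated) > 0
  kept_idx <- which(!removed)
  map <- purrr::map_dfr(which(removed), function(i) {
    js <- which(dominated[i, ] & !removed)
    tibble(id = aln$info$id[i], kept_id = aln$info$id[js[1L]])
  })
  list(alignment = aln[kept_idx, ], map = map)
}
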