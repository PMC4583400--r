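#' Maximum-likelihood Poisson tree process delimitation
#'
#' Delimits species on a rooted tree with substitution branch lengths by
#' modelling within-species and between-species branch lengths as two
#' exponential classes.  A candidate delimitation is a set of species-root
#' nodes (an antichain covering every tip); edges strictly inside a
#' species subtree are "within", all others — stems and backbone — are
#' "between".  Class rates are profiled out analytically, so the
#' log-likelihood of a delimitation is
#' `sum_c N_c * (log(N_c / L_c) - 1)` over the two classes (empty classes
#' contribute 0), with `N_c` edges and `L_c` total length.
#'
#' The search is a seeded greedy hill climb: at each step every split of
#' a species root into its children and every merge of a sibling set back
#' into its parent is scored, and the best strictly improving move is
#' applied (ties broken by the seeded RNG) until no move improves.  The
#' accepted-move likelihood trace within a climb is therefore
#' non-decreasing.  Because the move set is local, the climb is run from
#' many starts — the single-class fit at the root, the all-singletons
#' fit at the tips, antichains cut at a grid of subtree-height
#' thresholds, and `n_restarts` random antichains — and the best final
#' likelihood wins.
#'
#' Branch lengths shorter than `min_branch` are floored at it before
#' fitting: a zero-length branch (zero observed substitutions) would
#' otherwise let the within-species rate estimate diverge, making the
#' "likelihood" of any partition isolating zero-length branches
#' unbounded.
#'
#' @param tree a rooted [ape::phylo] with branch lengths `>= 0`, >= 3 tips.
#' @param seed integer seed for restarts and tie-breaking; identical seeds
#'   give identical results.
#' @param n_restarts number of additional random-antichain starts.
#' @param min_branch floor applied to branch lengths (substitutions/site).
#' @return A `ptp_fit` with elements `partition` ([otu_partition()]),
#'   `n_entities`, `lambda_within`, `lambda_between`, `logL`,
#'   `logL_single`, `trace` (accepted-move log-likelihoods of the winning
#'   climb), `degenerate`.
#' @export
ptp_fit <- function(tree, seed = 1L, n_restarts = 5L, min_branch = 1e-4) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("need at least 3 tips")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must have non-negative branch lengths")
  }
  degenerate <- stats::var(tree$edge.length) < 1e-24
  tree$edge.length <- pmax(tree$edge.length, min_branch)
  set.seed(seed)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  children <- vector("list", nnode)
  edge_len_to <- numeric(nnode)  # length of the edge above each node
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    children[[p]] <- c(children[[p]], c)
    edge_len_to[c] <- tree$edge.length[e]
  }
  # child-edge sums per internal node drive O(1) move deltas
  kdeg <- lengths(children)
  child_len <- vapply(seq_len(nnode), function(v)
    sum(edge_len_to[children[[v]]]), numeric(1))
  total_N <- nrow(tree$edge)
  total_L <- sum(tree$edge.length)
  cl <- function(N, L) if (N == 0L) 0 else N * (log(N / max(L, 1e-300)) - 1)
  obj <- function(Nw, Lw) cl(Nw, Lw) + cl(total_N - Nw, total_L - Lw)

  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  kdeg_below <- integer(nnode)  # edges strictly below each node
  len_below <- numeric(nnode)
  for (v in postorder_nodes(tree)) {  # children before parents
    if (v > ntip) {
      ch <- children[[v]]
      kdeg_below[v] <- sum(1L + kdeg_below[ch])
      len_below[v] <- sum(edge_len_to[ch] + len_below[ch])
    }
  }
  climb <- function(R) {
    Nw <- sum(kdeg_below[R]); Lw <- sum(len_below[R])
    trace <- obj(Nw, Lw)
    repeat {
      in_R <- logical(nnode); in_R[R] <- TRUE
      cur <- obj(Nw, Lw)
      cand <- list()
      for (r in R[R > ntip]) {
        cand[[length(cand) + 1L]] <- list(kind = "split", node = r,
          val = obj(Nw - kdeg[r], Lw - child_len[r]))
      }
      pars <- unique(parent[R[R != root]])
      for (p in pars) {
        if (all(in_R[children[[p]]])) {
          cand[[length(cand) + 1L]] <- list(kind = "merge", node = p,
            val = obj(Nw + kdeg[p], Lw + child_len[p]))
        }
      }
      if (length(cand) == 0L) break
      vals <- vapply(cand, `[[`, numeric(1), "val")
      if (max(vals) <= cur + 1e-12) break
      top <- which(vals >= max(vals) - 1e-12)
      pick <- cand[[if (length(top) > 1L) sample(top, 1L) else top]]
      if (pick$kind == "split") {
        R <- c(setdiff(R, pick$node), children[[pick$node]])
        Nw <- Nw - kdeg[pick$node]; Lw <- Lw - child_len[pick$node]
      } else {
        R <- c(setdiff(R, children[[pick$node]]), pick$node)
        Nw <- Nw + kdeg[pick$node]; Lw <- Lw + child_len[pick$node]
      }
      trace <- c(trace, obj(Nw, Lw))
    }
    list(R = R, Nw = Nw, Lw = Lw, trace = trace)
  }
  random_antichain <- function() {
    R <- integer(0)
    stack <- root
    while (length(stack)) {
      v <- stack[1L]; stack <- stack[-1L]
      if (v <= ntip || stats::runif(1) < 0.35) {
        R <- c(R, v)
      } else {
        stack <- c(children[[v]], stack)
      }
    }
    R
  }
  # subtree height below each node: cut starts place species roots at the
  # maximal subtrees not taller than a threshold
  height_below <- numeric(nnode)
  for (v in postorder_nodes(tree)) {
    if (v > ntip) {
      ch <- children[[v]]
      height_below[v] <- max(edge_len_to[ch] + height_below[ch])
    }
  }
  cut_antichain <- function(t) {
    R <- integer(0)
    stack <- root
    while (length(stack)) {
      v <- stack[1L]; stack <- stack[-1L]
      if (v <= ntip || height_below[v] <= t) R <- c(R, v)
      else stack <- c(children[[v]], stack)
    }
    R
  }
  logL_single <- obj(total_N, total_L)
  R <- root; Nw <- total_N; Lw <- total_L
  trace <- logL_single
  if (!degenerate) {
    cuts <- stats::quantile(height_below[height_below > 0],
                            probs = seq(0.05, 0.95, by = 0.06),
                            names = FALSE)
    starts <- c(list(root, seq_len(ntip)),
                lapply(unique(cuts), cut_antichain),
                replicate(n_restarts, random_antichain(), simplify = FALSE))
    best <- NULL
    for (s in starts) {
      res <- climb(s)
      if (is.null(best) || obj(res$Nw, res$Lw) > obj(best$Nw, best$Lw) + 1e-12) {
        best <- res
      }
    }
    R <- best$R; Nw <- best$Nw; Lw <- best$Lw; trace <- best$trace
  }
  # assign tips to species roots
  memb <- integer(ntip)
  assign_tips <- function(v, r) {
    if (v <= ntip) memb[v] <<- r
    else for (c in children[[v]]) assign_tips(c, r)
  }
  for (r in sort(R)) assign_tips(r, r)
  Nb <- total_N - Nw; Lb <- total_L - Lw
  structure(list(
    partition = otu_partition(tree$tip.label, memb, method = "ptp",
                              params = list(seed = seed)),
    n_entities = length(R),
    lambda_within = if (Nw > 0) Nw / max(Lw, 1e-300) else NA_real_,
    lambda_between = if (Nb > 0) Nb / max(Lb, 1e-300) else NA_real_,
    logL = obj(Nw, Lw), logL_single = trace[1L],
    trace = trace, degenerate = degenerate, n_tips = ntip, seed = seed
  ), class = "ptp_fit")
}

# Nodes in postorder (every child before its parent).
postorder_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  c(rev(tree$edge[preorder_edges(tree), 2L]), root)
}

#' @export
print.ptp_fit <- function(x, ...) {
  cat("PTP maximum-likelihood fit (", x$n_tips, " tips)\n", sep = "")
  cat("  entities: ", x$n_entities,
      if (x$degenerate) "  [degenerate: equal branch lengths]", "\n", sep = "")
  cat("  logL ", round(x$logL, 3), " (single-class ", round(x$logL_single, 3),
      "); rates within/between = ", signif(x$lambda_within, 4), " / ",
      signif(x$lambda_between, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a PTP fit
#' @param x a `ptp_fit`. @param ... ignored.
#' @return The partition as a tibble (`id`, `group`).
#' @exportS3Method generics::tidy
tidy.ptp_fit <- function(x, ...) tibble::as_tibble(x$partition)

#' One-row PTP fit summary
#' @param x a `ptp_fit`. @param ... ignored.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.ptp_fit <- function(x, ...) {
  tibble(n_tips = x$n_tips, n_entities = x$n_entities, logL = x$logL,
         logL_single = x$logL_single, lambda_within = x$lambda_within,
         lambda_between = x$lambda_between, degenerate = x$degenerate)
}
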