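#' ABGD configuration
#'
#' Parameters of the automatic barcode gap discovery procedure.  `prior_P`
#' is the maximal prior intraspecific divergence: the inferred gap must lie
#' above it, and it is the fallback clustering radius when no gap is
#' found.  `X` is the relative gap width: a spacing between consecutive
#' ranked distances counts as the gap when it exceeds `X` times the local
#' average spacing, estimated over a sliding window of
#' `max(10, n / 100)` ranked pairs.
#'
#' @param prior_P prior maximal intraspecific divergence, in (0, 1).
#' @param X relative gap width (> 0), default 1.5.
#' @param recursion re-apply gap inference within each group until stable.
#' @return An `abgd_config` list.
#' @export
abgd_config <- function(prior_P = 0.01, X = 1.5, recursion = TRUE) {
  stopifnot(prior_P > 0, prior_P < 1, X > 0)
  structure(list(prior_P = prior_P, X = X, recursion = recursion),
            class = "abgd_config")
}

#' Infer the barcode gap from ranked pairwise distances
#'
#' Scans the sorted distances above the `prior_P` floor for the first
#' spacing between consecutive ranks that exceeds `X` times the trailing
#' local average spacing.  A positive spacing where the local average is
#' zero (a block of ties followed by a jump) always qualifies.  Returns
#' the midpoint of the qualifying spacing, or `NA` when no spacing
#' qualifies (e.g. all distances equal, or a uniform grid with no dominant
#' spacing).
#'
#' @param distances numeric vector of pairwise distances (proportions);
#'   need not be sorted.
#' @param config an [abgd_config()].
#' @return The gap location (distance value) or `NA_real_`.
#' @export
infer_gap <- function(distances, config = abgd_config()) {
  ds <- sort(distances[is.finite(distances)])
  n <- length(ds)
  if (n < 2L) return(NA_real_)
  w <- max(10L, ceiling(n / 100))
  gaps <- diff(ds)
  for (i in seq_len(n - 1L)) {
    if (ds[i + 1L] <= config$prior_P) next
    lo <- max(1L, i - w)
    local <- if (lo <= i - 1L) mean(gaps[lo:(i - 1L)]) else 0
    if (gaps[i] > 0 && gaps[i] > config$X * local) {
      return((ds[i] + ds[i + 1L]) / 2)
    }
  }
  NA_real_
}

components_below <- function(D, ids, cutoff, strict = TRUE) {
  idx <- match(ids, D$ids)
  d <- D$d[idx, idx, drop = FALSE]
  lt <- which(lower.tri(d), arr.ind = TRUE)
  sel <- if (strict) !is.na(d[lt]) & d[lt] < cutoff else !is.na(d[lt]) & d[lt] <= cutoff
  memb <- union_find(length(ids), lt[sel, , drop = FALSE])
  split(ids, memb)
}

#' ABGD partition at one prior
#'
#' Initial partition: connected components of the graph with edges where
#' `d < gap` (the inferred gap location); when no gap is found the
#' fallback is components at `d <= prior_P`, so a prior sweep is total.
#' With `recursion` on, gap inference and splitting are re-applied to each
#' group's internal distances until no group splits further; the recursive
#' partition always refines the initial one.
#'
#' @param D a `barcode_dist` from [distance_matrix()].
#' @param config an [abgd_config()].
#' @return An `abgd_result`: list with `gap`, `initial`, `recursive`
#'   ([otu_partition()]s), `n_initial`, `n_recursive`.
#' @export
abgd_partition <- function(D, config = abgd_config()) {
  ids <- D$ids
  if (length(ids) == 1L) {
    p <- otu_partition(ids, 1L, method = "abgd",
                       params = list(prior_P = config$prior_P, X = config$X))
    return(structure(list(gap = NA_real_, initial = p, recursive = p,
                          n_initial = 1L, n_recursive = 1L),
                     class = "abgd_result"))
  }
  gap <- infer_gap(finite_lower(D), config)
  prov <- if (is.na(gap)) {
    sprintf("no gap above prior %g: fallback components at d <= prior", config$prior_P)
  } else {
    sprintf("gap at %.5f (prior %g)", gap, config$prior_P)
  }
  groups <- if (is.na(gap)) {
    components_below(D, ids, config$prior_P, strict = FALSE)
  } else {
    components_below(D, ids, gap, strict = TRUE)
  }
  initial <- groups_to_partition(groups, ids, config, prov)
  recursive <- initial
  if (config$recursion) {
    groups <- recursive_split(D, groups, config)
    recursive <- groups_to_partition(groups, ids, config,
                                     c(prov, "recursive splitting applied"))
  }
  structure(list(gap = gap, initial = initial, recursive = recursive,
                 n_initial = n_groups(initial), n_recursive = n_groups(recursive)),
            class = "abgd_result")
}

groups_to_partition <- function(groups, ids, config, prov) {
  memb <- integer(length(ids))
  names(memb) <- ids
  for (g in seq_along(groups)) memb[groups[[g]]] <- g
  otu_partition(ids, memb[ids], method = "abgd",
                params = list(prior_P = config$prior_P, X = config$X),
                provenance = prov)
}

recursive_split <- function(D, groups, config) {
  out <- list()
  queue <- groups
  while (length(queue)) {
    g <- queue[[1L]]
    queue <- queue[-1L]
    if (length(g) < 3L) {
      out <- c(out, list(g))
      next
    }
    idx <- match(g, D$ids)
    d <- D$d[idx, idx]
    gap <- infer_gap(d[lower.tri(d)], config)
    if (is.na(gap)) {
      out <- c(out, list(g))
      next
    }
    sub <- components_below(D, g, gap, strict = TRUE)
    if (length(sub) == 1L) {
      out <- c(out, list(g))
    } else {
      queue <- c(queue, sub)
    }
  }
  out
}

#' @export
print.abgd_result <- function(x, ...) {
  cat("abgd_result: gap ",
      if (is.na(x$gap)) "none (fallback at prior)" else signif(x$gap, 4),
      "; ", x$n_initial, " initial / ", x$n_recursive, " recursive groups\n",
      sep = "")
  invisible(x)
}

#' Sweep of ABGD over priors
#'
#' Runs [abgd_partition()] for every prior and tabulates the group counts
#' (the recursive count is the headline number; the initial count is
#' reported alongside).
#'
#' @param D a `barcode_dist`.
#' @param P_list ascending priors in (0, 1).
#' @param X relative gap width.
#' @param recursion as in [abgd_config()].
#' @return A tibble (`prior`, `gap`, `n_initial`, `n_recursive`).
#' @export
prior_sweep <- function(D, P_list, X = 1.5, recursion = TRUE) {
  stopifnot(!is.unsorted(P_list))
  purrr::map_dfr(P_list, function(P) {
    r <- abgd_partition(D, abgd_config(prior_P = P, X = X, recursion = recursion))
    tibble(prior = P, gap = r$gap, n_initial = r$n_initial,
           n_recursive = r$n_recursive)
  })
}
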