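#' Single-threshold GMYC species delimitation
#'
#' Fits the generalized mixed Yule-coalescent model on a rooted
#' ultrametric tree.  For every candidate threshold age `T` placed between
#' consecutive branching times, nodes older than `T` are diversification
#' (Yule) events among entity-level lineages and nodes younger than `T`
#' are coalescent events within entities.  Waiting intervals between
#' branching events contribute exponential densities with total rate
#' `lambda_yule * k(t)^p_yule + lambda_coal * sum_j n_j(t) * (n_j(t)-1)^p_coal`,
#' where `k(t)` counts entity-level lineages and `n_j(t)` the lineages of
#' entity `j`; each event contributes the rate of its own class evaluated
#' with the lineage configuration of the interval on its tip-ward side.
#' Rates are profiled out analytically; the scaling exponents are profiled
#' numerically (or pinned to 1 with `fixed_p = TRUE`).  The null model is
#' the same single-process likelihood with every node in one class, which
#' is the all-Yule threshold, so `LR >= 0` by construction.
#'
#' The threshold maximising the likelihood is returned together with a
#' likelihood-ratio test against the null (chi-squared reference,
#' `null_df` degrees of freedom for the two extra parameters plus the
#' threshold) and a confidence set of thresholds within 2 log-likelihood
#' units of the maximum.
#'
#' The waiting-interval likelihood needs strictly ordered branching
#' times, and two degeneracies of distance trees are handled explicitly.
#' Clades of (effectively) identical haplotypes — node heights at zero —
#' carry no information for the coalescent class but let its rate
#' estimate diverge, so they are collapsed onto one representative tip
#' before fitting and re-attached to that tip's entity afterwards; this
#' is the delimitation-scale analogue of running GMYC on unique
#' haplotypes.  Remaining tied node heights are spread deterministically
#' over a quarter of the gap down to the next distinct height (parents
#' staying older than children), which resolves the order without
#' creating the epsilon-length waiting intervals an additive jitter
#' would.
#'
#' @param tree a rooted ultrametric [ape::phylo] with at least 3 tips.
#' @param fixed_p pin both scaling exponents to 1 instead of profiling.
#' @param p_range interval over which exponents are profiled.
#' @param tol relative ultrametricity tolerance (fraction of tree height).
#' @param prune_zero collapse zero-height clades (identical haplotypes)
#'   onto a representative tip before fitting.
#' @param null_df degrees of freedom of the chi-squared reference for the
#'   likelihood-ratio test.
#' @param alpha significance level used for the reported `reject_null`.
#' @return A `gmyc_fit` object; see [tidy.gmyc_fit()] and
#'   [glance.gmyc_fit()].
#' @export
gmyc_single <- function(tree, fixed_p = FALSE, p_range = c(0, 5),
                        tol = 1e-6, prune_zero = TRUE, null_df = 3,
                        alpha = 0.05) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip_all <- length(tree$tip.label)
  if (ntip_all < 3L) stop("need at least 3 tips")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(ntip_all)])
  dev <- max(depths[seq_len(ntip_all)]) - min(depths[seq_len(ntip_all)])
  if (dev > tol * height) {
    stop("tree is not ultrametric: max tip-depth deviation ", signif(dev, 4),
         " exceeds tolerance ", signif(tol * height, 4))
  }
  dup_map <- NULL
  if (prune_zero) {
    pruned <- prune_zero_clades(tree, 1e-8 * height)
    tree <- pruned$tree
    dup_map <- pruned$map
  }
  ntip <- length(tree$tip.label)
  if (ntip < 3L) {
    stop("fewer than 3 distinct haplotypes after collapsing zero-height ",
         "clades; delimitation is trivial")
  }
  st <- gmyc_structure(tree, height)
  N <- st$N
  lik <- function(m) gmyc_loglik(st, m, fixed_p, p_range)
  fits <- lapply(0:N, lik)
  logLs <- vapply(fits, `[[`, numeric(1), "logL")
  best <- which.max(logLs)  # first maximum: oldest threshold on ties
  m_best <- best - 1L
  logL_null <- logLs[N + 1L]  # m = N is the single-process fit
  LR <- 2 * (logLs[best] - logL_null)
  p_value <- stats::pchisq(LR, df = null_df, lower.tail = FALSE)
  in_ci <- logLs >= logLs[best] - 2
  ents <- 0:N + 1L
  part <- gmyc_partition(st, m_best, tree)
  if (!is.null(dup_map) && nrow(dup_map)) {
    ext <- dplyr::left_join(dup_map, tibble::as_tibble(part),
                            by = c(rep = "id"))
    part <- otu_partition(c(part$id, ext$id), c(part$group, ext$group),
                          method = "gmyc",
                          params = list(m = m_best, n_entities = m_best + 1L))
  }
  fit <- fits[[best]]
  structure(list(
    threshold_age = if (m_best == 0L) Inf else st$ages[m_best],
    n_entities = m_best + 1L,
    ci_entities = range(ents[in_ci]),
    logL_gmyc = logLs[best], logL_null = logL_null,
    LR = LR, p_value = p_value, reject_null = p_value < alpha,
    # when the single-process null is not rejected the tree is consistent
    # with one species; the ML entity count is then not meaningful
    n_meaningful_entities = if (p_value < alpha) m_best + 1L else 1L,
    lambda_yule = fit$lambda1, p_yule = fit$p1,
    lambda_coal = fit$lambda2, p_coal = fit$p2,
    partition = part,
    profile = tibble(m = 0:N, threshold_age = c(Inf, st$ages)[1:(N + 1L)],
                     n_entities = ents, logL = logLs, in_ci = in_ci),
    n_tips = ntip_all, n_haplotypes = ntip, fixed_p = fixed_p,
    null_df = null_df
  ), class = "gmyc_fit")
}

# Collapse clades whose crown height is (numerically) zero onto their
# first tip; returns the pruned tree and a map tip id -> representative.
prune_zero_clades <- function(tree, tol0) {
  ntip <- length(tree$tip.label)
  ages <- ape::branching.times(tree)
  zero_nodes <- as.integer(names(ages)[ages <= tol0])
  if (length(zero_nodes) == 0L) {
    return(list(tree = tree, map = tibble(id = character(), rep = character())))
  }
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  is_zero <- logical(ntip + tree$Nnode)
  is_zero[zero_nodes] <- TRUE
  top_zero <- function(v) {
    # highest ancestor (or self) in a chain of zero-height nodes
    while (parent[v] != 0L && is_zero[parent[v]]) v <- parent[v]
    v
  }
  group <- vapply(seq_len(ntip), function(t) {
    if (parent[t] != 0L && is_zero[parent[t]]) top_zero(parent[t]) else t
  }, integer(1))
  rep_of_group <- tapply(seq_len(ntip), group, min)  # first tip represents
  rep_tip <- rep_of_group[as.character(group)]
  is_dropped <- seq_len(ntip) != rep_tip
  map <- tibble(id = tree$tip.label[is_dropped],
                rep = tree$tip.label[rep_tip[is_dropped]])
  list(tree = ape::drop.tip(tree, tree$tip.label[is_dropped]), map = map)
}

# Precompute the age-ordered event structure used by the likelihood.
# Ranks: 1 = oldest internal node (parents always before children; ties
# broken deterministically and ages perturbed to be strictly decreasing).
gmyc_structure <- function(tree, height) {
  ntip <- length(tree$tip.label)
  N <- tree$Nnode
  ages <- ape::branching.times(tree)  # named by node number, n+1 .. n+N
  nodes <- as.integer(names(ages))
  depth <- ape::node.depth(tree)  # larger = closer to root (clade size)
  ord <- order(-ages, -depth[nodes], nodes)
  nodes <- nodes[ord]
  a <- as.numeric(ages[ord])
  a <- spread_ties(a, height)
  rank_of <- integer(ntip + N)
  rank_of[nodes] <- seq_len(N)
  parent <- integer(ntip + N)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  pr_nodes <- parent[nodes]
  par_rank <- integer(N)  # 0 for the root
  par_rank[pr_nodes != 0L] <- rank_of[pr_nodes[pr_nodes != 0L]]
  if (any(par_rank >= seq_len(N))) {
    stop("inconsistent node ages: a parent is younger than its child")
  }
  len <- a - c(a[-1L], 0)  # segment i spans [a_i, a_{i+1}], a_{N+1} = 0
  list(N = N, ntip = ntip, ages = a, len = len, nodes = nodes,
       par_rank = as.integer(par_rank), rank_of = rank_of, parent = parent)
}

# Resolve tied ages (sorted descending, parents before children) by
# spreading each tie group over a quarter of the gap down to the next
# distinct age, keeping the sort order.  Avoids epsilon-length waiting
# intervals whose likelihood contribution would diverge.
spread_ties <- function(a, height) {
  N <- length(a)
  tol <- 1e-12 * height
  i <- 1L
  while (i <= N) {
    j <- i
    while (j < N && a[j + 1L] >= a[i] - tol) j <- j + 1L
    if (j > i) {
      nxt <- if (j < N) a[j + 1L] else 0
      gap <- a[i] - nxt
      if (gap <= tol) gap <- max(a[i], tol)  # all-tied tail near zero
      k <- j - i + 1L
      a[i:j] <- a[i] - (seq_len(k) - 1L) * gap / (4 * k)
    }
    i <- j + 1L
  }
  pmax(a, 1e-12 * max(height, 1))
}

# Profile log-likelihood of one class given per-segment rate factors
# B (length N), event factors B_ev (one per observed event of the class).
class_profile <- function(n_ev, S, sum_log_Bev) {
  if (n_ev == 0L) return(0)
  if (S <= 0) return(-Inf)
  n_ev * log(n_ev / S) + sum_log_Bev - n_ev
}

gmyc_loglik <- function(st, m, fixed_p, p_range) {
  N <- st$N
  len <- st$len
  k <- pmin(seq_len(N), m) + 1  # entity lineages per segment
  # Yule class: events are ranks 1..m, event rank i has factor k_i = i + 1
  yule_prof <- function(p) {
    class_profile(m, sum(len * k^p), if (m > 0) p * sum(log(seq_len(m) + 1)) else 0)
  }
  # Coalescent class: events are ranks m+1..N; per event, the size s of its
  # entity before the event; segment factor is the running sum of
  # (s+1) * s^p - s * (s-1)^p deltas.
  n_coal <- N - m
  if (n_coal > 0L) {
    s_ev <- numeric(n_coal)
    ent <- integer(N)  # entity id (a rank) per coal event rank
    cnt <- integer(N + 1L)
    for (j in (m + 1L):N) {
      pr <- st$par_rank[j]
      e <- if (pr <= m) j else ent[pr]
      ent[j] <- e
      if (cnt[e] == 0L) cnt[e] <- 1L
      s_ev[j - m] <- cnt[e]
      cnt[e] <- cnt[e] + 1L
    }
    seg_len <- len[(m + 1L):N]
    coal_prof <- function(p) {
      delta <- (s_ev + 1) * s_ev^p - ifelse(s_ev > 1, s_ev * (s_ev - 1)^p, 0)
      B2 <- cumsum(delta)
      class_profile(n_coal, sum(seg_len * B2), sum(log(B2)))
    }
  } else {
    coal_prof <- function(p) 0
  }
  if (fixed_p) {
    p1 <- 1; p2 <- 1
  } else {
    p1 <- if (m > 0L) stats::optimize(yule_prof, p_range, maximum = TRUE)$maximum else 1
    p2 <- if (n_coal > 0L) stats::optimize(coal_prof, p_range, maximum = TRUE)$maximum else 1
  }
  l1 <- yule_prof(p1); l2 <- coal_prof(p2)
  k_p <- sum(len * k^p1)
  lam1 <- if (m > 0L && k_p > 0) m / k_p else 0
  lam2 <- if (n_coal > 0L) {
    delta <- (s_ev + 1) * s_ev^p2 - ifelse(s_ev > 1, s_ev * (s_ev - 1)^p2, 0)
    S2 <- sum(len[(m + 1L):N] * cumsum(delta))
    if (S2 > 0) n_coal / S2 else 0
  } else 0
  list(logL = l1 + l2, lambda1 = lam1, p1 = p1, lambda2 = lam2, p2 = p2)
}

# Assign tips to entities for a given threshold index m.
gmyc_partition <- function(st, m, tree) {
  ntip <- st$ntip
  N <- st$N
  ent <- integer(N)
  if (m < N) {
    for (j in (m + 1L):N) {
      pr <- st$par_rank[j]
      ent[j] <- if (pr <= m) j else ent[pr]
    }
  }
  tip_ent <- integer(ntip)
  for (t in seq_len(ntip)) {
    pr <- st$rank_of[st$parent[t]]
    tip_ent[t] <- if (pr <= m) -t else ent[pr]
  }
  otu_partition(tree$tip.label, tip_ent, method = "gmyc",
                params = list(m = m, n_entities = m + 1L))
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("GMYC single-threshold fit (", x$n_tips, " tips)\n", sep = "")
  cat("  ML entities: ", x$n_entities, "  (2-logL CI ",
      x$ci_entities[1L], "-", x$ci_entities[2L], ")\n", sep = "")
  cat("  logL ", round(x$logL_gmyc, 3), " vs null ", round(x$logL_null, 3),
      "; LR = ", round(x$LR, 3), ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Per-threshold GMYC profile
#' @param x a `gmyc_fit`. @param ... ignored.
#' @return Tibble with one row per candidate threshold (`m`,
#'   `threshold_age`, `n_entities`, `logL`, `in_ci`).
#' @exportS3Method generics::tidy
tidy.gmyc_fit <- function(x, ...) x$profile

#' One-row GMYC fit summary
#' @param x a `gmyc_fit`. @param ... ignored.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.gmyc_fit <- function(x, ...) {
  tibble(n_tips = x$n_tips, n_entities = x$n_entities,
         n_meaningful_entities = x$n_meaningful_entities,
         ci_lo = x$ci_entities[1L], ci_hi = x$ci_entities[2L],
         logL = x$logL_gmyc, logL_null = x$logL_null, LR = x$LR,
         p_value = x$p_value,
         lambda_yule = x$lambda_yule, p_yule = x$p_yule,
         lambda_coal = x$lambda_coal, p_coal = x$p_coal)
}

#' Plot the GMYC threshold profile
#' @param object a `gmyc_fit`. @param ... ignored.
#' @return A ggplot of log-likelihood against entity count.
#' @exportS3Method ggplot2::autoplot
autoplot.gmyc_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$n_entities, y = .data$logL)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_ci), size = 1) +
    ggplot2::geom_vline(xintercept = object$n_entities, linetype = 2) +
    ggplot2::labs(x = "entities at threshold", y = "log-likelihood",
                  colour = "within 2 logL") +
    ggplot2::theme_minimal()
}
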