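#' Objective clustering at a fixed distance threshold
#'
#' Single-linkage grouping: OTUs are the connected components of the graph
#' with an edge wherever `d(i, j) <= t` (inclusive boundary), so every
#' member of a group lies within `t` of at least one other member, and
#' isolated sequences are singletons.  Undefined (zero-overlap) and
#' saturated (infinite) distances never create an edge; they behave as
#' "above any threshold".
#'
#' @param D a `barcode_dist` from [distance_matrix()].
#' @param t distance threshold as a proportion (e.g. `0.02` for 2%).
#' @param missing how to treat sequences with undefined pairs:
#'   `"as-singleton"` (default; they simply gain no edges through those
#'   pairs) or `"drop"` (sequences with any undefined pair are removed
#'   from the partition).
#' @return An [otu_partition()] with method `"objective"`.
#' @export
objective_cluster <- function(D, t, missing = c("as-singleton", "drop")) {
  missing <- match.arg(missing)
  stopifnot(t >= 0)
  d <- D$d
  keep <- seq_along(D$ids)
  prov <- character()
  has_undef <- anyNA(d)
  if (missing == "drop" && has_undef) {
    # greedily remove the sequences causing undefined pairs (most first)
    while (anyNA(d)) {
      worst <- which.max(rowSums(is.na(d)))
      keep <- keep[-worst]
      d <- d[-worst, -worst, drop = FALSE]
    }
    prov <- paste(length(D$ids) - length(keep),
                  "sequence(s) with undefined pairs dropped")
  } else if (has_undef) {
    prov <- "undefined pairs treated as above threshold"
  }
  n <- length(keep)
  lt <- which(lower.tri(d), arr.ind = TRUE)
  sel <- !is.na(d[lt]) & d[lt] <= t
  memb <- union_find(n, lt[sel, , drop = FALSE])
  otu_partition(D$ids[keep], memb, method = "objective",
                params = list(threshold = t, missing = missing),
                provenance = prov)
}

#' Group counts across a threshold sweep
#'
#' @param D a `barcode_dist`.
#' @param t_list ascending thresholds (proportions).
#' @param ... passed to [objective_cluster()].
#' @return A tibble (`threshold`, `n_groups`); `n_groups` is
#'   non-increasing in the threshold.
#' @export
threshold_sweep <- function(D, t_list, ...) {
  stopifnot(!is.unsorted(t_list))
  purrr::map_dfr(t_list, function(t) {
    tibble(threshold = t, n_groups = n_groups(objective_cluster(D, t, ...)))
  })
}

#' Histogram of pairwise distances
#'
#' Bins the defined, finite pairwise distances of the matrix.  The total
#' count is `n(n-1)/2` minus the undefined and saturated pairs, which are
#' reported in attributes `n_undefined` and `n_saturated`.  An empty band
#' between the within- and between-species modes is the classical
#' "barcode gap".
#'
#' @param D a `barcode_dist`.
#' @param bin_width bin width in distance units (proportion), > 0.
#' @return A tibble (`bin_start`, `bin_end`, `bin_mid`, `count`) of class
#'   `distance_histogram`.
#' @export
distance_histogram <- function(D, bin_width = 0.005) {
  stopifnot(bin_width > 0)
  v <- D$d[lower.tri(D$d)]
  n_undef <- sum(is.na(v))
  n_sat <- sum(is.infinite(v))
  v <- v[is.finite(v)]
  n_bins <- max(1L, ceiling(max(v, bin_width) / bin_width + 1e-9))
  breaks <- seq(0, n_bins * bin_width, by = bin_width)
  cnt <- tabulate(pmin(findInterval(v, breaks, left.open = TRUE) + 1L,
                       n_bins), nbins = n_bins)
  # findInterval with left.open: bins are (start, end]; zero distances fall
  # in the first bin via the +1 shift.
  out <- tibble(bin_start = breaks[-length(breaks)], bin_end = breaks[-1L],
                bin_mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                count = cnt)
  structure(out, n_undefined = n_undef, n_saturated = n_sat,
            class = c("distance_histogram", class(out)))
}

#' Plot a distance histogram
#' @param object a [distance_histogram()] result.
#' @param ... ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.distance_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 100 * .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = 100 * (object$bin_end[1L] - object$bin_start[1L]),
                      fill = "grey35") +
    ggplot2::labs(x = "pairwise distance (%)", y = "number of pairs") +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#' @param sweep result of [threshold_sweep()] or [prior_sweep()].
#' @return A ggplot of OTU count against threshold/prior (percent).
#' @export
plot_sweep <- function(sweep) {
  xcol <- if ("threshold" %in% names(sweep)) "threshold" else "prior"
  ycol <- if ("n_groups" %in% names(sweep)) "n_groups" else "n_recursive"
  ggplot2::ggplot(sweep, ggplot2::aes(x = 100 * .data[[xcol]], y = .data[[ycol]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = paste0(xcol, " (%)"), y = "number of OTUs") +
    ggplot2::theme_minimal()
}
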