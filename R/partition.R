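#' OTU partition objects
#'
#' A partition assigns every sequence id to exactly one OTU.  It is stored
#' as a tibble (`id`, `group`) with the delimitation method and its
#' parameters attached, so results from objective clustering, ABGD, GMYC,
#' PTP or manual cuts share one shape.
#'
#' @param id character vector of sequence ids (no duplicates).
#' @param group group membership, coerced to integer codes in order of
#'   first appearance.
#' @param method one of `"objective"`, `"abgd"`, `"gmyc"`, `"ptp"`,
#'   `"manual"`.
#' @param params named list of method parameters.
#' @param provenance free-text log lines.
#' @return An `otu_partition`: a tibble with attributes `method`, `params`,
#'   `provenance`.
#' @export
otu_partition <- function(id, group, method = "manual", params = list(),
                          provenance = character()) {
  stopifnot(length(id) == length(group), !anyDuplicated(id))
  grp <- match(group, unique(group))
  out <- tibble(id = as.character(id), group = grp)
  structure(out, method = method, params = params, provenance = provenance,
            class = c("otu_partition", class(out)))
}

#' Number of groups in a partition
#' @param partition an [otu_partition()].
#' @return Integer.
#' @export
n_groups <- function(partition) length(unique(partition$group))

#' @export
print.otu_partition <- function(x, ...) {
  cat("otu_partition (", attr(x, "method"), "): ", nrow(x), " ids in ",
      n_groups(x), " groups\n", sep = "")
  NextMethod()
}

# groups as list of id vectors
partition_groups <- function(partition) {
  split(partition$id, partition$group)
}

#' Write a partition as TSV
#' @param partition an [otu_partition()]. @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(id = partition$id, group = partition$group,
                   method = attr(partition, "method"),
                   params = paste(names(attr(partition, "params")),
                                  unlist(attr(partition, "params")),
                                  sep = "=", collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition from TSV
#' @param path TSV with columns `id` and `group`.
#' @return An [otu_partition()] with method `"manual"`.
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  otu_partition(df$id, df$group, method = "manual",
                provenance = paste("read from", path))
}

# Union-find over n elements; edges is a 2-column integer matrix.
union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1L]); rj <- find(edges[k, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
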