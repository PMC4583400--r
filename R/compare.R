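#' Propagate species names through a molecular partition
#'
#' Re-labels genus-level records by the OTU they fall in: when a group
#' contains exactly one named morphospecies, every genus-only member takes
#' that name; when it contains none, all members receive one fresh group
#' code (`cluster_001`, ...); when it contains two or more named species
#' the group is flagged as a conflict and its genus-only members stay
#' unnamed.  Records whose `id_level` is `species` are never renamed.
#'
#' @param partition an [otu_partition()] over the alignment's ids.
#' @param aln the [barcode_alignment()] carrying `species`/`id_level`.
#' @return A list with `labels` (tibble `id`, `species`, `id_level` after
#'   propagation) and `conflicts` (tibble `group`, `species` listing
#'   groups with >= 2 named species).
#' @export
propagate_names <- function(partition, aln) {
  if (!setequal(partition$id, aln$info$id)) {
    stop("partition ids do not match alignment ids")
  }
  info <- aln$info[match(partition$id, aln$info$id), ]
  labels <- tibble(id = info$id, species = info$species,
                   id_level = info$id_level, group = partition$group)
  conflicts <- list()
  code_counter <- 0L
  for (g in sort(unique(labels$group))) {
    sel <- labels$group == g
    named <- unique(labels$species[sel & labels$id_level == "species"])
    named <- named[!is.na(named)]
    codes <- unique(labels$species[sel & labels$id_level == "group_code"])
    codes <- codes[!is.na(codes)]
    open <- sel & labels$id_level == "genus_only"
    if (length(named) == 1L) {
      labels$species[open] <- named
      labels$id_level[open] <- "species"
    } else if (length(named) == 0L) {
      # no morphospecies name available: the whole group gets one
      # distinguishable code (an existing group code if it is unique,
      # otherwise a fresh cluster code)
      code <- if (length(codes) == 1L) codes else {
        code_counter <- code_counter + 1L
        sprintf("cluster_%03d", code_counter)
      }
      labels$species[open] <- code
      labels$id_level[open] <- "group_code"
    } else {
      conflicts[[length(conflicts) + 1L]] <-
        tibble(group = g, species = list(named))
    }
  }
  list(labels = labels[, c("id", "species", "id_level")],
       conflicts = if (length(conflicts)) dplyr::bind_rows(conflicts)
       else tibble(group = integer(), species = list()))
}

#' Species discrimination rate of a partition
#'
#' A named species is "discriminated" when no OTU containing any of its
#' sequences also contains sequences of a different named species.  A
#' species split over several pure OTUs still counts as discriminated; two
#' species sharing an OTU are both undiscriminated.  The rate is reported
#' for named species only and, as the alternative denominator, for named
#' plus group-code morphospecies.
#'
#' @param partition an [otu_partition()].
#' @param labels tibble with columns `id`, `species`, `id_level` (e.g.
#'   from [propagate_names()], or `aln$info`).
#' @return A list with `rate`, `n_discriminated`, `n_species`,
#'   `rate_incl_codes`, `n_species_incl_codes` and `verdicts` (tibble
#'   `species`, `id_level`, `discriminated`).
#' @export
discrimination_rate <- function(partition, labels) {
  df <- dplyr::inner_join(tibble::as_tibble(partition), labels, by = "id")
  df <- df[!is.na(df$species) & df$id_level %in% c("species", "group_code"), ]
  if (nrow(df) == 0L) stop("no named species in labels")
  # species sharing a group with a different species are undiscriminated
  impure <- df |>
    dplyr::distinct(.data$group, .data$species) |>
    dplyr::add_count(.data$group, name = "n_sp") |>
    dplyr::filter(.data$n_sp > 1L)
  verdicts <- df |>
    dplyr::distinct(.data$species, .data$id_level) |>
    dplyr::mutate(discriminated = !.data$species %in% impure$species)
  named <- verdicts$id_level == "species"
  list(
    rate = mean(verdicts$discriminated[named]),
    n_discriminated = sum(verdicts$discriminated[named]),
    n_species = sum(named),
    rate_incl_codes = mean(verdicts$discriminated),
    n_species_incl_codes = nrow(verdicts),
    verdicts = verdicts
  )
}

#' Intra- and interspecific divergence summaries
#'
#' Mirrors the usual within-/between-groups divergence tables: per species
#' with n >= 2, the number of sequences and mean/max within-species
#' distance; per species pair, the mean/min/max between-species distance;
#' and global figures — the unweighted mean over species of within-species
#' means (with the pooled, pair-weighted mean alongside), the mean
#' interspecific distance averaged over sequence pairs and over
#' species-pair means, and the attained extremes with the taxa attaining
#' them.  Undefined pairs are ignored.
#'
#' @param D a `barcode_dist`.
#' @param labels tibble with `id`, `species` (NA species are excluded).
#' @return A `divergence_summary` list with tibbles `within`, `between`,
#'   `singletons`, and a one-row tibble `global`.
#' @export
divergence_summary <- function(D, labels) {
  labels <- labels[!is.na(labels$species) & labels$id %in% D$ids, ]
  sp <- split(labels$id, labels$species)
  sizes <- lengths(sp)
  if (!any(sizes >= 2L)) stop("need at least one species with >= 2 sequences")
  idx <- lapply(sp, match, table = D$ids)

  within <- purrr::map_dfr(names(sp)[sizes >= 2L], function(s) {
    d <- D$d[idx[[s]], idx[[s]]]
    v <- d[lower.tri(d)]
    v <- v[is.finite(v)]
    tibble(species = s, n_sequences = sizes[[s]],
           mean_within = mean(v), max_within = max(v))
  })
  singletons <- tibble(species = names(sp)[sizes == 1L])

  nm <- names(sp)
  if (length(nm) >= 2L) {
    pairs <- utils::combn(seq_along(nm), 2L)
    between <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      v <- D$d[idx[[i]], idx[[j]]]
      v <- v[is.finite(v)]
      if (length(v) == 0L) return(tibble())
      tibble(species_a = nm[i], species_b = nm[j],
             mean_between = mean(v), min_between = min(v), max_between = max(v))
    })
    all_between <- unlist(purrr::map(seq_len(ncol(pairs)), function(k) {
      v <- D$d[idx[[pairs[1L, k]]], idx[[pairs[2L, k]]]]
      v[is.finite(v)]
    }))
  } else {
    between <- tibble(species_a = character(), species_b = character(),
                      mean_between = numeric(), min_between = numeric(),
                      max_between = numeric())
    all_between <- numeric()
  }
  no_between <- nrow(between) == 0L
  i_max_w <- which.max(within$max_within)
  i_max_b <- if (no_between) NA_integer_ else which.max(between$max_between)
  i_min_b <- if (no_between) NA_integer_ else which.min(between$min_between)
  pair_or_na <- function(i) {
    if (is.na(i)) NA_character_ else
      paste(between$species_a[i], between$species_b[i], sep = " - ")
  }
  val_or_na <- function(x, i) if (is.na(i)) NA_real_ else x[i]
  global <- tibble(
    mean_intraspecific = mean(within$mean_within),
    mean_intraspecific_weighted = {
      wv <- unlist(purrr::map(names(sp)[sizes >= 2L], function(s) {
        d <- D$d[idx[[s]], idx[[s]]]; v <- d[lower.tri(d)]; v[is.finite(v)]
      }))
      mean(wv)
    },
    max_intraspecific = within$max_within[i_max_w],
    max_intraspecific_species = within$species[i_max_w],
    mean_interspecific_pairs = if (length(all_between)) mean(all_between)
      else NA_real_,
    mean_interspecific_species_pairs = if (no_between) NA_real_
      else mean(between$mean_between),
    max_interspecific = val_or_na(between$max_between, i_max_b),
    max_interspecific_pair = pair_or_na(i_max_b),
    min_interspecific = val_or_na(between$min_between, i_min_b),
    min_interspecific_pair = pair_or_na(i_min_b)
  )
  structure(list(within = within, between = between, singletons = singletons,
                 global = global), class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  g <- x$global
  cat("divergence_summary: ", nrow(x$within), " species with n >= 2, ",
      nrow(x$singletons), " singletons\n", sep = "")
  cat(sprintf("  mean intra %.2f%% | max intra %.2f%% (%s)\n",
              100 * g$mean_intraspecific, 100 * g$max_intraspecific,
              g$max_intraspecific_species))
  cat(sprintf("  mean inter %.2f%% | max inter %.2f%% (%s) | min inter %.2f%% (%s)\n",
              100 * g$mean_interspecific_pairs, 100 * g$max_interspecific,
              g$max_interspecific_pair, 100 * g$min_interspecific,
              g$min_interspecific_pair))
  invisible(x)
}
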