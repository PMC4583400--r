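#' Site variability by codon position
#'
#' Classifies every alignment column as variable (at least two distinct
#' unambiguous bases occur) and parsimony-informative (at least two
#' distinct unambiguous bases each occur in two or more sequences), and
#' tabulates the counts per codon-position class (1st, 2nd, 3rd, All).
#' Gaps, `N` and ambiguity codes never count as states; a column with no
#' unambiguous base at all is "not considered".
#'
#' Two percentage conventions circulate for informative sites (fraction of
#' the class's columns vs fraction of its variable columns), so both are
#' reported alongside the raw counts.
#'
#' @param aln a [barcode_alignment()] with `frame` set (see
#'   [detect_frame()]).
#' @return A tibble with one row per position class and columns
#'   `position`, `n_sites`, `n_considered`, `n_variable`, `n_informative`,
#'   `variable_pct`, `informative_pct_of_sites`,
#'   `informative_pct_of_variable`.
#' @examples
#' aln <- alignment_from_strings(c(a = "AAA", b = "AAA", c = "GAA", d = "GCA"),
#'                               frame = 1)
#' site_classification(aln)
#' @export
site_classification <- function(aln) {
  if (n_records(aln) == 0L) stop("empty alignment")
  if (is.na(aln$frame)) stop("frame not set; run detect_frame() first")
  counts <- base_count_matrix(aln)  # 4 x L
  n_states <- colSums(counts > 0L)
  n_deep <- colSums(counts >= 2L)
  variable <- n_states >= 2L
  informative <- n_deep >= 2L
  considered <- colSums(counts) > 0L
  pos <- codon_positions(n_columns(aln), aln$frame)
  cls <- list(`1st` = pos == 1L, `2nd` = pos == 2L, `3rd` = pos == 3L,
              All = rep(TRUE, length(pos)))
  purrr::map_dfr(names(cls), function(nm) {
    sel <- cls[[nm]]
    nv <- sum(variable[sel]); ni <- sum(informative[sel]); ns <- sum(sel)
    tibble(
      position = nm,
      n_sites = ns,
      n_considered = sum(considered[sel]),
      n_variable = nv,
      n_informative = ni,
      variable_pct = 100 * nv / ns,
      informative_pct_of_sites = 100 * ni / ns,
      informative_pct_of_variable = if (nv > 0) 100 * ni / nv else NA_real_
    )
  })
}

# 4 x L matrix of per-column counts of A, C, G, T.
base_count_matrix <- function(aln) {
  vapply(UNAMBIGUOUS, function(b) colSums(aln$seq == b),
         numeric(ncol(aln$seq))) |> t()
}

#' Average base composition by codon position
#'
#' Mean per-sequence base percentages over unambiguous bases, per
#' codon-position class and overall.  A sequence with no unambiguous base
#' in a class is excluded from that class's mean with a warning.
#'
#' @inheritParams site_classification
#' @return A tibble with columns `position`, `pct_T`, `pct_C`, `pct_A`,
#'   `pct_G`, `pct_AT`, `pct_GC` and `n_sequences` (sequences entering the
#'   class mean).
#' @export
base_composition <- function(aln) {
  if (n_records(aln) == 0L) stop("empty alignment")
  if (is.na(aln$frame)) stop("frame not set; run detect_frame() first")
  pos <- codon_positions(n_columns(aln), aln$frame)
  cls <- list(`1st` = pos == 1L, `2nd` = pos == 2L, `3rd` = pos == 3L,
              All = rep(TRUE, length(pos)))
  purrr::map_dfr(names(cls), function(nm) {
    sub <- aln$seq[, cls[[nm]], drop = FALSE]
    per_base <- vapply(UNAMBIGUOUS, function(b) rowSums(sub == b),
                       numeric(nrow(sub)))  # n x 4
    tot <- rowSums(per_base)
    keep <- tot > 0
    if (any(!keep)) {
      warning(sum(!keep), " sequence(s) with no unambiguous base in class ",
              nm, " excluded from composition")
    }
    pct <- 100 * per_base[keep, , drop = FALSE] / tot[keep]
    mp <- colMeans(pct)
    tibble(
      position = nm,
      pct_T = mp[["T"]], pct_C = mp[["C"]], pct_A = mp[["A"]], pct_G = mp[["G"]],
      pct_AT = mp[["A"]] + mp[["T"]], pct_GC = mp[["G"]] + mp[["C"]],
      n_sequences = sum(keep)
    )
  })
}

#' Combined per-position site statistics table
#'
#' Joins [site_classification()] and [base_composition()] into a single
#' table with one row per codon-position class, mirroring the usual layout
#' of barcode-survey site-statistics tables.
#'
#' @inheritParams site_classification
#' @return A tibble.
#' @export
site_stats <- function(aln) {
  dplyr::left_join(site_classification(aln), base_composition(aln),
                   by = "position")
}
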