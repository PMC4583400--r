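#' Run the full barcode delimitation pipeline
#'
#' Wires the stages together in the standard order: site statistics ->
#' distance matrix -> haplotype collapse -> trees -> objective-clustering
#' threshold sweep -> ABGD prior sweep -> GMYC (on a UPGMA tree of the
#' haplotype-reduced data) -> PTP (on an NJ tree of the reduced data,
#' rooted) -> comparison against morphospecies labels.  The result
#' carries a method-by-OTU-count summary table.  A stage failure aborts
#' with the stage name; results of completed stages are returned in the
#' condition's `partial` field.
#'
#' @param aln a [barcode_alignment()] (or a FASTA path).
#' @param model distance model.
#' @param thresholds objective-clustering thresholds (proportions).
#' @param priors ABGD priors (proportions).
#' @param bootstrap bootstrap replicates for the NJ tree (0 = skip).
#' @param run_gmyc,run_ptp toggle the tree-based delimiters.
#' @param compare_threshold objective-clustering threshold used for the
#'   morphospecies comparison (default 4%, inside the 4-5% band the
#'   threshold sweep of genus-scale COI surveys recommends).
#' @param seed integer seed for every stochastic stage.
#' @return A `pipeline_result` list with per-stage outputs and a
#'   `summary` tibble (`method`, `params`, `n_otus`).
#' @export
run_pipeline <- function(aln, model = "K2P",
                         thresholds = seq(0.02, 0.07, by = 0.01),
                         priors = c(0.005, 0.01, 0.02, 0.03, 0.04, 0.05, 0.07, 0.1),
                         bootstrap = 0L, run_gmyc = TRUE, run_ptp = TRUE,
                         compare_threshold = 0.04, seed = 1L) {
  if (is.character(aln)) aln <- read_fasta(aln)
  if (n_records(aln) < 3L) stop("stage input: need at least 3 sequences")
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.na(aln$frame)) aln <- stage("frame", detect_frame(aln))
  out$stats <- stage("stats", site_stats(aln))
  D <- stage("distances", distance_matrix(aln, model))
  out$distances <- D
  out$histogram <- stage("histogram", distance_histogram(D))
  coll <- stage("collapse", collapse_haplotypes(aln))
  out$haplotypes <- coll
  red <- coll$alignment
  Dred <- stage("distances_reduced", distance_matrix(red, model))
  out$sweep <- stage("objective_sweep", threshold_sweep(D, thresholds))
  out$abgd <- stage("abgd_sweep", prior_sweep(D, priors))
  if (bootstrap > 0L) {
    out$nj <- stage("nj_bootstrap",
                    bootstrap_support(aln, model, "nj", bootstrap, seed))
  } else {
    out$nj <- stage("nj", nj_tree(D))
  }
  if (run_gmyc) {
    out$gmyc <- stage("gmyc", gmyc_single(upgma_tree(Dred)))
  }
  if (run_ptp) {
    out$ptp <- stage("ptp", {
      tr <- upgma_tree(Dred)  # rooted input with substitution lengths
      ptp_fit(tr, seed = seed)
    })
  }
  out$compare_partition <- stage("compare",
                                 objective_cluster(D, compare_threshold))
  prop <- stage("propagate", propagate_names(out$compare_partition, aln))
  out$propagated <- prop
  has_named <- any(prop$labels$id_level %in% c("species", "group_code") &
                     !is.na(prop$labels$species))
  if (has_named) {
    out$discrimination <- stage("discrimination",
                                discrimination_rate(out$compare_partition,
                                                    prop$labels))
    out$divergence <- stage("divergence", divergence_summary(D, prop$labels))
  }

  rows <- list(
    tibble(method = "objective", params = sprintf("t=%g%%", 100 * thresholds),
           n_otus = out$sweep$n_groups),
    tibble(method = "abgd", params = sprintf("P=%g%%", 100 * priors),
           n_otus = out$abgd$n_recursive)
  )
  if (run_gmyc) {
    rows <- c(rows, list(tibble(method = "gmyc", params = "single-threshold",
                                n_otus = out$gmyc$n_entities)))
  }
  if (run_ptp) {
    rows <- c(rows, list(tibble(method = "ptp", params = "ML",
                                n_otus = out$ptp$n_entities)))
  }
  out$summary <- dplyr::bind_rows(rows)
  out$seed <- seed
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with stages:", paste(names(x), collapse = ", "), "\n")
  cat("OTU counts by method:\n")
  print(x$summary, n = Inf)
  invisible(x)
}
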