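#' End-to-end cohort analysis
#'
#' Runs the full pipeline over a cohort of fragment sets: per-sample
#' fragment-size profiles, cohort-consensus extrema and per-sample amplitude
#' statistics, per-sample binned copy-number analysis (correction,
#' CBS + HMM segmentation, consensus log2R, gene calls, mean SCNA), the
#' cohort table, and the amplitude-vs-SCNA Pearson association.
#'
#' @param samples named list of fragment data frames (e.g.
#'   `simulate_cohort()$samples`).
#' @param genome a [synthetic_genome()] (or compatible list with annotated
#'   `bins`, `blacklist`).
#' @param genes gene/region BED-like table; defaults to [glioma_genes()].
#' @param size_range histogram range in bp.
#' @param min_support cluster support for extrema averaging.
#' @param alpha,n_perm CBS parameters.
#' @param amp_thresh,del_thresh gene-call thresholds.
#' @param seed seed for the (seeded) segmentation permutation tests;
#'   per-sample streams are derived from it.
#' @return List of class `cohort_analysis`: `table` (`cohort_table` with an
#'   extra `fraction_below_150` column), `association` (see
#'   [associate_cohort()]), `profiles`, `scna` (per-sample `scna_result`s),
#'   and `averaged_extrema`.
#' @export
analyze_cohort <- function(samples, genome, genes = glioma_genes(genome),
                           size_range = c(50, 700), min_support = 0.5,
                           alpha = 0.01, n_perm = 1000,
                           amp_thresh = 0.15, del_thresh = -0.15,
                           seed = 1L) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples)))
    names(samples) <- sprintf("S%02d", seq_along(samples))
  ids <- names(samples)
  profiles <- lapply(samples, size_histogram, range = size_range)
  amp <- cohort_amplitude(profiles, min_support = min_support)
  scna <- vector("list", length(samples))
  names(scna) <- ids
  for (i in seq_along(samples)) {
    scna[[i]] <- scna_analysis(samples[[i]], genome, genes = genes,
                               alpha = alpha, n_perm = n_perm,
                               amp_thresh = amp_thresh,
                               del_thresh = del_thresh,
                               seed = derive_seed(seed, i))
  }
  ms <- data.frame(sample_id = ids,
                   mean_scna = vapply(scna, `[[`, numeric(1), "mean_scna"))
  calls <- lapply(scna, `[[`, "gene_calls")
  table <- build_cohort_table(amp[, c("sample_id", "amplitude")], ms, calls)
  table$fraction_below_150 <- vapply(profiles, fraction_below, numeric(1),
                                     threshold = 150)
  association <- associate_cohort(table)
  structure(list(table = table, association = association,
                 profiles = profiles, scna = scna,
                 averaged_extrema = attr(amp, "averaged_extrema")),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("cohort_analysis: %d samples, %d SCNA-positive\n",
              nrow(x$table), sum(x$table$scna_detected)))
  if (!is.null(x$association$correlation)) {
    print(x$association$correlation)
  } else {
    cat("  amplitude-SCNA correlation unavailable:",
        x$association$error, "\n")
  }
  invisible(x)
}
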