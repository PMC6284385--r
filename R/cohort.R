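#' Pearson correlation with t-based p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Constant input is an error (the correlation is undefined), never silently
#' reported as zero.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return Object of class `correlation_result`: list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (P = %.3g, n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Assemble the per-sample cohort table
#'
#' Joins the amplitude statistic, the mean-SCNA statistic, and the gene-call
#' derived detection flag into one row per sample. `scna_detected` is true
#' iff the sample has at least one non-neutral gene/region call (ignoring
#' `no-data` regions), matching how samples are grouped for fragmentation
#' comparisons.
#'
#' @param amplitudes data frame with `sample_id`, `amplitude` (from
#'   [cohort_amplitude()]).
#' @param mean_scnas data frame with `sample_id`, `mean_scna`.
#' @param gene_calls named list (by sample_id) of gene-call data frames from
#'   [call_genes()].
#' @param metadata optional data frame with `sample_id` plus free-form
#'   descriptive columns (subtype, tumor size class, ...); carried through
#'   untouched.
#' @return Data frame of class `cohort_table`.
#' @export
build_cohort_table <- function(amplitudes, mean_scnas, gene_calls,
                               metadata = NULL) {
  stopifnot(all(c("sample_id", "amplitude") %in% names(amplitudes)),
            all(c("sample_id", "mean_scna") %in% names(mean_scnas)))
  ids <- amplitudes$sample_id
  check_ids <- function(other, what) {
    miss <- union(setdiff(ids, other), setdiff(other, ids))
    if (length(miss))
      stop("sample_id mismatch in ", what, ": ", paste(miss, collapse = ", "))
  }
  check_ids(mean_scnas$sample_id, "mean_scnas")
  check_ids(names(gene_calls), "gene_calls")
  detected <- vapply(gene_calls[ids], function(g)
    any(g$state %in% c("amplification", "deletion")), logical(1))
  out <- data.frame(sample_id = ids,
                    amplitude = amplitudes$amplitude,
                    mean_scna = mean_scnas$mean_scna[
                      match(ids, mean_scnas$sample_id)],
                    scna_detected = unname(detected))
  if (!is.null(metadata)) {
    check_ids(metadata$sample_id, "metadata")
    out <- merge(out, metadata, by = "sample_id", sort = FALSE)
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Cohort-level association of fragmentation and SCNA level
#'
#' The headline cohort analysis: Pearson correlation between the 10 bp
#' periodicity amplitude and the mean-SCNA statistic, plus per-group
#' (SCNA-detected vs not) summaries of the mean amplitude and, when present
#' in the table, the mean sub-150 bp fraction. A degenerate cohort (constant
#' amplitude or mean SCNA, e.g. all tumor-free samples) is reported
#' gracefully: the correlation slot is `NULL` and `error` carries the
#' message.
#'
#' @param table a `cohort_table` from [build_cohort_table()].
#' @return List with `correlation` (a `correlation_result` or `NULL`),
#'   `groups` (per-group summary data frame), and `error` (`NULL` or
#'   character).
#' @export
associate_cohort <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table) < 3) stop("need at least 3 samples")
  corr <- tryCatch(pearson_cor(table$amplitude, table$mean_scna),
                   error = function(e) e)
  err <- NULL
  if (inherits(corr, "error")) {
    err <- conditionMessage(corr)
    corr <- NULL
  }
  grp <- factor(ifelse(table$scna_detected, "SCNA+", "SCNA-"),
                levels = c("SCNA-", "SCNA+"))
  groups <- data.frame(
    group = levels(grp),
    n = as.integer(table(grp)),
    mean_amplitude = as.numeric(tapply(table$amplitude, grp, mean)),
    mean_scna = as.numeric(tapply(table$mean_scna, grp, mean)))
  if ("fraction_below_150" %in% names(table))
    groups$mean_fraction_below_150 <-
      as.numeric(tapply(table$fraction_below_150, grp, mean))
  list(correlation = corr, groups = groups, error = err)
}
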