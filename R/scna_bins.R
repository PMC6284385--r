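#' Tile a genome into equal-width bins
#'
#' Non-overlapping fixed-width bins per chromosome, 0-based half-open; the
#' last bin of each chromosome is truncated at the chromosome end.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (>= 1000).
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
make_bins <- function(chrom_lengths, bin_size = 30000) {
  if (!length(chrom_lengths)) stop("empty genome")
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  if (bin_size < 1000) stop("bin_size must be >= 1000")
  pieces <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, L))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Count fragments per genomic bin
#'
#' Each fragment is assigned to exactly one bin by its start coordinate
#' (half-open convention: a start equal to a bin boundary falls in the
#' right-hand bin). Fragments on chromosomes absent from the bin table, or
#' starting beyond the last bin, are counted as unassigned and reported via
#' the `"unassigned"` attribute.
#'
#' @param records fragment data frame (`chrom`, `start`).
#' @param bins bin table from [make_bins()] (optionally annotated).
#' @return Integer vector of raw counts, one per bin, with attribute
#'   `"unassigned"`.
#' @export
count_in_bins <- function(records, bins) {
  counts <- integer(nrow(bins))
  unassigned <- 0L
  for (ch in unique(bins$chrom)) {
    b <- which(bins$chrom == ch)
    r <- records$start[records$chrom == ch]
    if (!length(r)) next
    idx <- findInterval(r, bins$start[b])
    beyond <- r >= bins$end[b][length(b)]
    unassigned <- unassigned + sum(beyond)
    idx <- idx[!beyond]
    counts[b] <- counts[b] + tabulate(idx, nbins = length(b))
  }
  unassigned <- unassigned + sum(!(records$chrom %in% bins$chrom))
  attr(counts, "unassigned") <- unassigned
  counts
}

# TRUE for bins overlapping any blacklist interval (same chrom, any bp)
flag_blacklisted <- function(bins, blacklist) {
  if (is.null(blacklist) || !nrow(blacklist)) return(rep(FALSE, nrow(bins)))
  out <- rep(FALSE, nrow(bins))
  for (i in seq_len(nrow(blacklist))) {
    out <- out | (bins$chrom == blacklist$chrom[i] &
                    bins$start < blacklist$end[i] &
                    bins$end > blacklist$start[i])
  }
  out
}

#' GC and mappability correction of bin counts
#'
#' Corrects raw bin counts for GC and mappability bias with stratified
#' median-ratio factors: bins are grouped into GC strata of width 0.01 and
#' mappability strata of width 0.05; each stratum's factor is the ratio of
#' its median count to the overall median, normalized so the per-bin factors
#' have median 1. Corrected counts are `raw / f(gc) / g(map)`. Strata with
#' fewer than 5 usable bins fall back to the pooled median (factor 1) with a
#' warning. Blacklisted bins are set to `NA` (unusable).
#'
#' @param raw integer vector of raw counts per bin.
#' @param gc,mappability per-bin annotation in `[0, 1]`.
#' @param blacklisted logical per-bin exclusion flag (optional).
#' @return Numeric vector of corrected counts (`NA` for blacklisted bins)
#'   with attribute `"factors"` (data frame of per-bin `f_gc`, `f_map`).
#' @export
correct_counts <- function(raw, gc, mappability, blacklisted = NULL) {
  n <- length(raw)
  stopifnot(length(gc) == n, length(mappability) == n)
  if (is.null(blacklisted)) blacklisted <- rep(FALSE, n)
  usable <- !blacklisted
  if (sum(usable) < 100)
    stop("too few usable bins for stratified correction (need >= 100)")
  med_all <- median(raw[usable])
  if (med_all <= 0) stop("median raw count is zero; nothing to correct")
  stratum_factor <- function(strata) {
    f <- rep(1, n)
    small <- 0L
    for (s in unique(strata[usable])) {
      idx <- usable & strata == s
      if (sum(idx) >= 5) f[idx] <- median(raw[idx]) / med_all
      else small <- small + 1L
    }
    if (small > 0)
      warning(small, " strata with < 5 bins fell back to the pooled median")
    f / median(f[usable])
  }
  f_gc <- stratum_factor(pmin(floor(gc / 0.01), 99))
  f_map <- stratum_factor(pmin(floor(mappability / 0.05), 19))
  corrected <- raw / f_gc / f_map
  corrected[!usable] <- NA_real_
  attr(corrected, "factors") <- data.frame(f_gc = f_gc, f_map = f_map)
  corrected
}

#' Median-normalized log2 copy-number ratios
#'
#' `log2r = log2(corrected) - median(log2(corrected))` over usable bins, so
#' the median log2 ratio is exactly zero. Zero-count and excluded bins are
#' flagged unusable (`NA`) rather than mapped to `-Inf`.
#'
#' @param corrected numeric vector of corrected counts (`NA` = excluded).
#' @return Numeric vector of log2 ratios (`NA` for unusable bins).
#' @export
to_log2r <- function(corrected) {
  usable <- !is.na(corrected) & corrected > 0
  if (!any(usable)) stop("all bins have zero corrected counts")
  l <- rep(NA_real_, length(corrected))
  l[usable] <- log2(corrected[usable])
  l[usable] <- l[usable] - median(l[usable])
  l
}

#' Binned copy-number profile of one sample
#'
#' Convenience wrapper running the binned sWGS workflow: count fragments in
#' the genome's bins, correct for GC/mappability, exclude blacklisted bins,
#' and median-normalize to per-bin log2 ratios.
#'
#' @param fragments fragment data frame.
#' @param genome a [synthetic_genome()], or a list with `bins` (annotated bin
#'   table with `chrom`, `start`, `end`, `gc`, `mappability`).
#' @param blacklist BED-like data frame of excluded regions; defaults to the
#'   genome's own blacklist.
#' @return Data frame of class `binned_profile`: the bin table plus
#'   `blacklisted`, `raw`, `corrected`, `log2r`, `usable`.
#' @export
bin_profile <- function(fragments, genome, blacklist = genome$blacklist) {
  bins <- genome$bins
  stopifnot(all(c("chrom", "start", "end", "gc", "mappability") %in% names(bins)))
  raw <- count_in_bins(fragments, bins)
  bl <- flag_blacklisted(bins, blacklist)
  corrected <- suppressWarnings(
    correct_counts(raw, bins$gc, bins$mappability, bl))
  log2r <- to_log2r(corrected)
  out <- bins
  out$blacklisted <- bl
  out$raw <- as.integer(raw)
  out$corrected <- as.numeric(corrected)
  out$log2r <- log2r
  out$usable <- !is.na(log2r)
  class(out) <- c("binned_profile", "data.frame")
  attr(out, "unassigned") <- attr(raw, "unassigned")
  out
}
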