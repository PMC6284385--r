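#' Read cfDNA fragment records
#'
#' Reads paired-end fragments either from a BED-like TSV (`chrom start end
#' [length]`, 0-based half-open) or from a coordinate BAM. For BAM input only
#' properly paired, primary, non-duplicate, non-supplementary first-of-pair
#' reads with both mates mapped to the same chromosome are used; the fragment
#' length is the outer distance of the pair (|template length|), taken from
#' read 1 only so each pair yields exactly one fragment. Records outside
#' `length_bounds` are discarded; the number of records dropped per reason is
#' attached as attribute `"filter_log"`.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"`, or `"bam"`. BAM support
#'   requires the Rsamtools package.
#' @param min_mapq minimum mapping quality (BAM only).
#' @param length_bounds inclusive fragment-length bounds in bp.
#' @return Data frame with columns `chrom`, `start`, `end`, `length` and a
#'   `"filter_log"` attribute (named integer vector of discard counts).
#' @export
read_fragments <- function(path, format = c("auto", "bed", "bam"),
                           min_mapq = 30, length_bounds = c(50, 700)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  if (!file.exists(path)) stop("cannot read fragment file: ", path)
  if (format == "bed") read_fragments_bed(path, length_bounds)
  else read_fragments_bam(path, min_mapq, length_bounds)
}

read_fragments_bed <- function(path, length_bounds) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "start", "end", "length")[1:4],
                   fill = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer", "integer"))
  if (!nrow(df)) stop("no records in ", path)
  if (all(is.na(df$length))) df$length <- df$end - df$start
  if (any(df$end <= df$start))
    stop("malformed BED: end must be greater than start")
  df$length <- df$end - df$start
  keep <- df$length >= length_bounds[1] & df$length <= length_bounds[2]
  out <- df[keep, ]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(length_out_of_bounds = sum(!keep))
  out
}

read_fragments_bam <- function(path, min_mapq, length_bounds) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  flag_r1 <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isFirstMateRead = TRUE,
    isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = FALSE)
  p <- Rsamtools::ScanBamParam(
    flag = flag_r1, what = c("rname", "pos", "mpos", "isize", "mapq", "mrnm"))
  res <- Rsamtools::scanBam(path, param = p)[[1]]
  total <- Rsamtools::countBam(path)$records
  n_r1_all <- Rsamtools::countBam(
    path, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isFirstMateRead = TRUE)))$records
  if (total > 0 && n_r1_all == 0)
    stop("BAM contains no paired reads; fragment lengths need read pairs")
  n0 <- length(res$pos)
  if (n0 == 0 && total == 0) stop("no records in ", path)
  same_chrom <- !is.na(res$mrnm) & as.character(res$mrnm) == as.character(res$rname)
  mq_ok <- !is.na(res$mapq) & res$mapq >= min_mapq
  len <- abs(res$isize)
  len_ok <- !is.na(res$isize) & res$isize != 0 &
    len >= length_bounds[1] & len <= length_bounds[2]
  keep <- same_chrom & mq_ok & len_ok
  start <- pmin(res$pos[keep], res$mpos[keep]) - 1L  # BAM 1-based -> 0-based
  out <- data.frame(chrom = as.character(res$rname)[keep],
                    start = start,
                    end = start + len[keep],
                    length = as.integer(len[keep]))
  ord <- order(out$chrom, out$start)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(
    flag_filtered = n_r1_all - n0,
    mate_other_chrom = sum(!same_chrom),
    low_mapq = sum(same_chrom & !mq_ok),
    length_out_of_bounds = sum(same_chrom & mq_ok & !len_ok))
  out
}

#' Write fragment records as BED-like TSV
#'
#' Tab-separated `chrom start end length`, no header; the exact inverse of
#' [read_fragments()] with `format = "bed"`.
#'
#' @param records fragment data frame.
#' @param path output file.
#' @export
write_fragments <- function(records, path) {
  stopifnot(all(c("chrom", "start", "end", "length") %in% names(records)))
  write.table(records[, c("chrom", "start", "end", "length")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Down-sample fragments to a fixed count
#'
#' Uniform sampling without replacement, as done when depth-matching samples
#' before comparing fragment-size profiles. If `n` is at least the number of
#' records the input is returned unchanged with a warning.
#'
#' @param records fragment data frame.
#' @param n target fragment count.
#' @param seed integer seed.
#' @return Fragment data frame with `min(n, nrow(records))` rows, original
#'   order preserved.
#' @export
downsample_fragments <- function(records, n, seed = 1L) {
  if (!is_count(n)) stop("n must be a count >= 1")
  if (n >= nrow(records)) {
    if (n > nrow(records))
      warning("requested ", n, " fragments but only ", nrow(records),
              " available; returning all")
    return(records)
  }
  idx <- withr::with_seed(as.integer(seed),
                          sort(sample.int(nrow(records), n)))
  out <- records[idx, ]
  rownames(out) <- NULL
  out
}
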