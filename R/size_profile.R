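new_size_profile <- function(counts, range, n_out_of_range = 0L,
                             density = NULL, n_samples = NULL) {
  sizes <- seq(range[1], range[2])
  if (is.null(density)) {
    n <- sum(counts)
    density <- counts / n
  } else {
    n <- if (is.null(counts)) NA_integer_ else sum(counts)
  }
  structure(list(range = as.integer(range), sizes = as.integer(sizes),
                 counts = counts, density = density, n = n,
                 n_out_of_range = as.integer(n_out_of_range),
                 n_samples = n_samples),
            class = "size_profile")
}

#' Fragment-size histogram
#'
#' Exact integer-bp histogram of fragment lengths over a fixed range. The
#' height (density) at x bp is the number of fragments of length x divided by
#' the total number of in-range fragments, so densities sum to one over the
#' range. No smoothing is applied: the periodicity statistics require raw bp
#' resolution.
#'
#' @param x fragment data frame (with a `length` column) or a numeric vector
#'   of lengths in bp.
#' @param range inclusive `[lo, hi]` bp range of the histogram.
#' @return An object of class `size_profile`: list with `range`, `sizes`,
#'   `counts`, `density`, `n` (in-range fragments) and `n_out_of_range`.
#' @export
size_histogram <- function(x, range = c(50, 700)) {
  lens <- if (is.data.frame(x)) x$length else x
  stopifnot(is.numeric(lens))
  range <- as.integer(range)
  in_range <- lens >= range[1] & lens <= range[2]
  if (!any(in_range)) stop("no fragments within size range")
  counts <- tabulate(as.integer(lens[in_range]) - range[1] + 1L,
                     nbins = range[2] - range[1] + 1L)
  new_size_profile(counts, range, n_out_of_range = sum(!in_range))
}

# profile carrying an externally supplied density (analytic or group mean)
profile_from_density <- function(density, range, n_samples = NULL) {
  stopifnot(length(density) == range[2] - range[1] + 1,
            all(density >= 0))
  new_size_profile(counts = NULL, range = range,
                   density = density / sum(density), n_samples = n_samples)
}

#' @export
print.size_profile <- function(x, ...) {
  cat(sprintf("size_profile over [%d, %d] bp; n = %s fragments%s\n",
              x$range[1], x$range[2],
              ifelse(is.na(x$n), "NA", format(x$n, big.mark = ",")),
              if (!is.null(x$n_samples))
                sprintf(" (mean of %d samples)", x$n_samples) else ""))
  invisible(x)
}

#' Fraction of fragments below a size threshold
#'
#' Strict inequality: the fraction of fragments with length `< threshold` bp,
#' the standard short-fragment summary contrasting CSF against plasma cfDNA.
#'
#' @param profile a `size_profile`.
#' @param threshold bp threshold, must lie within the profile range.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_below <- function(profile, threshold = 150) {
  stopifnot(inherits(profile, "size_profile"))
  if (threshold < profile$range[1] || threshold > profile$range[2])
    stop("threshold outside profile range")
  sum(profile$density[profile$sizes < threshold])
}

#' Cumulative size-frequency curve
#'
#' @param profile a `size_profile`.
#' @return Data frame with `size` and `cumulative` (monotone nondecreasing,
#'   reaching 1 at the range end).
#' @export
cumulative_curve <- function(profile) {
  stopifnot(inherits(profile, "size_profile"))
  data.frame(size = profile$sizes, cumulative = cumsum(profile$density))
}

#' Per-group mean fragment-size density
#'
#' Averages per-sample densities sample-wise (each sample contributes equally
#' regardless of depth) and renormalizes each group mean to sum to one.
#'
#' @param profiles list of `size_profile` objects on identical ranges.
#' @param groups character/factor vector of group labels, one per profile.
#' @return Named list of `size_profile` objects, one per group.
#' @export
group_mean_density <- function(profiles, groups) {
  stopifnot(length(profiles) == length(groups), length(profiles) >= 1)
  ranges <- vapply(profiles, function(p) p$range, integer(2))
  if (any(ranges[1, ] != ranges[1, 1]) || any(ranges[2, ] != ranges[2, 1]))
    stop("profiles must share an identical size range")
  groups <- as.character(groups)
  out <- lapply(split(seq_along(profiles), groups), function(idx) {
    if (!length(idx)) stop("empty group")
    d <- rowMeans(vapply(profiles[idx], function(p) p$density,
                         numeric(length(profiles[[1]]$density))))
    profile_from_density(d, profiles[[1]]$range, n_samples = length(idx))
  })
  out
}

#' Per-size log2 ratio of two densities
#'
#' `log2((a(x) + eps) / (b(x) + eps))` at every size x, with a small
#' pseudo-density `eps` guarding empty sizes; `eps` is recorded in the
#' `"pseudocount"` attribute of the result.
#'
#' @param a,b `size_profile` objects on identical ranges (e.g. the group mean
#'   densities of SCNA-positive and SCNA-negative samples).
#' @param pseudocount pseudo-density added to both numerator and denominator.
#' @return Data frame with `size` and `log2_ratio`.
#' @export
log2_ratio_curve <- function(a, b, pseudocount = 1e-6) {
  stopifnot(inherits(a, "size_profile"), inherits(b, "size_profile"))
  if (!identical(a$range, b$range))
    stop("profiles must share an identical size range")
  out <- data.frame(size = a$sizes,
                    log2_ratio = log2((a$density + pseudocount) /
                                      (b$density + pseudocount)))
  attr(out, "pseudocount") <- pseudocount
  out
}
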