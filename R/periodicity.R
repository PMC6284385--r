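#' Local extrema of a fragment-size density
#'
#' Finds the positions of the 10 bp periodic peaks and troughs of a
#' fragment-size density in the sub-nucleosomal range. A position y in
#' `[lo, hi]` is a local maximum iff its density is strictly larger than the
#' density at every other position in the window `[y - w, y + w]`; minima are
#' symmetric with the strictly smallest value. Exact ties within a window
#' disqualify all tied positions (conservative and reproducible on integer
#' count data). Positions whose window is not fully covered by the profile
#' are ineligible.
#'
#' @param profile a `size_profile` covering at least `[lo - w, hi + w]`.
#' @param lo,hi inclusive search range in bp (default 75-150).
#' @param w window half-width in bp (default 2).
#' @return An object of class `extrema_set`: list with sorted `maxima` and
#'   `minima` positions (bp), their densities `heights_maxima` /
#'   `heights_minima`, `search_range` and `w`.
#' @export
find_local_extrema <- function(profile, lo = 75, hi = 150, w = 2) {
  stopifnot(inherits(profile, "size_profile"))
  if (profile$range[1] > lo - w || profile$range[2] < hi + w)
    stop("profile must cover [lo - w, hi + w]")
  d <- profile$density
  sizes <- profile$sizes
  maxima <- integer()
  minima <- integer()
  for (y in lo:hi) {
    i <- y - profile$range[1] + 1L
    win <- d[(i - w):(i + w)]
    centre <- d[i]
    others <- win[-(w + 1L)]
    if (centre > max(others)) maxima <- c(maxima, y)
    else if (centre < min(others)) minima <- c(minima, y)
  }
  structure(list(maxima = maxima, minima = minima,
                 heights_maxima = d[maxima - profile$range[1] + 1L],
                 heights_minima = d[minima - profile$range[1] + 1L],
                 search_range = c(lo, hi), w = w),
            class = "extrema_set")
}

#' @export
print.extrema_set <- function(x, ...) {
  cat(sprintf("extrema_set in [%d, %d] bp: %d maxima (%s), %d minima (%s)\n",
              x$search_range[1], x$search_range[2],
              length(x$maxima), paste(x$maxima, collapse = ", "),
              length(x$minima), paste(x$minima, collapse = ", ")))
  invisible(x)
}

#' Does a sample show a clear 10 bp comb?
#'
#' Qualifying rule for cross-sample extrema averaging: a sample has "clear
#' peaks" if its detected maxima contain a run of at least `min_maxima`
#' consecutive positions whose spacings all lie inside `spacing` bp. This
#' captures the 10 bp comb while excluding flat or noise-dominated profiles,
#' and tolerates stray noise maxima outside the comb (common in the
#' low-density 75-100 bp tail at shallow depth).
#'
#' @param extrema an `extrema_set`.
#' @param min_maxima minimum length of the evenly spaced run of maxima.
#' @param spacing allowed `[lo, hi]` spacing between consecutive maxima (bp).
#' @return Logical scalar.
#' @export
has_clear_peaks <- function(extrema, min_maxima = 5, spacing = c(8, 13)) {
  stopifnot(inherits(extrema, "extrema_set"))
  m <- extrema$maxima
  if (length(m) < min_maxima) return(FALSE)
  ok <- diff(m) >= spacing[1] & diff(m) <= spacing[2]
  r <- rle(ok)
  any(r$values & r$lengths >= min_maxima - 1)
}

# greedy position clustering: positions (with sample ids) sorted ascending,
# a new cluster opens when a position is > width bp from the running mean
cluster_positions <- function(pos, sample_idx, width) {
  o <- order(pos)
  pos <- pos[o]; sample_idx <- sample_idx[o]
  clusters <- list()
  cur <- numeric(); cur_s <- integer()
  for (k in seq_along(pos)) {
    if (length(cur) && pos[k] - mean(cur) > width) {
      clusters[[length(clusters) + 1L]] <- list(pos = cur, samples = cur_s)
      cur <- numeric(); cur_s <- integer()
    }
    cur <- c(cur, pos[k]); cur_s <- c(cur_s, sample_idx[k])
  }
  if (length(cur))
    clusters[[length(clusters) + 1L]] <- list(pos = cur, samples = cur_s)
  clusters
}

#' Average extrema positions across samples
#'
#' Pools per-sample extrema from the samples with a clear 10 bp comb,
#' clusters positions within `cluster_width` bp across samples, and averages
#' each sufficiently supported cluster to one consensus position (arithmetic
#' mean, rounded half-up to 1 bp). The consensus positions are then applied
#' uniformly to every sample when computing the amplitude statistic.
#'
#' @param extrema_sets list of `extrema_set` objects, one per sample.
#' @param min_support minimum fraction of qualifying samples a cluster must
#'   appear in to be retained.
#' @param cluster_width maximum distance (bp) from a cluster's running mean;
#'   the default 3 bp is below half the 10 bp period, so neighboring comb
#'   teeth are never merged.
#' @param require_clear_peaks apply the [has_clear_peaks()] qualifying rule
#'   (the canonical behavior); set `FALSE` to average all supplied samples.
#' @return An object of class `averaged_extrema`: list with `mean_maxima`,
#'   `mean_minima` (integer bp) and `n_samples_used`.
#' @export
average_extrema_positions <- function(extrema_sets, min_support = 0.5,
                                      cluster_width = 3,
                                      require_clear_peaks = TRUE) {
  stopifnot(length(extrema_sets) >= 1,
            all(vapply(extrema_sets, inherits, logical(1), "extrema_set")))
  qualify <- if (require_clear_peaks)
    vapply(extrema_sets, has_clear_peaks, logical(1))
  else rep(TRUE, length(extrema_sets))
  if (!any(qualify))
    stop("no qualifying samples: no profile shows a clear 10 bp comb")
  sets <- extrema_sets[qualify]
  n_q <- length(sets)
  consensus <- function(kind) {
    pos <- unlist(lapply(sets, `[[`, kind))
    idx <- rep(seq_along(sets),
               vapply(sets, function(s) length(s[[kind]]), integer(1)))
    if (!length(pos)) return(integer())
    cl <- cluster_positions(pos, idx, cluster_width)
    keep <- vapply(cl, function(c) length(unique(c$samples)) >= min_support * n_q,
                   logical(1))
    as.integer(sort(vapply(cl[keep], function(c) round_half_up(mean(c$pos)),
                           numeric(1))))
  }
  structure(list(mean_maxima = consensus("maxima"),
                 mean_minima = consensus("minima"),
                 n_samples_used = n_q),
            class = "averaged_extrema")
}

#' @export
print.averaged_extrema <- function(x, ...) {
  cat(sprintf("averaged_extrema from %d samples\n  maxima: %s\n  minima: %s\n",
              x$n_samples_used, paste(x$mean_maxima, collapse = ", "),
              paste(x$mean_minima, collapse = ", ")))
  invisible(x)
}

#' The 10 bp periodicity amplitude statistic
#'
#' Sum of the density heights at the consensus maxima positions minus the sum
#' at the consensus minima positions, where the height at x bp is the number
#' of fragments of length x divided by the total fragment count. The larger
#' the value, the more distinct the 10 bp periodic peaks; tumor-derived cfDNA
#' damps the oscillation and lowers the statistic.
#'
#' @param profile a `size_profile`.
#' @param averaged an `averaged_extrema` (cohort consensus positions), or an
#'   `extrema_set` for the non-canonical per-sample variant.
#' @return An object of class `amplitude_stat`: list with `value`
#'   (`maxima_height_sum - minima_height_sum`), the two height sums, and the
#'   positions used.
#' @export
amplitude_statistic <- function(profile, averaged) {
  stopifnot(inherits(profile, "size_profile"))
  if (inherits(averaged, "extrema_set")) {
    maxima <- averaged$maxima; minima <- averaged$minima
  } else if (inherits(averaged, "averaged_extrema")) {
    maxima <- averaged$mean_maxima; minima <- averaged$mean_minima
  } else stop("`averaged` must be an averaged_extrema or extrema_set")
  pos <- c(maxima, minima)
  if (length(pos) && (min(pos) < profile$range[1] || max(pos) > profile$range[2]))
    stop("extrema position outside profile range")
  h <- function(p) sum(profile$density[p - profile$range[1] + 1L])
  structure(list(value = h(maxima) - h(minima),
                 maxima_height_sum = h(maxima),
                 minima_height_sum = h(minima),
                 n_maxima = length(maxima), n_minima = length(minima)),
            class = "amplitude_stat")
}

#' @export
print.amplitude_stat <- function(x, ...) {
  cat(sprintf("amplitude A = %.5g (%d maxima, %d minima)\n",
              x$value, x$n_maxima, x$n_minima))
  invisible(x)
}

#' Cohort amplitude table
#'
#' Runs the canonical amplitude workflow over a cohort: per-sample extremum
#' detection, consensus position averaging across the samples with clear
#' peaks, then the amplitude statistic of every sample at the shared
#' consensus positions.
#'
#' @param profiles named list of `size_profile` objects.
#' @param lo,hi,w extremum search parameters, see [find_local_extrema()].
#' @param min_support see [average_extrema_positions()].
#' @return Data frame with `sample_id`, `amplitude`, `n_maxima_used`,
#'   `n_minima_used`; the consensus positions are attached as attribute
#'   `"averaged_extrema"`.
#' @export
cohort_amplitude <- function(profiles, lo = 75, hi = 150, w = 2,
                             min_support = 0.5) {
  stopifnot(length(profiles) >= 1)
  if (is.null(names(profiles)))
    names(profiles) <- sprintf("S%02d", seq_along(profiles))
  ex <- lapply(profiles, find_local_extrema, lo = lo, hi = hi, w = w)
  avg <- average_extrema_positions(ex, min_support = min_support)
  amps <- vapply(profiles, function(p) amplitude_statistic(p, avg)$value,
                 numeric(1))
  out <- data.frame(sample_id = names(profiles), amplitude = unname(amps),
                    n_maxima_used = length(avg$mean_maxima),
                    n_minima_used = length(avg$mean_minima))
  attr(out, "averaged_extrema") <- avg
  out
}

#' Analytic amplitude statistic of the simulator density
#'
#' Computes the amplitude statistic directly on the exact mixture density of
#' a [sim_config()] (no sampling noise). Mirroring the canonical cohort
#' workflow -- where consensus extrema positions come from the samples with a
#' clear 10 bp comb and are then applied to every sample -- the positions are
#' by default the extrema of the background (tumor-free) analytic density,
#' and the heights are read off the mixture density at the requested tumor
#' fraction. With fixed positions the statistic is linear in the tumor
#' fraction, so it decreases strictly whenever the tumor component's comb is
#' damped.
#'
#' @inheritParams length_density
#' @param lo,hi,w extremum search parameters.
#' @param positions optional `extrema_set`/`averaged_extrema` giving the
#'   height-readout positions; defaults to the extrema of the background
#'   density.
#' @return Numeric amplitude value.
#' @export
analytic_amplitude <- function(config, tumor_fraction = config$tumor_fraction,
                               lo = 75, hi = 150, w = 2, positions = NULL) {
  if (is.null(positions)) {
    bg <- length_density(config, tumor_fraction = 0)
    pbg <- profile_from_density(bg$density, config$length_range)
    positions <- find_local_extrema(pbg, lo = lo, hi = hi, w = w)
  }
  dens <- length_density(config, tumor_fraction)
  p <- profile_from_density(dens$density, config$length_range)
  amplitude_statistic(p, positions)$value
}
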