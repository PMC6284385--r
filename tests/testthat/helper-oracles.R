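# Independent brute-force oracles used to validate the package's algorithms.
# These deliberately share no code with the implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive window-scan extremum finder: y is a maximum iff its density is
# strictly greater than the density at every other position in [y-w, y+w]
oracle_extrema <- function(density, range_lo, lo = 75, hi = 150, w = 2) {
  maxima <- integer(0)
  minima <- integer(0)
  for (y in lo:hi) {
    vals <- vapply((y - w):(y + w), function(z) density[z - range_lo + 1L],
                   numeric(1))
    centre <- density[y - range_lo + 1L]
    others <- vals[-(w + 1L)]
    if (all(centre > others)) maxima <- c(maxima, y)
    if (all(centre < others)) minima <- c(minima, y)
  }
  list(maxima = maxima, minima = minima)
}

# exhaustive max-|t| split search via t.test (pooled variance), arms >= 2
oracle_best_split <- function(x) {
  n <- length(x)
  best <- NULL
  for (k in 2:(n - 2)) {
    tt <- unname(stats::t.test(x[1:k], x[(k + 1):n], var.equal = TRUE)$statistic)
    if (is.null(best) || abs(tt) > best$t) best <- list(k = k, t = abs(tt))
  }
  best
}

# exhaustive enumeration of all K^n state paths of the Gaussian HMM
oracle_viterbi <- function(x, means, sd, eps) {
  K <- length(means)
  n <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- apply(paths, 1, function(p) {
    v <- log(1 / K) + sum(dnorm(x, means[p], sd, log = TRUE))
    if (n > 1)
      v <- v + sum(ifelse(diff(p) == 0, log(1 - (K - 1) * eps), log(eps)))
    v
  })
  unname(paths[which.max(lp), ])
}

# analytic simulator density recomputed from its definition (independent of
# length_density): Gaussian mixture with a cosine modulation in osc_range
oracle_density <- function(cfg, tf) {
  x <- seq(cfg$length_range[1], cfg$length_range[2])
  comp <- function(mode, sd, di_mode, di_sd, di_w, amp, sh_w = 0) {
    d <- (1 - di_w - cfg$variant_weight - sh_w) * dnorm(x, mode, sd) +
      sh_w * dnorm(x, cfg$bg_shoulder_mode, cfg$bg_shoulder_sd) +
      di_w * dnorm(x, di_mode, di_sd) +
      cfg$variant_weight * dnorm(x, cfg$variant_mode, cfg$variant_sd)
    osc <- x >= cfg$osc_range[1] & x <= cfg$osc_range[2]
    d[osc] <- d[osc] *
      (1 + amp * cos(2 * pi * (x[osc] - cfg$osc_phase) / cfg$osc_period))
    d / sum(d)
  }
  bg <- comp(cfg$bg_mono_mode, cfg$bg_mono_sd, cfg$bg_di_mode, cfg$bg_di_sd,
             cfg$bg_di_weight, cfg$osc_amp_bg, cfg$bg_shoulder_weight)
  tm <- comp(cfg$tumor_mode, cfg$tumor_sd, cfg$tumor_di_mode, cfg$tumor_di_sd,
             cfg$tumor_di_weight, cfg$osc_amp_tumor)
  data.frame(length = x, density = (1 - tf) * bg + tf * tm)
}

# comb fixture: Gaussian bumps (sigma 1.5 bp) on a flat baseline
comb_profile <- function(centers, range = c(50, 700), sigma = 1.5,
                         baseline = 1) {
  x <- seq(range[1], range[2])
  d <- rep(baseline, length(x))
  for (c0 in centers) d <- d + 50 * dnorm(x, c0, sigma)
  csffrag:::profile_from_density(d, as.integer(range))
}

# small fragment table helper
frag_df <- function(chrom, start, len) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), length = as.integer(len))
}
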