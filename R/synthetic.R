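#' Simulation configuration for synthetic cfDNA fragments
#'
#' Parameterizes the two-component (background / tumor) fragment-length model
#' and the genomic placement model used by [simulate_sample()]. The background
#' component emulates non-tumor cfDNA: a mono-nucleosomal mode near 167 bp, a
#' di-nucleosomal mode near 320 bp, and a strong 10 bp oscillation below
#' 150 bp. The tumor component is shifted to a ~145 bp mode, carries a damped
#' oscillation, and has a larger di-nucleosomal weight (with a broader, lower
#' mode) so that tumor-rich samples are relatively enriched in 220-320 bp
#' fragments.
#'
#' On the integer length grid (default 50-700 bp) each component density is a
#' Gaussian mixture; within `osc_range` it is multiplied by
#' `1 + a * cos(2*pi*(x - osc_phase)/osc_period)` where `a` is the component's
#' oscillation amplitude. The sample density is the `tumor_fraction`-weighted
#' mixture of the normalized component densities.
#'
#' @param n_fragments number of fragments per simulated sample.
#' @param tumor_fraction fraction of fragments drawn from the tumor component,
#'   in `[0, 1]`.
#' @param bg_mono_mode,bg_mono_sd background mono-nucleosomal mode / sd (bp).
#' @param bg_shoulder_mode,bg_shoulder_sd,bg_shoulder_weight broad
#'   sub-nucleosomal shoulder of the background component. Real cfDNA
#'   profiles pair a sharp mono-nucleosomal peak with a long sub-150 bp
#'   shoulder on which the 10 bp ladder rides; a single Gaussian cannot give
#'   both, so the shoulder is modeled explicitly.
#' @param bg_di_mode,bg_di_sd,bg_di_weight background di-nucleosomal mode, sd
#'   (bp) and mixture weight.
#' @param tumor_mode,tumor_sd tumor mono-nucleosomal mode / sd (bp).
#' @param tumor_di_mode,tumor_di_sd,tumor_di_weight tumor di-nucleosomal mode,
#'   sd (bp) and weight; must be `>= bg_di_weight`.
#' @param variant_mode,variant_sd,variant_weight optional third ("histone
#'   variant") mode near 133 bp; off by default (`variant_weight = 0`).
#' @param osc_period oscillation period in bp (default 10.4).
#' @param osc_phase oscillation phase in bp: cosine maxima fall at
#'   `osc_phase + k * osc_period`. The default (81) places analytic maxima
#'   near 81, 91, 102, ..., 143 bp.
#' @param osc_amp_bg,osc_amp_tumor oscillation amplitudes in `[0, 1)`;
#'   `osc_amp_tumor` must be strictly below `osc_amp_bg`.
#' @param osc_range bp range in which the oscillation applies.
#' @param gc_bias_slope linear GC-bias slope of the placement weights
#'   (`1 + slope * (gc - mean(gc))`); `0` disables GC bias.
#' @param length_range integer bp grid on which lengths are drawn.
#' @param seed integer seed for this sample's random stream.
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [length_density()], [sample_fragment_lengths()], [simulate_sample()]
#' @export
sim_config <- function(n_fragments = 200000L,
                       tumor_fraction = 0,
                       bg_mono_mode = 167, bg_mono_sd = 12,
                       bg_shoulder_mode = 110, bg_shoulder_sd = 25,
                       bg_shoulder_weight = 0.12,
                       bg_di_mode = 320, bg_di_sd = 25, bg_di_weight = 0.10,
                       tumor_mode = 145, tumor_sd = 12,
                       tumor_di_mode = 300, tumor_di_sd = 40,
                       tumor_di_weight = 0.25,
                       variant_mode = 133, variant_sd = 8, variant_weight = 0,
                       osc_period = 10.4, osc_phase = 81,
                       osc_amp_bg = 0.30, osc_amp_tumor = 0.05,
                       osc_range = c(75, 150),
                       gc_bias_slope = 0.5,
                       length_range = c(50L, 700L),
                       seed = 1L) {
  cfg <- list(
    n_fragments = n_fragments, tumor_fraction = tumor_fraction,
    bg_mono_mode = bg_mono_mode, bg_mono_sd = bg_mono_sd,
    bg_shoulder_mode = bg_shoulder_mode, bg_shoulder_sd = bg_shoulder_sd,
    bg_shoulder_weight = bg_shoulder_weight,
    bg_di_mode = bg_di_mode, bg_di_sd = bg_di_sd, bg_di_weight = bg_di_weight,
    tumor_mode = tumor_mode, tumor_sd = tumor_sd,
    tumor_di_mode = tumor_di_mode, tumor_di_sd = tumor_di_sd,
    tumor_di_weight = tumor_di_weight,
    variant_mode = variant_mode, variant_sd = variant_sd,
    variant_weight = variant_weight,
    osc_period = osc_period, osc_phase = osc_phase,
    osc_amp_bg = osc_amp_bg, osc_amp_tumor = osc_amp_tumor,
    osc_range = osc_range, gc_bias_slope = gc_bias_slope,
    length_range = as.integer(length_range), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("tumor_fraction", "bg_di_weight", "tumor_di_weight",
                   "variant_weight", "bg_shoulder_weight")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_field(f, "must be a fraction in [0, 1]")
  }
  for (f in c("osc_amp_bg", "osc_amp_tumor")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v >= 1)
      stop_field(f, "must be in [0, 1) so the density stays non-negative")
  }
  if (cfg$osc_amp_tumor >= cfg$osc_amp_bg)
    stop_field("osc_amp_tumor", "must be strictly below `osc_amp_bg`")
  if (cfg$tumor_di_weight < cfg$bg_di_weight)
    stop_field("tumor_di_weight", "must be >= `bg_di_weight`")
  if (cfg$bg_shoulder_weight + cfg$bg_di_weight + cfg$variant_weight >= 1)
    stop_field("bg_shoulder_weight",
               "background component weights must sum below 1")
  for (f in c("bg_mono_mode", "bg_shoulder_mode", "bg_di_mode", "tumor_mode",
              "tumor_di_mode", "variant_mode")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 50 || v > 500)
      stop_field(f, "mode must lie within [50, 500] bp")
  }
  for (f in c("bg_mono_sd", "bg_shoulder_sd", "bg_di_sd", "tumor_sd",
              "tumor_di_sd", "variant_sd")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop_field(f, "sd must be > 0")
  }
  if (!is_count(cfg$n_fragments)) stop_field("n_fragments", "must be a count >= 1")
  if (!is.numeric(cfg$osc_period) || cfg$osc_period <= 0)
    stop_field("osc_period", "must be > 0")
  if (length(cfg$osc_range) != 2L || cfg$osc_range[1] >= cfg$osc_range[2])
    stop_field("osc_range", "must be an increasing [lo, hi] pair")
  if (length(cfg$length_range) != 2L || cfg$length_range[1] >= cfg$length_range[2])
    stop_field("length_range", "must be an increasing [lo, hi] pair")
  invisible(cfg)
}

# normalized density of one mixture component on the integer grid x
component_density <- function(x, mono_mode, mono_sd, di_mode, di_sd, di_weight,
                              variant_mode, variant_sd, variant_weight,
                              osc_amp, osc_period, osc_phase, osc_range,
                              shoulder_mode = 110, shoulder_sd = 25,
                              shoulder_weight = 0) {
  mono_weight <- 1 - di_weight - variant_weight - shoulder_weight
  d <- mono_weight * dnorm(x, mono_mode, mono_sd) +
    shoulder_weight * dnorm(x, shoulder_mode, shoulder_sd) +
    di_weight * dnorm(x, di_mode, di_sd) +
    variant_weight * dnorm(x, variant_mode, variant_sd)
  in_osc <- x >= osc_range[1] & x <= osc_range[2]
  d[in_osc] <- d[in_osc] *
    (1 + osc_amp * cos(2 * pi * (x[in_osc] - osc_phase) / osc_period))
  d / sum(d)
}

#' Analytic fragment-length density of the simulator
#'
#' Evaluates the exact mixture density that [sample_fragment_lengths()] draws
#' from, on the integer bp grid of `config$length_range`. This is the
#' independent reference for tests of modal positions, sub-150 bp fractions
#' and the analytic amplitude statistic.
#'
#' @param config a [sim_config()].
#' @param tumor_fraction mixture weight of the tumor component; defaults to
#'   the value stored in `config`.
#' @return A data frame with columns `length` and `density` (sums to 1).
#' @export
length_density <- function(config, tumor_fraction = config$tumor_fraction) {
  stopifnot(inherits(config, "sim_config"))
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop_field("tumor_fraction", "must be a fraction in [0, 1]")
  x <- seq(config$length_range[1], config$length_range[2])
  bg <- component_density(x, config$bg_mono_mode, config$bg_mono_sd,
                          config$bg_di_mode, config$bg_di_sd, config$bg_di_weight,
                          config$variant_mode, config$variant_sd,
                          config$variant_weight,
                          config$osc_amp_bg, config$osc_period, config$osc_phase,
                          config$osc_range,
                          config$bg_shoulder_mode, config$bg_shoulder_sd,
                          config$bg_shoulder_weight)
  tm <- component_density(x, config$tumor_mode, config$tumor_sd,
                          config$tumor_di_mode, config$tumor_di_sd,
                          config$tumor_di_weight,
                          config$variant_mode, config$variant_sd,
                          config$variant_weight,
                          config$osc_amp_tumor, config$osc_period,
                          config$osc_phase, config$osc_range)
  data.frame(length = x,
             density = (1 - tumor_fraction) * bg + tumor_fraction * tm)
}

# inverse-CDF draw of n integer lengths from a density data.frame
draw_lengths <- function(dens, n) {
  cdf <- cumsum(dens$density)
  cdf[length(cdf)] <- 1
  u <- runif(n)
  dens$length[findInterval(u, cdf, left.open = TRUE) + 1L]
}

#' Sample fragment lengths from the analytic density
#'
#' Draws integer fragment lengths by inverse-CDF sampling on the integer bp
#' grid, which is deterministic for a fixed seed across platforms.
#'
#' @inheritParams length_density
#' @param n number of lengths to draw.
#' @param seed integer seed.
#' @return Integer vector of `n` fragment lengths (bp).
#' @export
sample_fragment_lengths <- function(config, n = config$n_fragments,
                                    seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(n)) stop_field("n", "must be a count >= 1")
  dens <- length_density(config)
  withr::with_seed(as.integer(seed), draw_lengths(dens, n))
}

#' Synthetic genome for desk-scale pipeline runs
#'
#' Builds a small stand-in genome: `n_chrom` autosome-like chromosomes of
#' equal length, tiled into fixed-width bins with per-bin GC fraction (drawn
#' once per build from a beta distribution centered near 0.41) and
#' mappability (1.0 except a small fraction of dropout bins), plus a small
#' random blacklist of artifact-prone bins. The default 22 x 3 Mb layout is a
#' ~1:47 scale model of the human autosomes, keeping full-pipeline runs fast
#' while preserving per-chromosome bin counts large enough for segmentation.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin width in bp.
#' @param gc_shape two beta shape parameters for per-bin GC.
#' @param map_dropout_frac fraction of bins with reduced mappability.
#' @param dropout_map mappability value assigned to dropout bins.
#' @param blacklist_frac fraction of bins put on the exclusion blacklist.
#' @param seed build seed (a genome is built once and reused).
#' @return An object of class `synthetic_genome`: list with `chroms`,
#'   `chrom_lengths` (named), `bin_size`, `bins` (data frame with `chrom`,
#'   `start`, `end`, `gc`, `mappability`) and `blacklist` (BED-like data
#'   frame).
#' @export
synthetic_genome <- function(n_chrom = 22, chrom_length = 3e6,
                             bin_size = 30000,
                             gc_shape = c(41, 59),
                             map_dropout_frac = 0.02, dropout_map = 0.5,
                             blacklist_frac = 0.01,
                             seed = 1L) {
  stopifnot(n_chrom >= 1, chrom_length > 0, bin_size >= 1000)
  chroms <- paste0("chr", seq_len(n_chrom))
  lens <- stats::setNames(rep(chrom_length, n_chrom), chroms)
  bins <- make_bins(lens, bin_size)
  nb <- nrow(bins)
  withr::with_seed(as.integer(seed), {
    bins$gc <- rbeta(nb, gc_shape[1], gc_shape[2])
    bins$mappability <- rep(1, nb)
    n_drop <- round(map_dropout_frac * nb)
    if (n_drop > 0)
      bins$mappability[sample.int(nb, n_drop)] <- dropout_map
    n_bl <- round(blacklist_frac * nb)
    bl_idx <- if (n_bl > 0) sort(sample.int(nb, n_bl)) else integer()
  })
  blacklist <- bins[bl_idx, c("chrom", "start", "end")]
  rownames(blacklist) <- NULL
  structure(list(chroms = chroms, chrom_lengths = lens, bin_size = bin_size,
                 bins = bins, blacklist = blacklist),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d chromosomes x %s bp, %d bins of %s bp, %d blacklisted\n",
              length(x$chroms),
              format(x$chrom_lengths[1], big.mark = ",", scientific = FALSE),
              nrow(x$bins),
              format(x$bin_size, big.mark = ",", scientific = FALSE),
              nrow(x$blacklist)))
  invisible(x)
}

#' Copy-number profile of the tumor component
#'
#' A set of non-overlapping genomic events, each assigning an integer tumor
#' copy number to a region; everything not covered is diploid
#' (`tumor_copies = 2`).
#'
#' @param events data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open bp) and `tumor_copies` (integer >= 0). May have zero rows.
#' @return An object of class `cn_profile`.
#' @export
cn_profile <- function(events = data.frame(chrom = character(),
                                           start = numeric(),
                                           end = numeric(),
                                           tumor_copies = numeric())) {
  stopifnot(all(c("chrom", "start", "end", "tumor_copies") %in% names(events)))
  if (nrow(events)) {
    if (any(events$end <= events$start))
      stop("cn_profile: events must have end > start")
    if (any(events$tumor_copies < 0 | events$tumor_copies != floor(events$tumor_copies)))
      stop("cn_profile: tumor_copies must be non-negative integers")
    ev <- events[order(events$chrom, events$start), ]
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    if (nrow(ev) > 1 && any(same & ev$start[-1] < ev$end[-nrow(ev)]))
      stop("cn_profile: events must not overlap")
    events <- ev
    rownames(events) <- NULL
  }
  structure(list(events = events), class = "cn_profile")
}

#' Neutral (diploid) copy-number profile
#' @return A `cn_profile` with no events.
#' @export
cn_neutral <- function() cn_profile()

#' Glioma-like gene regions on a synthetic genome
#'
#' Maps a small panel of genes recurrently altered in glioblastoma (EGFR,
#' MET, PDGFRA, CDKN2A, PTEN, CDK4, MDM2, RB1, NF1, TP53) onto the synthetic
#' genome by rescaling their GRCh37 coordinates to the synthetic chromosome
#' length, then padding each region to at least `pad_to` bp (so that every
#' region spans several bins at the default 30 kb binning).
#'
#' @param genome a [synthetic_genome()].
#' @param pad_to minimum region width in bp after padding (centered).
#' @return BED-like data frame with `chrom`, `start`, `end`, `name`.
#' @export
glioma_genes <- function(genome, pad_to = 120000) {
  stopifnot(inherits(genome, "synthetic_genome"))
  # GRCh37 gene spans (bp) and chromosome lengths (bp)
  tab <- data.frame(
    name  = c("PDGFRA", "EGFR", "MET", "CDKN2A", "PTEN", "CDK4", "MDM2",
              "RB1", "NF1", "TP53"),
    chrom = c("chr4", "chr7", "chr7", "chr9", "chr10", "chr12", "chr12",
              "chr13", "chr17", "chr17"),
    g_start = c(55095264, 55086714, 116312444, 21967751, 89623195, 58141510,
                69201956, 48877883, 29421945, 7571720),
    g_end   = c(55164414, 55324313, 116438440, 21995300, 89728532, 58149796,
                69239214, 49056026, 29704695, 7590868),
    g_len   = c(191154276, 159138663, 159138663, 141213431, 135534747,
                133851895, 133851895, 115169878, 81195210, 81195210)
  )
  tab <- tab[tab$chrom %in% genome$chroms, ]
  L <- genome$chrom_lengths[tab$chrom]
  start <- tab$g_start / tab$g_len * L
  end <- tab$g_end / tab$g_len * L
  mid <- (start + end) / 2
  width <- pmax(end - start, pad_to)
  start <- pmax(0, round(mid - width / 2))
  end <- pmin(L, round(mid + width / 2))
  out <- data.frame(chrom = tab$chrom, start = start, end = end,
                    name = tab$name)
  rownames(out) <- NULL
  out
}

#' Glioma-like copy-number profile
#'
#' Builds the canonical glioblastoma pattern on the synthetic genome: gain of
#' all of chr7 and loss of all of chr10, optionally with a focal EGFR
#' amplification and focal PTEN deletion nested inside (encoded as adjacent
#' non-overlapping events).
#'
#' @param genome a [synthetic_genome()].
#' @param gain_copies tumor copies for the chr7 gain.
#' @param loss_copies tumor copies for the chr10 loss.
#' @param focal add focal EGFR amplification / PTEN deletion on top of the
#'   whole-chromosome events.
#' @param egfr_copies,pten_copies tumor copies of the focal events.
#' @return A [cn_profile()].
#' @export
glioma_cn_profile <- function(genome, gain_copies = 3, loss_copies = 1,
                              focal = FALSE, egfr_copies = 6, pten_copies = 0) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (!all(c("chr7", "chr10") %in% genome$chroms))
    stop("genome lacks chr7/chr10; supply a custom cn_profile instead")
  L7 <- unname(genome$chrom_lengths["chr7"])
  L10 <- unname(genome$chrom_lengths["chr10"])
  if (!focal) {
    ev <- data.frame(chrom = c("chr7", "chr10"), start = c(0, 0),
                     end = c(L7, L10),
                     tumor_copies = c(gain_copies, loss_copies))
    return(cn_profile(ev))
  }
  genes <- glioma_genes(genome)
  egfr <- genes[genes$name == "EGFR", ]
  pten <- genes[genes$name == "PTEN", ]
  ev <- data.frame(
    chrom = c("chr7", "chr7", "chr7", "chr10", "chr10", "chr10"),
    start = c(0, egfr$start, egfr$end, 0, pten$start, pten$end),
    end = c(egfr$start, egfr$end, L7, pten$start, pten$end, L10),
    tumor_copies = c(gain_copies, egfr_copies, gain_copies,
                     loss_copies, pten_copies, loss_copies)
  )
  cn_profile(ev)
}

# per-bin tumor copy number: the event covering the bin midpoint, else 2
bin_tumor_copies <- function(bins, cn) {
  copies <- rep(2, nrow(bins))
  ev <- cn$events
  if (!nrow(ev)) return(copies)
  mid <- (bins$start + bins$end) / 2
  for (i in seq_len(nrow(ev))) {
    hit <- bins$chrom == ev$chrom[i] & mid >= ev$start[i] & mid < ev$end[i]
    copies[hit] <- ev$tumor_copies[i]
  }
  copies
}

#' Simulate one cfDNA sample on a synthetic genome
#'
#' Draws `config$n_fragments` fragments. Each fragment belongs to the tumor
#' component with probability `tumor_fraction` and takes its length from that
#' component's size model. Genomic placement is binned: the probability of a
#' bin is proportional to
#' `mappability * [(1 - tf) * 2 + tf * tumor_copies] / 2 *
#'  (1 + gc_bias_slope * (gc - mean(gc)))`
#' split into the background part (`2`) for background fragments and the
#' tumor part (`tumor_copies`) for tumor fragments, so that copy-number
#' events shape coverage only through the tumor component. The start
#' coordinate is uniform within the bin.
#'
#' @param config a [sim_config()].
#' @param genome a [synthetic_genome()].
#' @param cn a [cn_profile()]; defaults to neutral.
#' @param seed integer seed; defaults to `config$seed`.
#' @return Data frame of fragment records with columns `chrom`, `start`,
#'   `end`, `length` (0-based half-open; `end - start == length`), sorted by
#'   chromosome then start.
#' @export
simulate_sample <- function(config, genome, cn = cn_neutral(),
                            seed = config$seed) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genome, "synthetic_genome"),
            inherits(cn, "cn_profile"))
  ev <- cn$events
  if (nrow(ev)) {
    bad <- !(ev$chrom %in% genome$chroms) |
      ev$end > genome$chrom_lengths[ev$chrom]
    if (any(bad))
      stop("cn event beyond genome bounds: ",
           paste(ev$chrom[bad], collapse = ", "))
  }
  bins <- genome$bins
  copies <- bin_tumor_copies(bins, cn)
  gc_w <- 1 + config$gc_bias_slope * (bins$gc - mean(bins$gc))
  gc_w <- pmax(gc_w, 0)
  w_bg <- bins$mappability * gc_w
  w_tm <- bins$mappability * (copies / 2) * gc_w
  tf <- config$tumor_fraction
  if (sum(w_bg) * (1 - tf) + sum(w_tm) * tf <= 0)
    stop("zero total placement weight")
  n <- config$n_fragments
  dens_bg <- length_density(config, tumor_fraction = 0)
  dens_tm <- length_density(config, tumor_fraction = 1)
  chrom_levels <- genome$chroms
  out <- withr::with_seed(as.integer(seed), {
    is_tumor <- runif(n) < tf
    n_tm <- sum(is_tumor)
    len <- integer(n)
    if (n - n_tm > 0) len[!is_tumor] <- draw_lengths(dens_bg, n - n_tm)
    if (n_tm > 0) len[is_tumor] <- draw_lengths(dens_tm, n_tm)
    bin_idx <- integer(n)
    if (n - n_tm > 0)
      bin_idx[!is_tumor] <- sample.int(nrow(bins), n - n_tm, replace = TRUE,
                                       prob = w_bg)
    if (n_tm > 0)
      bin_idx[is_tumor] <- sample.int(nrow(bins), n_tm, replace = TRUE,
                                      prob = w_tm)
    width <- bins$end[bin_idx] - bins$start[bin_idx]
    start <- bins$start[bin_idx] + floor(runif(n) * width)
    chrom <- bins$chrom[bin_idx]
    # keep fragments inside the chromosome
    start <- pmax(0, pmin(start, genome$chrom_lengths[chrom] - len))
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + len), length = as.integer(len))
  })
  ord <- order(match(out$chrom, chrom_levels), out$start, out$end)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of cfDNA samples
#'
#' Generates one fragment set per configuration, with per-sample random
#' streams derived from the single global `seed` by stable counter-based
#' splitting (sample `i` uses seed `(seed + 104729 * i) mod (2^31 - 1)`), so
#' results do not depend on generation order.
#'
#' @param configs list of [sim_config()] objects (length >= 2).
#' @param genome a [synthetic_genome()] shared by all samples.
#' @param cn_profiles a single [cn_profile()] shared by all samples, or a
#'   list of profiles, one per sample.
#' @param seed global cohort seed.
#' @param sample_ids optional character sample names.
#' @return List with `samples` (named list of fragment data frames), `truth`
#'   (data frame recording each sample's tumor fraction, fragment count,
#'   oscillation amplitudes, number of CN events and derived seed),
#'   `configs`, and `cn_profiles`.
#' @export
simulate_cohort <- function(configs, genome, cn_profiles = cn_neutral(),
                            seed = 1L, sample_ids = NULL) {
  if (!is.list(configs) || length(configs) < 2L)
    stop("cohort spec must contain at least 2 samples")
  n <- length(configs)
  if (inherits(cn_profiles, "cn_profile"))
    cn_profiles <- rep(list(cn_profiles), n)
  stopifnot(length(cn_profiles) == n)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n))
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    samples[[i]] <- simulate_sample(configs[[i]], genome, cn_profiles[[i]],
                                    seed = seeds[i])
  }
  names(samples) <- sample_ids
  names(cn_profiles) <- sample_ids
  truth <- data.frame(
    sample_id = sample_ids,
    tumor_fraction = vapply(configs, `[[`, numeric(1), "tumor_fraction"),
    n_fragments = vapply(configs, `[[`, numeric(1), "n_fragments"),
    osc_amp_bg = vapply(configs, `[[`, numeric(1), "osc_amp_bg"),
    osc_amp_tumor = vapply(configs, `[[`, numeric(1), "osc_amp_tumor"),
    n_cn_events = vapply(cn_profiles, function(p) nrow(p$events), numeric(1)),
    seed = seeds
  )
  rownames(truth) <- NULL
  list(samples = samples, truth = truth, configs = configs,
       cn_profiles = cn_profiles)
}

#' Default cohort specification
#'
#' Builds the configurations for an n-sample synthetic cohort emulating a
#' CSF glioma series: tumor fractions drawn from `{0, 0.05, 0.1, 0.2, 0.4}`
#' and a shared glioma-like copy-number profile (chr7 gain, chr10 loss).
#'
#' @param n_samples cohort size (default 13).
#' @param genome a [synthetic_genome()].
#' @param tumor_fractions optional explicit tumor fractions (length
#'   `n_samples`); drawn randomly when `NULL`.
#' @param n_fragments fragments per sample.
#' @param seed seed for the tumor-fraction draw.
#' @param ... further arguments passed to [sim_config()].
#' @return List with `configs` and `cn` ready for [simulate_cohort()].
#' @export
cohort_spec <- function(n_samples = 13, genome,
                        tumor_fractions = NULL,
                        n_fragments = 200000, seed = 1L, ...) {
  stopifnot(n_samples >= 2)
  if (is.null(tumor_fractions)) {
    tumor_fractions <- withr::with_seed(as.integer(seed),
      sample(c(0, 0.05, 0.1, 0.2, 0.4), n_samples, replace = TRUE))
  }
  stopifnot(length(tumor_fractions) == n_samples)
  configs <- lapply(tumor_fractions, function(tf)
    sim_config(n_fragments = n_fragments, tumor_fraction = tf, ...))
  list(configs = configs, cn = glioma_cn_profile(genome))
}
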