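test_that("binning tiles chromosomes with a truncated last bin", {
  b1 <- make_bins(c(chrA = 90000), 30000)
  expect_identical(nrow(b1), 3L)
  expect_equal(b1$end - b1$start, rep(30000, 3))

  b2 <- make_bins(c(chrA = 95000), 30000)
  expect_identical(nrow(b2), 4L)
  expect_equal(b2$end[4] - b2$start[4], 5000)

  g <- synthetic_genome()
  expect_identical(nrow(g$bins), 2200L)
  expect_error(make_bins(numeric(0)), "empty genome")
  expect_error(make_bins(c(chrA = 1e5), 10), "bin_size")
})

test_that("fragments are assigned to bins by start coordinate, half-open", {
  bins <- make_bins(c(chr1 = 90000), 30000)
  recs <- frag_df("chr1", c(29999, 30000, 0, 89999), 100)
  counts <- count_in_bins(recs, bins)
  expect_identical(as.integer(counts), c(2L, 1L, 1L))

  # unknown chromosomes and starts beyond the last bin are reported
  recs2 <- frag_df(c("chrX", "chr1"), c(100, 95000), 100)
  counts2 <- count_in_bins(recs2, bins)
  expect_identical(sum(counts2), 0L)
  expect_identical(attr(counts2, "unassigned"), 2L)
})

test_that("bin counts equal a brute-force interval tally", {
  g <- synthetic_genome(n_chrom = 3)
  fr <- simulate_sample(sim_config(n_fragments = 2e4), g, seed = 13)
  counts <- count_in_bins(fr, g$bins)
  brute <- vapply(seq_len(nrow(g$bins)), function(i) {
    sum(fr$chrom == g$bins$chrom[i] &
          fr$start >= g$bins$start[i] & fr$start < g$bins$end[i])
  }, numeric(1))
  expect_equal(as.integer(counts), as.integer(brute))
  expect_identical(sum(counts) + attr(counts, "unassigned"), nrow(fr))
})

test_that("stratified correction is a near-identity without bias", {
  withr::local_seed(41)
  n <- 500
  raw <- rpois(n, 200)
  gc <- rbeta(n, 41, 59)
  corrected <- suppressWarnings(correct_counts(raw, gc, rep(1, n)))
  expect_true(all(abs(corrected / raw - 1) < 0.25, na.rm = TRUE))
  # total mass conserved within 5%
  expect_lt(abs(sum(corrected) / sum(raw) - 1), 0.05)
})

test_that("correction removes an injected linear GC bias", {
  g <- synthetic_genome(blacklist_frac = 0)
  cfg <- sim_config(n_fragments = 5e5, tumor_fraction = 0, gc_bias_slope = 0.5)
  fr <- simulate_sample(cfg, g, seed = 19)
  raw <- count_in_bins(fr, g$bins)
  expect_gt(abs(cor(as.numeric(raw), g$bins$gc)), 0.15)  # bias present
  corrected <- suppressWarnings(
    correct_counts(raw, g$bins$gc, g$bins$mappability))
  expect_lt(abs(cor(corrected, g$bins$gc)), 0.1)
})

test_that("blacklisted bins are excluded from correction and log2r", {
  withr::local_seed(43)
  n <- 300
  raw <- rpois(n, 100)
  bl <- rep(FALSE, n); bl[c(5, 50)] <- TRUE
  corrected <- suppressWarnings(correct_counts(raw, rbeta(n, 41, 59),
                                               rep(1, n), blacklisted = bl))
  expect_true(all(is.na(corrected[c(5, 50)])))
  l2r <- to_log2r(corrected)
  expect_true(all(is.na(l2r[c(5, 50)])))
  expect_error(suppressWarnings(
    correct_counts(rpois(50, 100), runif(50), rep(1, 50))), "100")
})

test_that("log2 ratios are median-normalized with zero-count bins flagged", {
  expect_equal(to_log2r(rep(7, 10)), rep(0, 10))
  x <- c(rep(100, 11), 200)
  expect_lt(abs(to_log2r(x)[12] - 1), 0.01)
  withzero <- c(rep(100, 10), 0)
  l <- to_log2r(withzero)
  expect_true(is.na(l[11]))
  expect_false(any(is.infinite(l)))
  expect_error(to_log2r(rep(0, 5)), "zero")

  # delta method: Poisson(100) counts give SD(log2r) ~ 1/(ln 2 * 10)
  withr::local_seed(47)
  l2 <- to_log2r(rpois(3000, 100))
  expect_equal(median(l2), 0)
  expect_lt(abs(sd(l2) - 0.1443), 0.2 * 0.1443)
})

test_that("CBS returns one segment for flat input and finds clean breakpoints", {
  flat <- segment_cbs(rep(0.3, 50))
  expect_identical(nrow(flat$segments), 1L)
  expect_equal(flat$segments$mean, 0.3)

  withr::local_seed(53)
  x <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1))
  seg <- segment_cbs(x, seed = 3)
  expect_identical(nrow(seg$segments), 2L)
  expect_lte(abs(seg$segments$end_bin[1] - 50), 1)
})

test_that("the CBS split point equals the brute-force max-|t| location", {
  withr::local_seed(59)
  for (i in 1:40) {
    n <- sample(8:20, 1)
    x <- rnorm(n, 0, 0.2) + c(rep(0, 7), rep(0.8, n - 7))
    or <- oracle_best_split(x)
    bs <- csffrag:::best_split(x)
    expect_identical(bs$k, or$k)
    expect_equal(bs$stat, or$t, tolerance = 1e-10)
    # when the split is accepted end-to-end it lands at the same place
    seg <- segment_cbs(x, seed = i)
    if (nrow(seg$segments) == 2)
      expect_identical(seg$segments$end_bin[1], or$k)
  }
})

test_that("noiseless piecewise-constant signals are segmented exactly", {
  x <- rep(c(0, 1, 0), times = c(20, 15, 25))
  cbs <- segment_cbs(x, seed = 1)
  expect_equal(cbs$segments$n_bins, c(20, 15, 25))
  expect_equal(cbs$segments$mean, c(0, 1, 0))
  hmm <- segment_hmm(rep(c(0, 0.4, 0), times = c(20, 15, 25)))
  expect_equal(hmm$segments$n_bins, c(20, 15, 25))
  expect_identical(hmm$segments$state, c("neutral", "gain", "neutral"))
})

test_that("the HMM decodes states as designed", {
  all0 <- segment_hmm(rep(0, 40))
  expect_identical(nrow(all0$segments), 1L)
  expect_identical(all0$segments$state, "neutral")

  withr::local_seed(61)
  x <- c(rnorm(30, 0, 0.1), rnorm(30, 0.4, 0.1), rnorm(30, 0, 0.1))
  seg <- segment_hmm(x)
  gain <- seg$segments[seg$segments$state == "gain", ]
  expect_identical(nrow(gain), 1L)
  expect_lte(abs(gain$start_bin - 31), 1)
  expect_lte(abs(gain$end_bin - 60), 1)
})

test_that("Viterbi equals exhaustive path enumeration on small instances", {
  means <- c(-0.5, 0, 0.4)
  withr::local_seed(67)
  for (i in 1:30) {
    x <- rnorm(8, sample(c(-0.5, 0, 0.4), 8, replace = TRUE), 0.25)
    sd_hat <- sqrt(max(mean((x - median(x))^2), 1e-4))
    got <- csffrag:::viterbi_gauss(x, means, sd_hat, 1e-3)
    expect_identical(as.integer(got),
                     as.integer(oracle_viterbi(x, means, sd_hat, 1e-3)))
  }
})

test_that("consensus is the per-bin mean of both segmentations", {
  x <- rep(0, 30)
  cbs <- segment_cbs(x)
  hmm <- segment_hmm(c(rep(0, 10), rep(0.4, 10), rep(0, 10)))
  cons <- consensus_log2r(cbs, hmm)
  expect_equal(cons[15], 0.2)
  expect_equal(cons[1], 0)

  withr::local_seed(71)
  y <- rnorm(40, 0, 0.2)
  c2 <- segment_cbs(y, seed = 2); h2 <- segment_hmm(y)
  expect_equal(consensus_log2r(c2, h2), (c2$binmean + h2$binmean) / 2)
  # a consensus value always lies between its two sources
  expect_true(all(consensus_log2r(c2, h2) >= pmin(c2$binmean, h2$binmean) &
                    consensus_log2r(c2, h2) <= pmax(c2$binmean, h2$binmean)))

  bad <- segment_cbs(c(NA, y[-1]))
  expect_error(consensus_log2r(bad, h2), "partition")
})

test_that("gene calls follow the declared thresholds", {
  bins <- make_bins(c(chr1 = 150000), 30000)
  genes <- data.frame(chrom = "chr1", start = c(0, 60000, 120000),
                      end = c(60000, 120000, 150000),
                      name = c("GAIN", "FLAT", "LOST"))
  cons <- c(0.2, 0.2, 0, 0, -0.2)
  calls <- call_genes(bins, cons, genes)
  expect_identical(calls$state, c("amplification", "neutral", "deletion"))
  expect_equal(attr(calls, "thresholds"), c(amp = 0.15, del = -0.15))

  cons_na <- c(NA, NA, 0, 0, 0)
  calls2 <- call_genes(bins, cons_na, genes)
  expect_identical(calls2$state[1], "no-data")
})

test_that("mean SCNA is the mean absolute consensus log2 ratio", {
  expect_equal(mean_scna(rep(0, 100)), 0)
  expect_equal(mean_scna(c(rep(0.4, 50), rep(0, 50))), 0.2)
  expect_equal(mean_scna(c(NA, 0.3, -0.3)), 0.3)
  expect_error(mean_scna(c(NA_real_, NA_real_)), "usable")
})

test_that("whole-chromosome events are detected above the threshold-implied tumor fraction", {
  # +/-0.15 log2 call thresholds imply detectability of single-copy events
  # from tf ~ 0.23 (gain) / ~ 0.20 (loss); verified at tf = 0.25, with a
  # clean negative control at tf = 0
  g <- synthetic_genome()
  genes <- glioma_genes(g)
  for (s in 1:2) {
    fr <- simulate_sample(sim_config(n_fragments = 1e6, tumor_fraction = 0.25),
                          g, glioma_cn_profile(g), seed = 200 + s)
    res <- scna_analysis(fr, g, genes = genes, seed = s)
    calls <- res$gene_calls
    expect_identical(calls$state[calls$gene == "EGFR"], "amplification")
    expect_identical(calls$state[calls$gene == "PTEN"], "deletion")

    fr0 <- simulate_sample(sim_config(n_fragments = 1e6, tumor_fraction = 0),
                           g, glioma_cn_profile(g), seed = 300 + s)
    res0 <- scna_analysis(fr0, g, genes = genes, seed = s)
    expect_true(all(res0$gene_calls$state == "neutral"))
    expect_gt(res$mean_scna, res0$mean_scna)
  }
})
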