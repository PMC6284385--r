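test_that("monotone densities yield no interior extrema", {
  d <- seq(1, 2, length.out = 80)  # strictly increasing on [73, 152]
  p <- csffrag:::profile_from_density(d, c(73, 152))
  ex <- find_local_extrema(p)
  expect_length(ex$maxima, 0)
  expect_length(ex$minima, 0)
})

test_that("exact ties disqualify all tied positions", {
  d <- rep(1, 80)
  d[100 - 73 + 1] <- 2
  d[101 - 73 + 1] <- 2  # plateau of two equal values
  p <- csffrag:::profile_from_density(d, c(73, 152))
  ex <- find_local_extrema(p)
  expect_false(100 %in% ex$maxima)
  expect_false(101 %in% ex$minima)
  # flat baseline produces no extrema at all outside the plateau
  expect_length(ex$maxima, 0)
})

test_that("extremum finder agrees with the exhaustive window-scan oracle", {
  withr::local_seed(17)
  for (i in 1:300) {
    counts <- sample(0:30, 80, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    p <- size_histogram(rep(73:152, counts), range = c(73, 152))
    ex <- find_local_extrema(p)
    or <- oracle_extrema(p$density, 73)
    expect_identical(ex$maxima, or$maxima)
    expect_identical(ex$minima, or$minima)
  }
})

test_that("extrema search demands a fully covered window", {
  p <- size_histogram(rep(100, 5), range = c(76, 152))
  expect_error(find_local_extrema(p), "cover")
})

test_that("clear-peaks qualification finds the 10 bp comb and rejects flat profiles", {
  comb <- comb_profile(c(81, 92, 102, 112, 122, 134, 144))
  ex <- find_local_extrema(comb)
  expect_true(has_clear_peaks(ex))
  flat <- csffrag:::profile_from_density(rep(1, 651), c(50, 700))
  expect_false(has_clear_peaks(find_local_extrema(flat)))
  # stray maxima outside the comb do not disqualify a sample
  comb2 <- comb_profile(c(77, 102, 112, 122, 134, 144))
  expect_true(has_clear_peaks(find_local_extrema(comb2)))
})

test_that("position averaging clusters and rounds as specified", {
  comb <- comb_profile(c(81, 92, 102, 112, 122, 134, 144))
  ex <- find_local_extrema(comb)
  avg <- average_extrema_positions(list(ex))
  expect_identical(avg$mean_maxima, ex$maxima)
  expect_identical(avg$n_samples_used, 1L)

  # two single-peak samples average to the midpoint (qualification waived)
  mk <- function(center) find_local_extrema(comb_profile(center))
  avg2 <- average_extrema_positions(list(mk(100), mk(102)),
                                    require_clear_peaks = FALSE)
  expect_identical(avg2$mean_maxima, 101L)

  # a cluster present in 1 of 3 samples fails min_support = 0.5
  avg3 <- average_extrema_positions(list(mk(100), mk(100), mk(140)),
                                    require_clear_peaks = FALSE)
  expect_identical(avg3$mean_maxima, 100L)

  flat <- csffrag:::profile_from_density(rep(1, 651), c(50, 700))
  expect_error(average_extrema_positions(list(find_local_extrema(flat))),
               "no qualifying samples")
})

test_that("averaged positions from simulated background samples match the analytic comb", {
  cfg <- sim_config(tumor_fraction = 0)
  d <- oracle_density(cfg, 0)
  ana <- oracle_extrema(d$density, 50)
  sets <- lapply(1:5, function(s) {
    l <- sample_fragment_lengths(cfg, 5e5, seed = 100 + s)
    find_local_extrema(size_histogram(l))
  })
  avg <- average_extrema_positions(sets)
  # every consensus maximum sits within 1 bp of an analytic comb position
  for (m in avg$mean_maxima)
    expect_lte(min(abs(ana$maxima - m)), 1)
  expect_gte(length(avg$mean_maxima), 5)
})

test_that("amplitude statistic is the sum-of-heights difference", {
  unif <- csffrag:::profile_from_density(rep(1, 651), c(50, 700))
  fake <- structure(list(mean_maxima = c(81, 92, 102, 112, 122, 134, 144),
                         mean_minima = c(84, 96, 106, 116, 126, 137, 148),
                         n_samples_used = 1L), class = "averaged_extrema")
  a0 <- amplitude_statistic(unif, fake)
  expect_equal(a0$value, 0)

  d <- rep(0.01, 651)
  d[fake$mean_maxima - 50 + 1] <- 0.02
  d[fake$mean_minima - 50 + 1] <- 0.01
  prof <- structure(list(range = c(50L, 700L), sizes = 50:700, counts = NULL,
                         density = d, n = NA_integer_, n_out_of_range = 0L,
                         n_samples = NULL), class = "size_profile")
  a <- amplitude_statistic(prof, fake)
  expect_equal(a$value, 7 * 0.02 - 7 * 0.01)
  expect_equal(a$value, a$maxima_height_sum - a$minima_height_sum)

  out <- structure(list(mean_maxima = 40L, mean_minima = integer(0),
                        n_samples_used = 1L), class = "averaged_extrema")
  expect_error(amplitude_statistic(prof, out), "outside")
})

test_that("amplitude is invariant to count rescaling", {
  withr::local_seed(23)
  counts <- sample(10:500, 651, replace = TRUE)
  p1 <- size_histogram(rep(50:700, counts), range = c(50, 700))
  p2 <- size_histogram(rep(50:700, counts * 7), range = c(50, 700))
  ex <- find_local_extrema(p1)
  avg <- average_extrema_positions(list(ex), require_clear_peaks = FALSE)
  expect_equal(amplitude_statistic(p1, avg)$value,
               amplitude_statistic(p2, avg)$value)
})

test_that("maxima and minima interleave on profiles with strict extrema", {
  cfg <- sim_config()
  d <- length_density(cfg, 0)
  p <- csffrag:::profile_from_density(d$density, cfg$length_range)
  ex <- find_local_extrema(p)
  expect_gte(length(ex$maxima), 5)
  for (i in seq_len(length(ex$maxima) - 1)) {
    between <- ex$minima > ex$maxima[i] & ex$minima < ex$maxima[i + 1]
    expect_gte(sum(between), 1)
  }
})

test_that("the analytic amplitude decreases continuously with tumor fraction", {
  cfg <- sim_config()
  tf <- seq(0, 1, by = 0.1)
  A <- vapply(tf, function(t) analytic_amplitude(cfg, t), numeric(1))
  expect_true(all(diff(A) < 0))
  # linear in tf at fixed positions: continuity check
  expect_lt(max(abs(diff(diff(A)))), 1e-12)
})
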