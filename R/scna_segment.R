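# ---- circular binary segmentation (max-|t| recursive splitting) ----

# pooled-variance t statistics for every admissible split of x
# (each arm >= 2 bins); NULL when x is too short to split
split_t_stats <- function(x) {
  n <- length(x)
  if (n < 4) return(NULL)
  k <- 2:(n - 2)
  if (!length(k)) return(NULL)
  S <- cumsum(x); Q <- cumsum(x^2)
  Sn <- S[n]; Qn <- Q[n]
  m1 <- S[k] / k
  m2 <- (Sn - S[k]) / (n - k)
  sse <- (Q[k] - S[k]^2 / k) + ((Qn - Q[k]) - (Sn - S[k])^2 / (n - k))
  sse <- pmax(sse, 0)  # guard tiny negative rounding
  se <- sqrt(sse / (n - 2) * (1 / k + 1 / (n - k)))
  t <- (m1 - m2) / se
  t[is.nan(t)] <- 0  # 0/0: no mean difference, no split evidence
  list(k = k, t = t)
}

best_split <- function(x) {
  st <- split_t_stats(x)
  if (is.null(st)) return(NULL)
  i <- which.max(abs(st$t))
  list(k = st$k[i], stat = abs(st$t[i]))
}

# permutation p-value of the max-|t| statistic with early stopping once the
# exceedance count already forces p >= alpha
cbs_perm_pvalue <- function(x, obs, n_perm, alpha, block = 100L) {
  limit <- floor(alpha * (n_perm + 1))
  exceed <- 0L
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    for (j in seq_len(b)) {
      bs <- best_split(sample(x))
      if (!is.null(bs) && bs$stat >= obs) exceed <- exceed + 1L
    }
    done <- done + b
    if (exceed >= limit && limit > 0) break
  }
  (1 + exceed) / (1 + n_perm)
}

cbs_chrom <- function(x, alpha, n_perm) {
  rec <- function(lo, hi) {
    xx <- x[lo:hi]
    bs <- best_split(xx)
    if (is.null(bs) || bs$stat == 0)
      return(data.frame(lo = lo, hi = hi))
    p <- cbs_perm_pvalue(xx, bs$stat, n_perm, alpha)
    if (p >= alpha) return(data.frame(lo = lo, hi = hi))
    rbind(rec(lo, lo + bs$k - 1L), rec(lo + bs$k, hi))
  }
  rec(1L, length(x))
}

# normalize segmentation input: binned_profile or bare log2r vector
as_seg_input <- function(x, chrom) {
  if (inherits(x, "binned_profile")) {
    list(log2r = x$log2r, chrom = x$chrom, start = x$start, end = x$end)
  } else {
    stopifnot(is.numeric(x))
    if (is.null(chrom)) chrom <- rep("chr1", length(x))
    idx <- seq_along(x)
    list(log2r = as.numeric(x), chrom = chrom, start = idx - 1L, end = idx)
  }
}

segment_generic <- function(inp, per_chrom_fun, source) {
  usable <- !is.na(inp$log2r)
  binmean <- rep(NA_real_, length(inp$log2r))
  seg_rows <- list()
  for (ch in unique(inp$chrom)) {
    u <- which(inp$chrom == ch & usable)
    if (!length(u)) next
    x <- inp$log2r[u]
    parts <- per_chrom_fun(x)
    for (r in seq_len(nrow(parts))) {
      idx <- u[parts$lo[r]:parts$hi[r]]
      m <- mean(inp$log2r[idx])
      binmean[idx] <- m
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        chrom = ch, start = inp$start[idx[1]], end = inp$end[idx[length(idx)]],
        start_bin = idx[1], end_bin = idx[length(idx)],
        n_bins = length(idx), mean = m, source = source)
    }
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  structure(list(segments = segments, binmean = binmean, source = source),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set (%s): %d segments over %d usable bins\n",
              x$source, nrow(x$segments), sum(!is.na(x$binmean))))
  invisible(x)
}

#' Circular binary segmentation of log2 copy-number ratios
#'
#' Recursive change-point detection per chromosome: at each step the split
#' maximizing the absolute pooled-variance t statistic between the two
#' candidate arms (each at least 2 bins) is tested against `n_perm`
#' permutations of the segment's bins and accepted iff the permutation
#' p-value is below `alpha`; the procedure recurses into accepted arms.
#' Segment means are the mean log2 ratio of member bins. A constant segment
#' yields no split.
#'
#' @param x a `binned_profile` or a numeric log2-ratio vector (`NA` =
#'   unusable bin).
#' @param chrom chromosome labels when `x` is a bare vector (default: a
#'   single chromosome).
#' @param alpha significance level of the permutation test.
#' @param n_perm number of permutations.
#' @param seed integer seed making the permutation test reproducible.
#' @return A `segment_set`: list with `segments` (data frame `chrom`,
#'   `start`, `end`, `start_bin`, `end_bin`, `n_bins`, `mean`, `source`) and
#'   `binmean` (per-bin segment mean, `NA` for unusable bins).
#' @export
segment_cbs <- function(x, chrom = NULL, alpha = 0.01, n_perm = 1000,
                        seed = 1L) {
  inp <- as_seg_input(x, chrom)
  withr::with_seed(as.integer(seed),
    segment_generic(inp, function(v) cbs_chrom(v, alpha, n_perm), "cbs"))
}

# ---- 3-state Gaussian HMM segmentation (Viterbi) ----

viterbi_gauss <- function(x, means, sd, eps) {
  n <- length(x)
  K <- length(means)
  emis <- vapply(means, function(m) dnorm(x, m, sd, log = TRUE), numeric(n))
  emis <- matrix(emis, nrow = n, ncol = K)
  logA <- matrix(log(eps), K, K)
  diag(logA) <- log(1 - (K - 1) * eps)
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1, ] <- log(1 / K) + emis[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in seq_len(K)) {
        cand <- delta[t - 1, ] + logA[, j]
        psi[t, j] <- which.max(cand)
        delta[t, j] <- cand[psi[t, j]] + emis[t, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Hidden Markov model segmentation of log2 copy-number ratios
#'
#' Three-state Gaussian HMM (loss / neutral / gain) with fixed state means, a
#' shared emission variance estimated by method of moments from the
#' median-centered data (floored at `var_floor`), symmetric transition
#' probability `epsilon` and uniform initial state probabilities. The Viterbi
#' path is computed per chromosome and runs of equal state become segments;
#' segment means are the empirical mean log2 ratio of member bins.
#'
#' @inheritParams segment_cbs
#' @param state_means fixed emission means of the loss/neutral/gain states.
#' @param epsilon symmetric state-switch probability.
#' @param var_floor lower bound of the shared emission variance.
#' @param seed accepted for interface symmetry; the algorithm is
#'   deterministic.
#' @return A `segment_set` with `source = "hmm"`; segments additionally carry
#'   a `state` column.
#' @export
segment_hmm <- function(x, chrom = NULL, state_means = c(-0.5, 0, 0.4),
                        epsilon = 1e-3, var_floor = 1e-4, seed = 1L) {
  inp <- as_seg_input(x, chrom)
  usable <- !is.na(inp$log2r)
  z <- inp$log2r[usable]
  v <- max(mean((z - median(z))^2), var_floor)
  sd_hat <- sqrt(v)
  state_names <- c("loss", "neutral", "gain")[order(order(state_means))]
  res <- segment_generic(inp, function(vv) {
    path <- viterbi_gauss(vv, state_means, sd_hat, epsilon)
    r <- rle(path)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    data.frame(lo = lo, hi = hi, state = r$values)
  }, "hmm")
  # annotate states onto segments (segment_generic preserved row order)
  states <- integer(0)
  for (ch in unique(inp$chrom)) {
    u <- which(inp$chrom == ch & usable)
    if (!length(u)) next
    path <- viterbi_gauss(inp$log2r[u], state_means, sd_hat, epsilon)
    states <- c(states, rle(path)$values)
  }
  res$segments$state <- state_names[states]
  res$sd <- sd_hat
  res
}

#' Per-bin consensus log2 ratio of two segmentations
#'
#' The averaged log2 ratio per bin: the mean of the CBS segment mean and the
#' HMM segment mean covering each usable bin.
#'
#' @param cbs,hmm `segment_set` objects over the same bins.
#' @return Numeric vector of per-bin consensus log2 ratios (`NA` for
#'   unusable bins).
#' @export
consensus_log2r <- function(cbs, hmm) {
  stopifnot(inherits(cbs, "segment_set"), inherits(hmm, "segment_set"))
  if (length(cbs$binmean) != length(hmm$binmean) ||
      !identical(is.na(cbs$binmean), is.na(hmm$binmean)))
    stop("segmentations do not partition the same usable bins")
  (cbs$binmean + hmm$binmean) / 2
}

#' Gene-level copy-number calls
#'
#' Averages the consensus log2 ratio over the usable bins overlapping each
#' gene/region and thresholds it: `amplification` if the mean is at least
#' `amp_thresh`, `deletion` if at most `del_thresh`, otherwise `neutral`;
#' regions with no usable bin are called `no-data`. Thresholds are recorded
#' in the `"thresholds"` attribute.
#'
#' @param bins bin table (`chrom`, `start`, `end`), e.g. a `binned_profile`.
#' @param consensus per-bin consensus log2 ratios from [consensus_log2r()].
#' @param genes BED-like data frame (`chrom`, `start`, `end`, `name`).
#' @param amp_thresh,del_thresh log2-ratio call thresholds.
#' @return Data frame with `gene`, `chrom`, `start`, `end`, `n_bins`,
#'   `mean_log2r`, `state`.
#' @export
call_genes <- function(bins, consensus, genes,
                       amp_thresh = 0.15, del_thresh = -0.15) {
  stopifnot(length(consensus) == nrow(bins),
            all(c("chrom", "start", "end", "name") %in% names(genes)))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- bins$chrom == genes$chrom[i] &
      bins$start < genes$end[i] & bins$end > genes$start[i] &
      !is.na(consensus)
    if (!any(hit)) {
      return(data.frame(gene = genes$name[i], chrom = genes$chrom[i],
                        start = genes$start[i], end = genes$end[i],
                        n_bins = 0L, mean_log2r = NA_real_, state = "no-data"))
    }
    m <- mean(consensus[hit])
    state <- if (m >= amp_thresh) "amplification"
    else if (m <= del_thresh) "deletion"
    else "neutral"
    data.frame(gene = genes$name[i], chrom = genes$chrom[i],
               start = genes$start[i], end = genes$end[i],
               n_bins = sum(hit), mean_log2r = m, state = state)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(amp = amp_thresh, del = del_thresh)
  out
}

#' Mean somatic copy-number alteration statistic
#'
#' Operationalized as the mean absolute consensus log2 ratio over usable
#' autosomal bins: zero iff the consensus profile is flat at zero, and
#' monotone in both the breadth and the amplitude of alterations.
#'
#' @param consensus per-bin consensus log2 ratios.
#' @return Non-negative numeric scalar.
#' @export
mean_scna <- function(consensus) {
  usable <- !is.na(consensus)
  if (!any(usable)) stop("no usable bins")
  mean(abs(consensus[usable]))
}

#' Full copy-number analysis of one sample
#'
#' Runs the binned sWGS copy-number workflow end to end: bin counts,
#' GC/mappability correction with blacklist exclusion, median-normalized
#' log2 ratios, CBS and HMM segmentation, per-bin consensus, the mean-SCNA
#' statistic, and (optionally) gene-level calls.
#'
#' @inheritParams bin_profile
#' @inheritParams segment_cbs
#' @inheritParams segment_hmm
#' @param genes optional BED-like gene table for [call_genes()].
#' @param amp_thresh,del_thresh gene-call thresholds.
#' @return Object of class `scna_result`: list with `bins`
#'   (`binned_profile`), `cbs`, `hmm` (`segment_set`s), `consensus`
#'   (per-bin), `mean_scna`, and `gene_calls` (or `NULL`).
#' @export
scna_analysis <- function(fragments, genome, genes = NULL,
                          blacklist = genome$blacklist,
                          alpha = 0.01, n_perm = 1000,
                          state_means = c(-0.5, 0, 0.4),
                          amp_thresh = 0.15, del_thresh = -0.15,
                          seed = 1L) {
  bins <- bin_profile(fragments, genome, blacklist)
  cbs <- segment_cbs(bins, alpha = alpha, n_perm = n_perm, seed = seed)
  hmm <- segment_hmm(bins, state_means = state_means)
  cons <- consensus_log2r(cbs, hmm)
  calls <- if (!is.null(genes))
    call_genes(bins, cons, genes, amp_thresh, del_thresh)
  structure(list(bins = bins, cbs = cbs, hmm = hmm, consensus = cons,
                 mean_scna = mean_scna(cons), gene_calls = calls),
            class = "scna_result")
}

#' @export
print.scna_result <- function(x, ...) {
  cat(sprintf("scna_result: %d usable bins, %d CBS + %d HMM segments, mean SCNA = %.4f\n",
              sum(x$bins$usable), nrow(x$cbs$segments), nrow(x$hmm$segments),
              x$mean_scna))
  if (!is.null(x$gene_calls)) {
    alt <- x$gene_calls[x$gene_calls$state %in% c("amplification", "deletion"), ]
    cat(sprintf("  gene calls: %d altered of %d\n", nrow(alt),
                nrow(x$gene_calls)))
  }
  invisible(x)
}

#' Write segments in SEG format
#'
#' Standard tab-separated SEG layout (`ID, chrom, loc.start, loc.end,
#' num.mark, seg.mean`) consumable by genome browsers.
#'
#' @param segset a `segment_set`.
#' @param path output file.
#' @param sample_id identifier written in the first column.
#' @export
write_seg <- function(segset, path, sample_id = "sample") {
  stopifnot(inherits(segset, "segment_set"))
  s <- segset$segments
  out <- data.frame(ID = sample_id, chrom = s$chrom, loc.start = s$start,
                    loc.end = s$end, num.mark = s$n_bins,
                    seg.mean = round(s$mean, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
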