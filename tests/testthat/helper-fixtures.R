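# Shared fixtures built in code at test time.

# standard-error of a trace mean from 1 s chunk means (handles the
# autocorrelation of shot noise without assuming Poisson statistics)
chunk_se <- function(trace, burn_in = 1, chunk_s = 1) {
  i0 <- round(burn_in / trace$dt) + 1L
  v <- trace$values[i0:length(trace$values)]
  per <- round(chunk_s / trace$dt)
  n <- floor(length(v) / per)
  m <- colMeans(matrix(v[seq_len(n * per)], nrow = per))
  stats::sd(m) / sqrt(n)
}

# all-pairs brute-force correlogram oracle (independent of the
# findInterval-based implementation); mirrors the centered binning and
# the edge rule of cross_correlogram()
brute_correlogram_counts <- function(ref, target, window = 20, bin = 0.1) {
  half_s <- window / 2 * 1e-3
  bin_s <- bin * 1e-3
  ref_u <- ref$times[ref$times >= half_s & ref$times <= ref$duration - half_s]
  n_bins <- round(window / bin) + 1L
  counts <- integer(n_bins)
  for (r in ref_u) {
    for (t in target$times) {
      lag <- t - r
      if (lag >= -half_s && lag <= half_s) {
        b <- floor((lag + half_s + bin_s / 2) / bin_s) + 1L
        if (b >= 1L && b <= n_bins) counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

# hand-built correlogram object for metric-convention checks
make_correlogram <- function(lag_ms, rate, bin = 0.1,
                             baseline_window = c(-10, -5)) {
  base_idx <- lag_ms >= baseline_window[1] & lag_ms <= baseline_window[2]
  structure(list(lag_ms = lag_ms, rate = rate, prob = rate * bin * 1e-3,
                 counts = NA, n_ref = 1L, baseline = mean(rate[base_idx]),
                 baseline_window = baseline_window, bin = bin,
                 window = diff(range(lag_ms))),
            class = "correlogram")
}

# depth and full width at half depth of the pre-spike dip of a
# spike-triggered-average conductance
sta_dip <- function(sta) {
  m <- mean(sta$g[abs(sta$lag_ms) > 7])   # far-lag reference level
  depth <- m - min(sta$g)
  below <- sta$lag_ms[sta$g < m - depth / 2]
  list(depth = depth, width = if (length(below)) diff(range(below)) else 0)
}
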