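test_that("counts are normalized per reference spike and per bin", {
  ref <- spike_train(0.5, 1)
  target <- spike_train(c(0.499, 0.503), 1)
  cc <- cross_correlogram(ref, target, window = 20, bin = 1)
  expect_equal(cc$n_ref, 1)
  expect_equal(cc$rate[cc$lag_ms == -1], 1000)
  expect_equal(cc$rate[cc$lag_ms == 3], 1000)
  expect_equal(sum(cc$rate != 0), 2)
  # identity between the two normalizations
  expect_lt(max(abs(cc$rate * cc$bin * 1e-3 - cc$prob)), 1e-12)
})

test_that("correlogram equals the all-pairs brute force on small trains", {
  for (s in 1:5) {
    set.seed(s)
    ref <- spike_train(sort(runif(40, 0, 0.5)), 0.5)
    target <- spike_train(sort(runif(50, 0, 0.5)), 0.5)
    cc <- cross_correlogram(ref, target)
    expect_identical(cc$counts, brute_correlogram_counts(ref, target))
  }
})

test_that("empty or unusable reference trains raise errors", {
  t1 <- spike_train(0.5, 1)
  expect_error(cross_correlogram(spike_train(numeric(0), 1), t1), "empty")
  expect_error(cross_correlogram(t1, spike_train(numeric(0), 1)), "empty")
  # reference spike too close to the edges is dropped
  edge <- spike_train(0.001, 1)
  expect_error(cross_correlogram(edge, t1), "edges")
})

test_that("independent Poisson trains give a flat correlogram", {
  ref <- sample_spike_train(isi_poisson_model(80), 120, seed = 1)
  target <- sample_spike_train(isi_poisson_model(50), 120, seed = 2)
  cc <- cross_correlogram(ref, target)
  # every bin is Poisson(n_ref * rate * bin); 3 relative SE bound on the
  # mean over each half
  lam <- cc$n_ref * 50 * 1e-4
  se_half <- sqrt(lam) / (cc$n_ref * 1e-4) / sqrt(sum(cc$lag_ms < 0))
  expect_lt(abs(mean(cc$rate[cc$lag_ms < 0]) - 50), 3 * se_half)
  expect_lt(abs(mean(cc$rate[cc$lag_ms > 0]) - 50), 3 * se_half)
})

test_that("autocorrelogram is symmetric with unit probability at lag 0", {
  tr <- sample_spike_train(isi_lognormal_model(83), 60, seed = 3)
  ac <- autocorrelogram(tr)
  expect_equal(ac$prob[ac$lag_ms == 0], 1)
  # pair lags are exact floating-point negations, so the histogram is
  # symmetric up to rare ties exactly on a bin edge
  expect_lte(sum(abs(ac$counts - rev(ac$counts))), 2L)
})

test_that("refractory trough width shrinks as the firing rate grows", {
  trough_edge <- function(rate, seed) {
    ac <- autocorrelogram(sample_spike_train(isi_lognormal_model(rate),
                                             120, seed = seed))
    off <- ac$lag_ms > 0 & ac$lag_ms < 10
    # first positive lag at which probability recovers to 10% of baseline
    base_prob <- ac$baseline * ac$bin * 1e-3
    ac$lag_ms[off][which(ac$prob[off] >= 0.1 * base_prob)[1]]
  }
  e122 <- trough_edge(122, 4)
  e49 <- trough_edge(49, 5)
  expect_gte(e122, 1.5)   # near-zero probability out to ~1.5 ms at 122 Hz
  expect_gt(e49, e122)
  # Poisson train: flat away from zero, no trough
  ac <- autocorrelogram(sample_spike_train(isi_poisson_model(80), 120,
                                           seed = 6))
  off <- abs(ac$lag_ms) > 0.5
  lam <- ac$n_ref * 80 * 1e-4
  expect_lt(abs(mean(ac$rate[off]) - 80), 3 * 80 / sqrt(lam * sum(off)))
})

test_that("metrics follow the excitation/inhibition/half-decay conventions", {
  lag <- seq(-10, 10, by = 0.1)
  flat <- make_correlogram(lag, rep(100, length(lag)))
  m0 <- correlogram_metrics(flat)
  expect_equal(m0$e, 0)
  expect_equal(m0$i, 0)
  # pre-spike peak 1.61 x baseline -> e = 0.61
  r <- rep(100, length(lag)); r[lag == -1] <- 161
  expect_equal(correlogram_metrics(make_correlogram(lag, r))$e, 0.61)
  # complete post-spike suppression -> i = 1
  r2 <- rep(100, length(lag)); r2[lag >= 0 & lag <= 2] <- 0
  m2 <- correlogram_metrics(make_correlogram(lag, r2))
  expect_equal(m2$i, 1)
  expect_gt(m2$t_half, 0)
  # linear recovery from a trough at 0: trough 0 at lag 0, back to 100
  # at lag 4 -> smoothed half-recovery (50) crossed at lag 2 + O(bin)
  r3 <- rep(100, length(lag))
  ramp <- lag >= 0 & lag <= 4
  r3[ramp] <- 25 * lag[ramp]
  m3 <- correlogram_metrics(make_correlogram(lag, r3))
  expect_equal(m3$t_half, 2, tolerance = 0.15)
  expect_error(correlogram_metrics(make_correlogram(lag, rep(0, length(lag)))),
               "baseline")
})

test_that("rate-code slope is the least-squares gain", {
  expect_equal(rate_code_slope(c(0, 160), c(126, 35)), -0.56875)
  expect_equal(rate_code_slope(c(0, 50, 100), c(80, 80, 80)), 0)
  expect_error(rate_code_slope(5, 5), "two points")
  expect_error(rate_code_slope(c(80, 80), c(10, 20)), "equal")
})

test_that("pause PSTH normalizes by the pre-pause baseline", {
  # stationary Poisson spiking with no pause applied: flat near 1
  tr <- sample_spike_train(isi_poisson_model(60), 200, seed = 7)
  onsets <- periodic_onsets(199, 0.05, start = 1)
  ps <- pause_psth(tr, onsets)
  expect_lt(abs(mean(ps$psth$norm) - 1), 0.05)
  expect_equal(ps$baseline, 60, tolerance = 0.1)
  # constructed transient: extra spikes 3 ms after every onset
  burst <- sort(c(tr$times, onsets + 3e-3))
  tb <- spike_train(burst[burst < 200], 200)
  ps2 <- pause_psth(tb, onsets)
  expect_gt(ps2$peak, 1)
  expect_gt(ps2$peak_time, 0)
  expect_lte(ps2$peak_time, 7)
  # reading the peak at an imposed time
  ps3 <- pause_psth(tb, onsets, peak_time = ps2$peak_time)
  expect_equal(ps3$peak, ps2$peak)
  expect_error(pause_psth(spike_train(190.5, 200), onsets), "baseline")
})
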