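#' Cross-correlogram of two spike trains
#'
#' For every reference spike, target spikes within half the window are
#' binned at their relative lag (centered bins, so lag 0 is a bin
#' center). Two normalizations are carried: \code{rate} =
#' counts/(n_ref * bin width) in spikes/s, and \code{prob} = counts/n_ref
#' (spikes per reference spike per bin); they satisfy
#' \code{rate * bin = prob} exactly. Reference spikes closer than
#' window/2 to either end of the reference train are dropped. The
#' baseline is the mean of the rate variant over
#' \code{baseline_window} lags.
#'
#' @param ref Reference [spike_train()] (e.g. one PC input).
#' @param target Target [spike_train()] (e.g. the CbN neuron).
#' @param window Full window width, ms (lags span +-window/2).
#' @param bin Bin width, ms.
#' @param baseline_window Lag interval (ms) over which the baseline rate
#'   is averaged.
#' @return Object of class \code{correlogram} with fields \code{lag_ms},
#'   \code{rate}, \code{prob}, \code{counts}, \code{n_ref},
#'   \code{baseline}, \code{bin}, \code{window}.
#' @export
cross_correlogram <- function(ref, target, window = 20, bin = 0.1,
                              baseline_window = c(-10, -5)) {
  stopifnot(inherits(ref, "spike_train"), inherits(target, "spike_train"))
  if (!length(ref$times)) stop("reference train is empty")
  if (!length(target$times)) stop("target train is empty")
  half_s <- window / 2 * 1e-3
  bin_s <- bin * 1e-3
  ref_u <- ref$times[ref$times >= half_s & ref$times <= ref$duration - half_s]
  n_ref <- length(ref_u)
  if (!n_ref) stop("no reference spikes at least window/2 from the train edges")
  tgt <- target$times
  lo <- findInterval(ref_u - half_s, tgt)
  hi <- findInterval(ref_u + half_s, tgt)
  n_pair <- hi - lo
  n_bins <- round(window / bin) + 1L
  if (sum(n_pair) > 0) {
    tgt_idx <- sequence(n_pair, from = lo + 1L)
    lags <- tgt[tgt_idx] - rep(ref_u, n_pair)
    b <- floor((lags + half_s + bin_s / 2) / bin_s) + 1L
    b <- b[b >= 1L & b <= n_bins]
    counts <- tabulate(b, nbins = n_bins)
  } else counts <- integer(n_bins)
  lag_ms <- seq(-window / 2, window / 2, by = bin)
  rate <- counts / (n_ref * bin_s)
  base_idx <- lag_ms >= baseline_window[1] & lag_ms <= baseline_window[2]
  structure(list(lag_ms = lag_ms, rate = rate, prob = counts / n_ref,
                 counts = counts, n_ref = n_ref,
                 baseline = mean(rate[base_idx]),
                 baseline_window = baseline_window,
                 bin = bin, window = window),
            class = "correlogram")
}

#' Autocorrelogram of a spike train
#'
#' The cross-correlogram of a train with itself, self-pairs included, so
#' the probability variant equals 1 in the lag-0 bin. Purkinje-cell
#' trains show a central refractory trough whose width shrinks with the
#' firing rate; Poisson trains are flat away from 0.
#'
#' @inheritParams cross_correlogram
#' @param train The [spike_train()].
#' @return A \code{correlogram}.
#' @export
autocorrelogram <- function(train, window = 20, bin = 0.1,
                            baseline_window = c(-10, -5)) {
  cross_correlogram(train, train, window = window, bin = bin,
                    baseline_window = baseline_window)
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf(paste0("Correlogram: +-%.3g ms at %.3g ms bins, %d reference ",
                     "spikes, baseline %.4g spikes/s\n"),
              x$window / 2, x$bin, x$n_ref, x$baseline))
  invisible(x)
}

boxcar3 <- function(v, width = 3L) {
  if (width <= 1L) return(v)
  k <- rep(1 / width, width)
  as.numeric(stats::filter(v, k, sides = 2))
}

#' Excitation, inhibition and half-decay metrics of a correlogram
#'
#' Summary metrics of an input's temporal influence: \code{e}, the
#' fractional rate increase above baseline in the pre-spike window
#' (disinhibition caused by the input's refractory period); \code{i},
#' the fractional rate decrease below baseline in the post-spike window
#' (the inhibition delivered by the input); and \code{t_half}, the lag
#' interval from the post-spike trough until the deficit first recovers
#' to half of (baseline - trough), measured on the rate variant after
#' boxcar smoothing.
#'
#' @param c A \code{correlogram}.
#' @param e_window Pre-spike search window, ms (max is taken over lags in
#'   \code{[e_window[1], e_window[2])}).
#' @param i_window Post-spike search window, ms (min over
#'   \code{[i_window[1], i_window[2]]}).
#' @param smooth_bins Boxcar width (bins) used for the \code{t_half}
#'   crossing.
#' @return List with \code{e}, \code{i}, \code{t_half} (ms),
#'   \code{baseline}, and the window settings.
#' @export
correlogram_metrics <- function(c, e_window = c(-5, 0), i_window = c(0, 5),
                                smooth_bins = 3L) {
  stopifnot(inherits(c, "correlogram"))
  if (!is.finite(c$baseline) || c$baseline <= 0)
    stop("correlogram baseline is undefined or zero")
  lag <- c$lag_ms
  e_idx <- lag >= e_window[1] & lag < e_window[2]
  i_idx <- lag >= i_window[1] & lag <= i_window[2]
  e <- (max(c$rate[e_idx]) - c$baseline) / c$baseline
  trough <- min(c$rate[i_idx])
  i <- (c$baseline - trough) / c$baseline
  sm <- boxcar3(c$rate, smooth_bins)
  sm_i <- sm[i_idx]
  trough_pos <- which.min(sm_i)
  trough_lag <- lag[i_idx][trough_pos]
  half_level <- sm_i[trough_pos] + (c$baseline - sm_i[trough_pos]) / 2
  after <- which(lag > trough_lag & !is.na(sm) & sm >= half_level)
  t_half <- if (i > 0 && length(after))
    lag[after[1L]] - trough_lag else NA_real_
  list(e = e, i = i, t_half = t_half, baseline = c$baseline,
       e_window = e_window, i_window = i_window,
       smooth_bins = smooth_bins)
}

#' Slope of output firing rate versus input firing rate
#'
#' Least-squares slope of CbN output rate against the rate of one swept
#' PC input; the rate-code transfer gain of that input.
#'
#' @param input_rates,output_rates Paired rates, spikes/s (>= 2 points).
#' @return Dimensionless slope.
#' @examples
#' rate_code_slope(c(0, 160), c(126, 35))  # ~ -0.569
#' @export
rate_code_slope <- function(input_rates, output_rates) {
  stopifnot(length(input_rates) == length(output_rates))
  if (length(input_rates) < 2) stop("need at least two points")
  if (stats::var(input_rates) == 0)
    stop("input rates are all equal; slope undefined")
  unname(stats::coef(stats::lm(output_rates ~ input_rates))[2L])
}

#' Pause-aligned PSTH and normalized peak
#'
#' Histogram of CbN spikes aligned to pause onsets, normalized by the
#' pre-pause baseline (average rate over the \code{baseline_window} ms
#' before each onset). The normalized peak is read at \code{peak_time}
#' when supplied (conventionally taken from the 100%-paused condition) or
#' at the post-onset maximum otherwise.
#'
#' @param cbn_spikes CbN [spike_train()] (or \code{sim_result}).
#' @param pause_onsets Onset times, seconds.
#' @param window Lag range \code{c(lo, hi)}, ms.
#' @param bin Bin width, ms.
#' @param baseline_window Pre-onset baseline period, ms.
#' @param peak_time Optional lag (ms) at which to read the peak.
#' @return List with \code{psth} (data frame: lag_ms, rate, norm),
#'   \code{baseline} (spikes/s), \code{peak} (normalized),
#'   \code{peak_time} (ms).
#' @export
pause_psth <- function(cbn_spikes, pause_onsets, window = c(-10, 15),
                       bin = 0.5, baseline_window = 5, peak_time = NULL) {
  times <- if (inherits(cbn_spikes, "spike_train")) cbn_spikes$times
           else cbn_spikes$spike_times
  onsets <- sort(as.numeric(pause_onsets))
  if (!length(onsets)) stop("need at least one pause onset")
  lo_s <- window[1] * 1e-3; hi_s <- window[2] * 1e-3
  bin_s <- bin * 1e-3
  idx_lo <- findInterval(onsets + lo_s, times)
  idx_hi <- findInterval(onsets + hi_s, times)
  n_pair <- idx_hi - idx_lo
  n_bins <- round((window[2] - window[1]) / bin)
  if (sum(n_pair) > 0) {
    tgt_idx <- sequence(n_pair, from = idx_lo + 1L)
    lags <- times[tgt_idx] - rep(onsets, n_pair)
    b <- floor((lags - lo_s) / bin_s) + 1L
    b <- b[b >= 1L & b <= n_bins]
    counts <- tabulate(b, nbins = n_bins)
  } else counts <- integer(n_bins)
  lag_ms <- window[1] + (seq_len(n_bins) - 0.5) * bin
  rate <- counts / (length(onsets) * bin_s)
  base_idx <- lag_ms >= -baseline_window & lag_ms < 0
  baseline <- mean(rate[base_idx])
  if (!is.finite(baseline) || baseline <= 0)
    stop("pre-pause baseline rate is zero; cannot normalize")
  norm <- rate / baseline
  if (is.null(peak_time)) {
    post <- lag_ms > 0
    peak <- max(norm[post])
    peak_time <- lag_ms[post][which.max(norm[post])]
  } else {
    peak <- norm[which.min(abs(lag_ms - peak_time))]
  }
  list(psth = data.frame(lag_ms = lag_ms, rate = rate, norm = norm),
       baseline = baseline, peak = peak, peak_time = peak_time,
       bin = bin, window = window, n_onsets = length(onsets))
}
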