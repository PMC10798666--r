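#' Lognormal interspike-interval model for Purkinje cell firing
#'
#' Purkinje cells recorded in awake animals fire with right-skewed ISI
#' distributions that are well described by lognormals whose standard
#' deviation grows linearly with the mean:
#' \eqn{sd = -0.00154 + 0.583 \cdot mean} (both in seconds). Given a target
#' firing rate this constructor sets \code{mean_isi = 1/rate}, derives
#' \code{sd_isi} from the linear relation, and moment-matches the
#' parameters \code{mu}, \code{sigma} of the underlying normal so that
#' \eqn{\exp(\mu + \sigma^2/2) = mean} and
#' \eqn{(\exp(\sigma^2) - 1) \cdot mean^2 = sd^2}.
#'
#' The relation yields a non-positive sd at and above
#' \eqn{rate = 0.583/0.00154 \approx 378.6} spikes/s, which bounds the
#' valid range.
#'
#' @param rate Target firing rate in spikes/s; must lie in (0, 378.5).
#' @return An object of class \code{isi_model} with fields \code{kind}
#'   (\code{"lognormal"}), \code{rate}, \code{mean_isi}, \code{sd_isi},
#'   \code{mu} and \code{sigma}.
#' @seealso [isi_poisson_model()], [sample_spike_train()]
#' @examples
#' m <- isi_lognormal_model(80)
#' m$mean_isi            # 0.0125 s
#' m$sd_isi              # 0.0057475 s
#' @export
isi_lognormal_model <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
  mean_isi <- 1 / rate
  sd_isi <- -0.00154 + 0.583 * mean_isi
  if (rate <= 0 || sd_isi <= 0) {
    stop("rate must lie in (0, 378.5) spikes/s: the linear mean-sd ",
         "relation sd = -0.00154 + 0.583*mean gives sd <= 0 at ",
         format(rate), " spikes/s")
  }
  sigma2 <- log(1 + (sd_isi / mean_isi)^2)
  structure(list(kind = "lognormal", rate = rate,
                 mean_isi = mean_isi, sd_isi = sd_isi,
                 mu = log(mean_isi) - sigma2 / 2, sigma = sqrt(sigma2)),
            class = "isi_model")
}

#' Poisson (exponential-ISI) control model
#'
#' Control spike trains without refractory structure: ISIs are i.i.d.
#' exponential with mean \code{1/rate}, so the ISI CV is 1 and the
#' autocorrelogram is flat away from zero lag.
#'
#' @param rate Target firing rate in spikes/s; must be positive.
#' @return An object of class \code{isi_model} with \code{kind
#'   = "exponential"}.
#' @export
isi_poisson_model <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (rate <= 0) stop("rate must be positive")
  structure(list(kind = "exponential", rate = rate,
                 mean_isi = 1 / rate, sd_isi = 1 / rate),
            class = "isi_model")
}

#' @export
print.isi_model <- function(x, ...) {
  cat(sprintf("ISI model: %s, rate %.6g spikes/s (mean ISI %.6g s, sd %.6g s)\n",
              x$kind, x$rate, x$mean_isi, x$sd_isi))
  invisible(x)
}

#' Construct a spike train
#'
#' @param times Strictly increasing spike times in seconds, all in
#'   \code{[0, duration)}.
#' @param duration Duration of the observation window in seconds.
#' @param source_id Identifier of the emitting input (any scalar).
#' @return An object of class \code{spike_train}.
#' @export
spike_train <- function(times, duration, source_id = NA) {
  times <- as.numeric(times)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration >= 0)
  if (length(times)) {
    if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
    if (times[1L] < 0 || times[length(times)] >= duration)
      stop("spike times must lie in [0, duration)")
  }
  structure(list(times = times, duration = duration, source_id = source_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train '%s': %d spikes over %.6g s (%.4g spikes/s)\n",
              format(x$source_id), length(x$times), x$duration,
              if (x$duration > 0) length(x$times) / x$duration else NA_real_))
  invisible(x)
}

# i.i.d. ISI draws from an isi_model
sample_isis <- function(model, n) {
  switch(model$kind,
         lognormal = stats::rlnorm(n, meanlog = model$mu, sdlog = model$sigma),
         exponential = stats::rexp(n, rate = model$rate),
         stop("unknown ISI model kind: ", model$kind))
}

#' Sample a spike train from an ISI model
#'
#' Spike times are the cumulative sums of i.i.d. ISI draws, truncated at
#' \code{duration}. Draws are taken in batches until the train covers the
#' window.
#'
#' @param model An [isi_lognormal_model()] or [isi_poisson_model()].
#' @param duration Train duration in seconds (\code{>= 0}).
#' @param seed Optional integer seed (calls \code{set.seed}); omit to use
#'   the current RNG state.
#' @param source_id Identifier attached to the train.
#' @return A [spike_train()].
#' @export
sample_spike_train <- function(model, duration, seed = NULL, source_id = NA) {
  stopifnot(inherits(model, "isi_model"), duration >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (duration == 0)
    return(spike_train(numeric(0), 0, source_id))
  n_batch <- max(16L, ceiling(duration * model$rate * 1.1) + 4L)
  times <- numeric(0)
  t_last <- 0
  while (t_last < duration) {
    isis <- sample_isis(model, n_batch)
    new_times <- t_last + cumsum(isis)
    times <- c(times, new_times)
    t_last <- times[length(times)]
  }
  spike_train(times[times < duration], duration, source_id)
}
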