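#' Model of the unitary PC->CbN conductance distribution
#'
#' Unitary Purkinje-cell inputs onto cerebellar nuclei neurons in juvenile
#' mice are highly variable: the measured distribution is right-skewed
#' with mean 52.9 nS and CV 1.0. The packaged parametric model is a
#' lognormal calibrated to those two moments. Alternatively a measured
#' multiset of raw conductances can be supplied (one value in nS per
#' draw-with-replacement), which then takes precedence over the
#' parametric family.
#'
#' Raw amplitudes are corrected before use: multiplied by the synaptic
#' depression factor (default 0.4, the steady-state depression at
#' physiological firing rates) and divided by the chloride divisor
#' (default 2.3, undoing the high-chloride recording internal).
#'
#' @param family \code{"lognormal"} (default) or \code{"empirical"}.
#' @param mean,cv Analytic mean (nS) and coefficient of variation of the
#'   raw lognormal model.
#' @param values Numeric vector of raw conductances (nS) for the
#'   empirical family.
#' @param depression_factor,chloride_divisor Correction factors applied
#'   by [correct_conductance()] when drawing populations.
#' @return An object of class \code{size_distribution} with analytic
#'   \code{mean} and \code{cv} fields.
#' @examples
#' m <- size_distribution_model()
#' m$mean  # 52.9
#' m$cv    # 1.0
#' @export
size_distribution_model <- function(family = c("lognormal", "empirical"),
                                    mean = 52.9, cv = 1.0, values = NULL,
                                    depression_factor = 0.4,
                                    chloride_divisor = 2.3) {
  family <- match.arg(family)
  if (!is.null(values)) family <- "empirical"
  if (family == "empirical") {
    values <- as.numeric(values)
    if (!length(values) || any(!is.finite(values)) || any(values <= 0))
      stop("empirical conductances must be a non-empty vector of positive nS values")
    mean <- base::mean(values)
    cv <- stats::sd(values) / mean
    mu <- sigma <- NA_real_
  } else {
    stopifnot(mean > 0, cv > 0)
    sigma2 <- log(1 + cv^2)
    mu <- log(mean) - sigma2 / 2
    sigma <- sqrt(sigma2)
  }
  structure(list(family = family, mean = mean, cv = cv,
                 mu = mu, sigma = sigma, values = values,
                 depression_factor = depression_factor,
                 chloride_divisor = chloride_divisor),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("Unitary conductance model (%s): raw mean %.4g nS, CV %.4g\n",
              x$family, x$mean, x$cv))
  cat(sprintf("  corrections: x%.3g (depression) / %.3g (chloride)\n",
              x$depression_factor, x$chloride_divisor))
  invisible(x)
}

#' Sample raw (uncorrected) unitary conductances
#'
#' @param model A [size_distribution_model()].
#' @param n Number of draws.
#' @return Numeric vector of raw conductances in nS.
#' @export
sample_raw_conductances <- function(model, n) {
  stopifnot(inherits(model, "size_distribution"), n >= 0)
  if (model$family == "empirical")
    model$values[sample.int(length(model$values), n, replace = TRUE)]
  else
    stats::rlnorm(n, meanlog = model$mu, sdlog = model$sigma)
}

#' Correct a measured conductance for depression and recording internal
#'
#' Measured unitary amplitudes are scaled by the depression factor
#' (x 0.4) and divided by the chloride divisor (2.3) to estimate the
#' in-vivo effective conductance: \code{raw * 0.4 / 2.3}.
#'
#' @param raw Raw conductance(s), nS, non-negative.
#' @param depression_factor,chloride_divisor Correction factors.
#' @return Corrected conductance(s) in nS.
#' @examples
#' correct_conductance(52.9)  # 9.2 nS
#' @export
correct_conductance <- function(raw, depression_factor = 0.4,
                                chloride_divisor = 2.3) {
  if (any(raw < 0)) stop("raw conductance must be non-negative")
  raw * depression_factor / chloride_divisor
}

new_population <- function(amplitude, rate, kind, sync_group, provenance) {
  stopifnot(length(amplitude) == length(rate),
            length(amplitude) == length(kind),
            length(amplitude) == length(sync_group))
  if (any(amplitude <= 0)) stop("input amplitudes must be positive")
  structure(list(
    inputs = data.frame(amplitude = as.numeric(amplitude),
                        rate = as.numeric(rate),
                        kind = as.character(kind),
                        sync_group = as.character(sync_group),
                        stringsAsFactors = FALSE),
    total_conductance = sum(amplitude),
    provenance = provenance), class = "input_population")
}

#' Construct an input population explicitly
#'
#' @param amplitude Per-input corrected amplitudes, nS.
#' @param rate Per-input firing rates, spikes/s (recycled).
#' @param kind Per-input ISI model kind, \code{"lognormal"} or
#'   \code{"exponential"} (recycled).
#' @param sync_group Synchrony-group labels; inputs sharing a label share
#'   one spike train. Defaults to all-singleton groups.
#' @param provenance Free-text label recording how the set was built.
#' @return An object of class \code{input_population} whose
#'   \code{$inputs} data frame has one row per input and whose
#'   \code{$total_conductance} is the sum of amplitudes.
#' @export
input_population <- function(amplitude, rate = 80, kind = "lognormal",
                             sync_group = NULL, provenance = "custom") {
  n <- length(amplitude)
  if (is.null(sync_group)) sync_group <- as.character(seq_len(n))
  new_population(amplitude, rep_len(rate, n), rep_len(kind, n),
                 rep_len(sync_group, n), provenance)
}

#' @export
print.input_population <- function(x, ...) {
  cat(sprintf("Input population (%s): %d inputs, total %.4g nS\n",
              x$provenance, nrow(x$inputs), x$total_conductance))
  amp <- sort(unique(x$inputs$amplitude), decreasing = TRUE)
  show <- utils::head(amp, 6)
  cat("  amplitudes (nS):", paste(signif(show, 4), collapse = ", "),
      if (length(amp) > 6) "..." else "", "\n")
  invisible(x)
}

#' Draw a random input population to a target total conductance
#'
#' Raw amplitudes are sampled from the unitary conductance model,
#' corrected for depression and chloride, multiplied by \code{scale}, and
#' accumulated until the running total reaches \code{total_target}; the
#' overshooting draw is kept and the actual total recorded. Each input
#' receives its own (independently sampled) spike train at \code{rate}.
#'
#' @param model A [size_distribution_model()].
#' @param total_target Target total inhibitory conductance, nS (default
#'   200, the estimated total PC input onto one CbN neuron).
#' @param rate Firing rate for every input, spikes/s.
#' @param seed Optional integer seed.
#' @param scale Multiplicative rescaling of the corrected input sizes
#'   (0.5/1/1.5 variants).
#' @param include Corrected amplitudes (nS) placed in the population
#'   before random drawing starts, e.g. to condition on the presence of
#'   one 37 nS input.
#' @param kind ISI model kind for all inputs.
#' @return An [input_population()] with provenance
#'   \code{"empirical-draw"}.
#' @export
draw_input_population <- function(model, total_target = 200, rate = 80,
                                  seed = NULL, scale = 1,
                                  include = numeric(0),
                                  kind = "lognormal") {
  stopifnot(inherits(model, "size_distribution"),
            total_target > 0, scale > 0)
  if (!is.null(seed)) set.seed(seed)
  amp <- as.numeric(include)
  total <- sum(amp)
  while (total < total_target) {
    draws <- correct_conductance(sample_raw_conductances(model, 32L),
                                 model$depression_factor,
                                 model$chloride_divisor) * scale
    cum <- total + cumsum(draws)
    stop_at <- which(cum >= total_target)
    take <- if (length(stop_at)) seq_len(stop_at[1L]) else seq_along(draws)
    amp <- c(amp, draws[take])
    total <- total + sum(draws[take])
  }
  input_population(amp, rate = rate, kind = kind,
                   provenance = "empirical-draw")
}

#' Simplified and uniform populations used by the standard protocols
#'
#' Named input sets: \code{"fig2"} = 16 x 3 nS + 10 x 10 nS + 2 x 30 nS
#' at 83 Hz (208 nS total); \code{"fig6"} = 16 x 3 nS + 8 x 12 nS +
#' 2 x 30 nS at 80 Hz; \code{"uniform40"} = 40 x 5 nS at 80 Hz;
#' \code{"fig3-49"} = 12 x 20 nS at 49 Hz; \code{"fig3-83"} = 9 x 20 nS
#' at 83 Hz; \code{"fig3-122"} = 6 x 20 nS at 122 Hz;
#' \code{"fig3-poisson"} = 9 x 20 nS Poisson at 80 Hz.
#'
#' @param variant One of the labels above.
#' @return An [input_population()].
#' @export
simplified_population <- function(variant = c("fig2", "fig6", "uniform40",
                                              "fig3-49", "fig3-83",
                                              "fig3-122", "fig3-poisson")) {
  variant <- match.arg(variant)
  spec <- switch(variant,
    "fig2" = list(amp = c(rep(3, 16), rep(10, 10), rep(30, 2)), rate = 83,
                  kind = "lognormal"),
    "fig6" = list(amp = c(rep(3, 16), rep(12, 8), rep(30, 2)), rate = 80,
                  kind = "lognormal"),
    "uniform40" = list(amp = rep(5, 40), rate = 80, kind = "lognormal"),
    "fig3-49" = list(amp = rep(20, 12), rate = 49, kind = "lognormal"),
    "fig3-83" = list(amp = rep(20, 9), rate = 83, kind = "lognormal"),
    "fig3-122" = list(amp = rep(20, 6), rate = 122, kind = "lognormal"),
    "fig3-poisson" = list(amp = rep(20, 9), rate = 80, kind = "exponential"))
  input_population(spec$amp, rate = spec$rate, kind = spec$kind,
                   provenance = paste0("simplified-", variant))
}

#' Uniform-size population with a given count and amplitude
#'
#' @param n Number of inputs.
#' @param amplitude Per-input amplitude, nS.
#' @param rate Firing rate, spikes/s.
#' @param kind ISI model kind.
#' @return An [input_population()].
#' @export
uniform_population <- function(n, amplitude, rate = 80, kind = "lognormal") {
  input_population(rep(amplitude, n), rate = rate, kind = kind,
                   provenance = sprintf("uniform-%dx%gnS", n, amplitude))
}

#' Synchronize subsets of inputs
#'
#' Inputs assigned to the same group share a single spike train (100%
#' spike-time synchrony), so synchronizing ten 5 nS inputs is equivalent
#' to one 50 nS input. Amplitudes, rates and the total conductance are
#' unchanged.
#'
#' @param pop An [input_population()].
#' @param groups Vector of group labels, one per input.
#' @return The population with updated \code{sync_group} labels.
#' @export
apply_synchrony <- function(pop, groups) {
  stopifnot(inherits(pop, "input_population"),
            length(groups) == nrow(pop$inputs))
  pop$inputs$sync_group <- as.character(groups)
  rates <- split(pop$inputs$rate, pop$inputs$sync_group)
  kinds <- split(pop$inputs$kind, pop$inputs$sync_group)
  ok <- all(vapply(rates, function(r) length(unique(r)) == 1L, logical(1))) &&
    all(vapply(kinds, function(k) length(unique(k)) == 1L, logical(1)))
  if (!ok) stop("inputs sharing a sync group must share rate and ISI kind")
  pop
}

#' Delete spikes inside pause windows
#'
#' Every spike with time in \code{[onset, onset + width)} for any onset is
#' removed; the remaining spikes are untouched (no re-drawing of later
#' ISIs). Overlapping windows are merged implicitly.
#'
#' @param train A [spike_train()].
#' @param onsets Pause onset times, seconds, within \code{[0, duration)}.
#' @param width Pause width in seconds (default 0.002, i.e. 2 ms).
#' @return The censored [spike_train()].
#' @export
apply_pauses <- function(train, onsets, width = 0.002) {
  stopifnot(inherits(train, "spike_train"), width > 0)
  onsets <- sort(as.numeric(onsets))
  if (length(onsets) && (onsets[1L] < 0 || onsets[length(onsets)] >= train$duration))
    stop("pause onsets must lie in [0, duration)")
  if (!length(onsets) || !length(train$times)) return(train)
  idx <- findInterval(train$times, onsets)
  inside <- idx >= 1L & train$times < onsets[pmax(idx, 1L)] + width
  spike_train(train$times[!inside], train$duration, train$source_id)
}

#' Periodic pause onsets
#'
#' @param duration Run duration, seconds.
#' @param interval Pause period, seconds (default 0.020).
#' @param start First onset, seconds.
#' @return Numeric vector of onsets in \code{[start, duration)}.
#' @export
periodic_onsets <- function(duration, interval = 0.020, start = 0) {
  stopifnot(interval > 0, duration > start)
  seq(start, duration - 1e-12, by = interval)
}

#' Sample one spike train per synchrony group
#'
#' Groups are visited in order of first appearance in the population;
#' each receives an independent spike train drawn from its ISI model.
#' With a fixed \code{seed} the mapping from population to trains is
#' fully reproducible.
#'
#' @param pop An [input_population()].
#' @param duration Train duration, seconds.
#' @param seed Optional integer seed.
#' @return Named list of [spike_train()]s, one per sync group label.
#' @export
population_trains <- function(pop, duration, seed = NULL) {
  stopifnot(inherits(pop, "input_population"))
  if (!is.null(seed)) set.seed(seed)
  groups <- unique(pop$inputs$sync_group)
  trains <- vector("list", length(groups))
  names(trains) <- groups
  for (g in groups) {
    row <- which(pop$inputs$sync_group == g)[1L]
    if (pop$inputs$rate[row] <= 0) {       # silenced input
      trains[[g]] <- spike_train(numeric(0), duration, source_id = g)
      next
    }
    model <- if (pop$inputs$kind[row] == "exponential")
      isi_poisson_model(pop$inputs$rate[row])
    else
      isi_lognormal_model(pop$inputs$rate[row])
    trains[[g]] <- sample_spike_train(model, duration, source_id = g)
  }
  trains
}
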