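#' Biexponential unitary synaptic conductance kernel
#'
#' Unitary synaptic events are modelled as peak-normalized biexponentials
#' \deqn{k(t) = A N (e^{-t/\tau_d} - e^{-t/\tau_r}), t \ge 0,}
#' with \eqn{N} chosen so that the maximum of \eqn{k} equals the declared
#' amplitude \eqn{A}. The peak occurs at
#' \eqn{t_p = \tau_r\tau_d/(\tau_d-\tau_r)\,\ln(\tau_d/\tau_r)} and the
#' time integral is \eqn{A N (\tau_d - \tau_r)}.
#'
#' Defaults follow the measured synapses: inhibitory PC inputs rise in
#' 0.1 ms and decay in 2.5 ms; excitatory mossy-fiber events rise in
#' 0.28 ms, decay in 1.06 ms, with amplitude 0.4 nS (after depression).
#'
#' @param tau_rise,tau_decay Rise and decay time constants, ms, with
#'   \code{0 < tau_rise < tau_decay}.
#' @param amplitude Peak conductance, nS.
#' @return Object of class \code{syn_kernel} with fields
#'   \code{tau_rise}, \code{tau_decay}, \code{amplitude}, \code{norm},
#'   \code{peak_time} (ms) and \code{integral} (nS s).
#' @examples
#' k <- unitary_kernel(0.1, 2.5, 1)
#' k$peak_time      # ~0.3353 ms
#' k$integral * 1e3 # ~2.8589 nS ms
#' @export
unitary_kernel <- function(tau_rise, tau_decay, amplitude = 1) {
  stopifnot(tau_rise > 0, amplitude > 0)
  if (tau_rise >= tau_decay)
    stop("tau_rise must be strictly smaller than tau_decay")
  peak_time <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  norm <- 1 / (exp(-peak_time / tau_decay) - exp(-peak_time / tau_rise))
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 amplitude = amplitude, norm = norm, peak_time = peak_time,
                 integral = amplitude * norm * (tau_decay - tau_rise) * 1e-3),
            class = "syn_kernel")
}

#' @rdname unitary_kernel
#' @export
inhibitory_kernel <- function(amplitude = 1) unitary_kernel(0.1, 2.5, amplitude)

#' @rdname unitary_kernel
#' @export
excitatory_kernel <- function(amplitude = 0.4) unitary_kernel(0.28, 1.06, amplitude)

#' @export
print.syn_kernel <- function(x, ...) {
  cat(sprintf(paste0("Biexponential kernel: tau_rise %.3g ms, tau_decay %.3g ms,",
                     " peak %.3g nS at %.4g ms, integral %.4g nS ms\n"),
              x$tau_rise, x$tau_decay, x$amplitude, x$peak_time,
              x$integral * 1e3))
  invisible(x)
}

#' Evaluate a kernel at given times
#'
#' Closed-form evaluation, mainly useful as an oracle for sampled traces.
#'
#' @param kernel A [unitary_kernel()].
#' @param t Times in seconds (values before 0 give 0).
#' @return Conductance values, nS.
#' @export
kernel_eval <- function(kernel, t) {
  tm <- t * 1e3
  ifelse(tm < 0, 0,
         kernel$amplitude * kernel$norm *
           (exp(-tm / kernel$tau_decay) - exp(-tm / kernel$tau_rise)))
}

new_trace <- function(values, dt, t0 = 0, components = NULL) {
  structure(list(values = values, dt = dt, t0 = t0, components = components),
            class = "conductance_trace")
}

#' @export
print.conductance_trace <- function(x, ...) {
  cat(sprintf("Conductance trace: %d samples, dt %.3g s (%.6g s), mean %.4g nS\n",
              length(x$values), x$dt, length(x$values) * x$dt,
              mean(x$values)))
  if (!is.null(x$components))
    cat("  components:", paste(names(x$components), collapse = ", "), "\n")
  invisible(x)
}

# shared impulse-to-trace path: all spike trains of one kernel class are
# binned to weighted impulses first, then filtered once, so that grouped
# (synchronous) inputs are bit-identical to a single merged input
impulse_trace <- function(times, weights, kernel, dt, n_steps) {
  o <- order(times)
  new_trace(biexp_trace_cpp(times[o], weights[o], kernel$tau_rise,
                            kernel$tau_decay, dt, n_steps), dt)
}

#' Conductance trace from one spike train
#'
#' Linear superposition of kernel copies at the spike times, sampled on a
#' uniform grid of step \code{dt}. Implemented with a recursive
#' exponential filter, which is exact for the biexponential kernel at the
#' sample points.
#'
#' @param train A [spike_train()].
#' @param kernel A [unitary_kernel()].
#' @param dt Sample step, seconds; a warning is issued when
#'   \code{dt > tau_rise/2} (undersampled rise).
#' @param duration Trace duration, seconds (defaults to the train's).
#' @return A \code{conductance_trace}.
#' @export
conductance_from_train <- function(train, kernel, dt = 2e-5,
                                   duration = train$duration) {
  stopifnot(inherits(train, "spike_train"), inherits(kernel, "syn_kernel"))
  if (dt > kernel$tau_rise * 1e-3 / 2)
    warning("dt exceeds tau_rise/2; the kernel rise is undersampled")
  n <- round(duration / dt)
  impulse_trace(train$times, rep(kernel$amplitude, length(train$times)),
                unitary_kernel(kernel$tau_rise, kernel$tau_decay, 1),
                dt, n)
}

#' Total inhibitory conductance of an input population
#'
#' Sums the contributions of all inputs (one shared spike train per
#' synchrony group, each input weighted by its amplitude) through the
#' inhibitory kernel. Optionally decomposes the total into per-size-class
#' component traces (small < 5 nS, medium 5-20 nS, large >= 20 nS) which
#' sum to the total.
#'
#' @param pop An [input_population()].
#' @param trains Named list of [spike_train()]s from
#'   [population_trains()], one per sync group.
#' @param tau_rise,tau_decay Inhibitory kernel time constants, ms.
#' @param dt Sample step, seconds.
#' @param duration Trace duration, seconds.
#' @param components Logical; attach per-size-class components.
#' @param breaks Size-class boundaries (nS) used when
#'   \code{components = TRUE}.
#' @return A \code{conductance_trace} (with \code{$components} when
#'   requested).
#' @export
total_inhibitory_conductance <- function(pop, trains, tau_rise = 0.1,
                                         tau_decay = 2.5, dt = 2e-5,
                                         duration = NULL,
                                         components = FALSE,
                                         breaks = c(5, 20)) {
  stopifnot(inherits(pop, "input_population"))
  groups <- unique(pop$inputs$sync_group)
  missing <- setdiff(groups, names(trains))
  if (length(missing))
    stop("missing spike train for sync group(s): ",
         paste(missing, collapse = ", "))
  if (is.null(duration)) duration <- trains[[groups[1L]]]$duration
  n <- round(duration / dt)
  kernel <- unitary_kernel(tau_rise, tau_decay, 1)
  group_amp <- vapply(groups, function(g)
    sum(pop$inputs$amplitude[pop$inputs$sync_group == g]), numeric(1))
  times <- unlist(lapply(groups, function(g) trains[[g]]$times),
                  use.names = FALSE)
  weights <- rep(group_amp, vapply(groups, function(g)
    length(trains[[g]]$times), integer(1)))
  total <- impulse_trace(times, weights, kernel, dt, n)
  if (components) {
    cls <- cut(pop$inputs$amplitude, c(-Inf, breaks, Inf),
               labels = c("small", "medium", "large"))
    comp <- lapply(levels(cls), function(lv) {
      rows <- which(cls == lv)
      if (!length(rows)) return(new_trace(numeric(n) * 0, dt))
      # per-class impulse weights: each group contributes only its
      # members of this class
      amp_cls <- vapply(groups, function(g)
        sum(pop$inputs$amplitude[rows][pop$inputs$sync_group[rows] == g]),
        numeric(1))
      keep <- amp_cls > 0
      tt <- unlist(lapply(groups[keep], function(g) trains[[g]]$times),
                   use.names = FALSE)
      ww <- rep(amp_cls[keep], vapply(groups[keep], function(g)
        length(trains[[g]]$times), integer(1)))
      impulse_trace(tt, ww, kernel, dt, n)
    })
    names(comp) <- levels(cls)
    total$components <- comp
  }
  total
}

#' Aggregate excitatory conductance from a Poisson event stream
#'
#' Mossy-fiber drive is modelled as one aggregate Poisson stream of
#' unitary excitatory events convolved with the excitatory kernel.
#'
#' @param events_per_second Aggregate event rate (e.g. 20,000-25,000/s).
#' @param dt Sample step, seconds.
#' @param duration Trace duration, seconds.
#' @param seed Optional integer seed.
#' @param kernel Unitary excitatory kernel.
#' @return A \code{conductance_trace}.
#' @export
excitatory_conductance <- function(events_per_second, dt = 2e-5, duration,
                                   seed = NULL,
                                   kernel = excitatory_kernel()) {
  stopifnot(events_per_second >= 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  if (events_per_second == 0) return(new_trace(numeric(n), dt))
  n_ev <- stats::rpois(1L, events_per_second * duration)
  times <- sort(stats::runif(n_ev, 0, duration))
  impulse_trace(times, rep(kernel$amplitude, n_ev),
                unitary_kernel(kernel$tau_rise, kernel$tau_decay, 1), dt, n)
}

#' Mean, sd and CV of a conductance trace
#'
#' Statistics are computed over \code{t >= burn_in}; the burn-in replaces
#' the initial filter transient. The CV is flagged \code{NA} for an
#' all-zero trace.
#'
#' @param trace A \code{conductance_trace}.
#' @param burn_in Discarded initial period, seconds.
#' @return List with \code{mean}, \code{sd}, \code{cv}, \code{burn_in}.
#' @export
trace_stats <- function(trace, burn_in = 1) {
  stopifnot(inherits(trace, "conductance_trace"))
  n <- length(trace$values)
  i0 <- round(burn_in / trace$dt) + 1L
  if (i0 >= n) stop("trace shorter than burn_in")
  v <- trace$values[i0:n]
  m <- mean(v)
  s <- stats::sd(v)
  list(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_,
       burn_in = burn_in)
}

#' Spike-triggered average of a conductance trace
#'
#' Averages trace segments aligned to each reference spike. Reference
#' spikes closer than the window to either trace edge are dropped.
#'
#' @param trace A \code{conductance_trace}.
#' @param ref Reference [spike_train()].
#' @param window Half-window, ms (lags span \code{-window..+window}).
#' @return Data frame with \code{lag_ms} and \code{g} (nS), plus
#'   attribute \code{n_ref}.
#' @export
spike_triggered_average <- function(trace, ref, window = 10) {
  stopifnot(inherits(trace, "conductance_trace"), inherits(ref, "spike_train"))
  w_s <- window * 1e-3
  n <- length(trace$values)
  idx <- round(ref$times / trace$dt) + 1L
  half <- round(w_s / trace$dt)
  use <- idx - half >= 1L & idx + half <= n
  if (!any(use)) stop("no reference spikes with a full window inside the trace")
  idx <- idx[use]
  lag_idx <- (-half):half
  seg <- outer(idx, lag_idx, `+`)
  sta <- colMeans(matrix(trace$values[seg], nrow = length(idx)))
  out <- data.frame(lag_ms = lag_idx * trace$dt * 1e3, g = sta)
  attr(out, "n_ref") <- length(idx)
  out
}
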