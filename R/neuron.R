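#' Membrane parameters of the CbN model neuron
#'
#' Single-compartment conductance-based integrate-and-fire neuron
#' \deqn{C_m dV/dt = g_E(t)(V_E - V) + g_I(t)(V_I - V) + g_L(V_L - V),}
#' with a spike emitted when \eqn{V} reaches the threshold \eqn{\theta},
#' followed by a refractory period during which the neuron is held at the
#' reset \eqn{V_r}.
#'
#' Named presets bundle the per-protocol parameter sets:
#' \describe{
#'   \item{\code{"fig2"}}{Cm 50 pF, gL 8.8 nS, VL -40 mV, 20,000
#'     excitatory events/s, t_ref 2 ms (correlogram protocol).}
#'   \item{\code{"fig4"}}{Cm 200 pF, gL 5 nS, VL -10 mV, 23,650
#'     excitatory events/s, t_ref 2 ms (rate/CV, rate-code and synchrony
#'     protocols).}
#'   \item{\code{"fig8"}}{Cm 70 pF, gL 20 nS, VL -49.9 mV, 23,650
#'     excitatory events/s, t_ref 1 ms (pause protocol, nonuniform
#'     inputs).}
#'   \item{\code{"fig8-uniform"}}{as \code{"fig8"} with 25,000
#'     excitatory events/s.}
#' }
#' All presets share VE 0 mV, VI -75 mV, theta -50 mV, Vr -60 mV.
#'
#' @param preset Optional preset name; explicit arguments override preset
#'   values.
#' @param Cm Membrane capacitance, pF.
#' @param gL Leak conductance, nS.
#' @param VL,VE,VI Leak, excitatory and inhibitory reversal potentials, mV.
#' @param theta Spike threshold, mV.
#' @param Vr Reset potential, mV.
#' @param t_ref Refractory period, ms.
#' @param exc_rate Aggregate excitatory event rate, events/s (used by the
#'   population-level simulators).
#' @return Object of class \code{neuron_params}.
#' @export
neuron_params <- function(preset = NULL, Cm = NULL, gL = NULL, VL = NULL,
                          VE = 0, VI = -75, theta = -50, Vr = -60,
                          t_ref = NULL, exc_rate = NULL) {
  base <- list(VE = VE, VI = VI, theta = theta, Vr = Vr)
  if (!is.null(preset)) {
    p <- switch(match.arg(preset, c("fig2", "fig4", "fig8", "fig8-uniform")),
      "fig2" = list(Cm = 50, gL = 8.8, VL = -40, t_ref = 2, exc_rate = 20000),
      "fig4" = list(Cm = 200, gL = 5, VL = -10, t_ref = 2, exc_rate = 23650),
      "fig8" = list(Cm = 70, gL = 20, VL = -49.9, t_ref = 1, exc_rate = 23650),
      "fig8-uniform" = list(Cm = 70, gL = 20, VL = -49.9, t_ref = 1,
                            exc_rate = 25000))
    base <- c(base, list(preset = preset))
    if (is.null(Cm)) Cm <- p$Cm
    if (is.null(gL)) gL <- p$gL
    if (is.null(VL)) VL <- p$VL
    if (is.null(t_ref)) t_ref <- p$t_ref
    if (is.null(exc_rate)) exc_rate <- p$exc_rate
  }
  if (is.null(t_ref)) t_ref <- 2
  if (is.null(exc_rate)) exc_rate <- 0
  stopifnot(!is.null(Cm), !is.null(gL), !is.null(VL), Cm > 0, gL > 0,
            t_ref >= 0, Vr < theta)
  structure(c(base, list(Cm = Cm, gL = gL, VL = VL, t_ref = t_ref,
                         exc_rate = exc_rate)),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(paste0("CbN neuron%s: Cm %.4g pF, gL %.4g nS, VL %.4g mV, ",
                     "theta %.4g mV, Vr %.4g mV, t_ref %.3g ms, ",
                     "exc %.5g events/s\n"),
              if (!is.null(x$preset)) sprintf(" [%s]", x$preset) else "",
              x$Cm, x$gL, x$VL, x$theta, x$Vr, x$t_ref, x$exc_rate))
  invisible(x)
}

new_sim_result <- function(spike_times, duration, dt, params,
                           gI_stats = NULL, gE_stats = NULL,
                           voltage = NULL, trains = NULL, seed = NULL) {
  structure(list(spike_times = spike_times, duration = duration, dt = dt,
                 params = params, gI_stats = gI_stats, gE_stats = gE_stats,
                 voltage = voltage, trains = trains, seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation: %d spikes over %.6g s (%.4g spikes/s), dt %.3g s\n",
              length(x$spike_times), x$duration,
              firing_rate(x, burn_in = min(1, x$duration / 2)), x$dt))
  invisible(x)
}

#' Integrate the CbN membrane equation over given conductance traces
#'
#' Per-step exponential-integrator update towards the instantaneous
#' steady state (exact for piecewise-constant conductances). Threshold
#' crossings are resolved at step granularity; after a spike the neuron
#' is held at the reset for the refractory period.
#'
#' @param params A [neuron_params()].
#' @param gE,gI Excitatory/inhibitory \code{conductance_trace}s sampled
#'   at \code{dt} (a scalar is promoted to a constant trace).
#' @param dt Integration step, seconds.
#' @param duration Simulated time, seconds (defaults to trace length).
#' @param record_v Record the voltage trace (mV).
#' @param v0 Initial voltage, mV (defaults to the reset potential).
#' @return A \code{sim_result} with \code{spike_times} (s).
#' @export
simulate_cbn <- function(params, gE, gI, dt = 2e-5, duration = NULL,
                         record_v = FALSE, v0 = NULL) {
  stopifnot(inherits(params, "neuron_params"))
  as_vals <- function(g, n) {
    if (inherits(g, "conductance_trace")) {
      if (abs(g$dt - dt) > 1e-12)
        stop("trace dt does not match the simulation dt")
      g$values
    } else rep_len(as.numeric(g), n)
  }
  n <- if (!is.null(duration)) round(duration / dt)
       else max(length(if (inherits(gE, "conductance_trace")) gE$values else 0),
                length(if (inherits(gI, "conductance_trace")) gI$values else 0))
  if (n < 1) stop("nothing to simulate: give duration or a non-empty trace")
  vE <- as_vals(gE, n); vI <- as_vals(gI, n)
  if (length(vE) < n || length(vI) < n)
    stop("conductance traces shorter than the requested duration")
  res <- lif_integrate_cpp(vE[1:n], vI[1:n], params$Cm, params$gL, params$VL,
                           params$VE, params$VI, params$theta, params$Vr,
                           params$t_ref, dt,
                           if (is.null(v0)) params$Vr else v0, record_v)
  new_sim_result(res$spike_times, n * dt, dt, params,
                 voltage = res$voltage)
}

#' Simulate a CbN neuron driven by an input population (streaming)
#'
#' End-to-end driver used by the protocol runners: samples one spike
#' train per synchrony group, optionally censors pause windows, merges
#' all trains into an amplitude-weighted impulse stream, generates the
#' aggregate excitatory Poisson drive, and integrates the membrane in a
#' single pass without materializing conductance traces. Running
#' mean/sd/CV of both conductances (after \code{burn_in}) are returned.
#'
#' @param params A [neuron_params()] (its \code{exc_rate} is used unless
#'   overridden).
#' @param pop An [input_population()].
#' @param duration Simulated time, seconds.
#' @param dt Integration step, seconds.
#' @param seed Optional master seed for trains and excitation.
#' @param exc_rate Aggregate excitatory event rate, events/s.
#' @param exc_amp Unitary excitatory amplitude, nS.
#' @param pauses Optional list with \code{onsets} (s), \code{width} (s)
#'   and optionally \code{groups} (sync-group labels to pause; default
#'   all).
#' @param burn_in Discarded initial period for conductance statistics, s.
#' @param keep_trains Keep the per-group spike trains in the result.
#' @param record_traces Also return full gE/gI traces (memory-heavy).
#' @return A \code{sim_result}; \code{$gI_stats} and \code{$gE_stats}
#'   hold mean/sd/cv of the conductances.
#' @export
simulate_cbn_population <- function(params, pop, duration, dt = 2e-5,
                                    seed = NULL,
                                    exc_rate = params$exc_rate,
                                    exc_amp = 0.4, pauses = NULL,
                                    burn_in = 1, keep_trains = FALSE,
                                    record_traces = FALSE) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(pop, "input_population"), duration > 0)
  if (!is.null(seed)) set.seed(seed)
  trains <- population_trains(pop, duration)
  if (!is.null(pauses)) {
    grp <- if (is.null(pauses$groups)) names(trains) else as.character(pauses$groups)
    width <- if (is.null(pauses$width)) 0.002 else pauses$width
    for (g in grp)
      trains[[g]] <- apply_pauses(trains[[g]], pauses$onsets, width)
  }
  groups <- unique(pop$inputs$sync_group)
  group_amp <- vapply(groups, function(g)
    sum(pop$inputs$amplitude[pop$inputs$sync_group == g]), numeric(1))
  times <- unlist(lapply(groups, function(g) trains[[g]]$times),
                  use.names = FALSE)
  weights <- rep(group_amp, vapply(groups, function(g)
    length(trains[[g]]$times), integer(1)))
  o <- order(times)
  ik <- inhibitory_kernel()
  ek <- excitatory_kernel()
  res <- simulate_cbn_cpp(times[o], weights[o], ik$tau_rise, ik$tau_decay,
                          exc_rate, exc_amp, ek$tau_rise, ek$tau_decay,
                          params$Cm, params$gL, params$VL, params$VE,
                          params$VI, params$theta, params$Vr, params$t_ref,
                          dt, duration, min(burn_in, duration / 2),
                          record_traces)
  out <- new_sim_result(res$spike_times, duration, dt, params,
                        gI_stats = list(mean = res$gI_mean, sd = res$gI_sd,
                                        cv = if (res$gI_mean > 0)
                                          res$gI_sd / res$gI_mean else NA_real_),
                        gE_stats = list(mean = res$gE_mean, sd = res$gE_sd),
                        trains = if (keep_trains) trains else NULL,
                        seed = seed)
  if (record_traces) {
    out$gI <- new_trace(res$gI, dt)
    out$gE <- new_trace(res$gE, dt)
  }
  out
}

#' Analytic firing rate in the constant-conductance limit
#'
#' For constant \eqn{g_E, g_I} the membrane relaxes towards
#' \eqn{V_\infty = (g_L V_L + g_E V_E + g_I V_I)/(g_L + g_E + g_I)} with
#' time constant \eqn{\tau = C_m/(g_L + g_E + g_I)}. If
#' \eqn{V_\infty \le \theta} the neuron is silent; otherwise the ISI is
#' \eqn{\tau \ln((V_\infty - V_r)/(V_\infty - \theta)) + t_{ref}}. Serves
#' as an independent closed-form oracle for the simulator.
#'
#' @param params A [neuron_params()].
#' @param gE0,gI0 Constant conductances, nS.
#' @return Firing rate, spikes/s.
#' @examples
#' constant_conductance_rate(neuron_params("fig4"), 20, 30)  # ~203.9
#' @export
constant_conductance_rate <- function(params, gE0 = 0, gI0 = 0) {
  stopifnot(inherits(params, "neuron_params"), gE0 >= 0, gI0 >= 0)
  gtot <- params$gL + gE0 + gI0
  vinf <- (params$gL * params$VL + gE0 * params$VE + gI0 * params$VI) / gtot
  if (vinf <= params$theta) return(0)
  tau_ms <- params$Cm / gtot
  isi_ms <- tau_ms * log((vinf - params$Vr) / (vinf - params$theta)) +
    params$t_ref
  1000 / isi_ms
}

#' Mean firing rate of a simulation result
#'
#' @param result A \code{sim_result} (or a [spike_train()]).
#' @param burn_in Discarded initial period, seconds.
#' @return Spikes/s over \code{t >= burn_in}.
#' @export
firing_rate <- function(result, burn_in = 1) {
  times <- if (inherits(result, "spike_train")) result$times
           else result$spike_times
  duration <- result$duration
  if (duration <= burn_in) stop("duration must exceed burn_in")
  sum(times >= burn_in) / (duration - burn_in)
}
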