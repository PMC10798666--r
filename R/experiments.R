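#' @title Protocol runners for the simulated figures
#' @description Each \code{run_fig*} function reproduces one simulation
#'   protocol end to end at desk scale and returns a results bundle: a
#'   list carrying the exact configuration used plus per-condition data
#'   frames, so every summary is traceable to a stored record.
#' @name experiments
NULL

# deterministic child seeds below 2^31
child_seed <- function(master, k) {
  as.integer((as.numeric(master) * 1000 + k) %% 2147483647) + 1L
}

new_bundle <- function(config, ...) {
  structure(c(list(config = config), list(...)), class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("Results bundle: %s\n", x$config$figure))
  for (nm in setdiff(names(x), "config"))
    if (is.data.frame(x[[nm]]))
      cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Per-input cross-correlogram protocol
#'
#' Draws random 200 nS input populations (83 Hz lognormal trains, fig2
#' neuron preset, 20,000 excitatory events/s), simulates each cell, and
#' computes the cross-correlogram of every input against the CbN spike
#' train together with its excitation/inhibition/half-decay metrics.
#'
#' @param n_cells Number of random populations.
#' @param duration Seconds per cell (the full protocol used 160,000 s;
#'   the desk-scale default keeps correlogram noise well below the
#'   effects measured).
#' @param scale Input-size scaling factor (0.5/1/1.5).
#' @param rate PC firing rate, spikes/s.
#' @param seed Master seed.
#' @param dt Integration step, s.
#' @param population Optional fixed [input_population()] reused for every
#'   cell (overrides the random draw).
#' @param model Unitary conductance model for random draws.
#' @param window,bin Correlogram window and bin, ms.
#' @return A results bundle with \code{$inputs} (one row per input:
#'   amplitude, e, i, t_half, n_ref) and \code{$cells} (firing rate and
#'   conductance statistics per cell).
#' @export
run_fig2 <- function(n_cells = 1, duration = 2000, scale = 1, rate = 83,
                     seed = 1, dt = 2e-5, population = NULL,
                     model = size_distribution_model(),
                     window = 20, bin = 0.1) {
  params <- neuron_params("fig2")
  inputs <- list(); cells <- list()
  for (cell in seq_len(n_cells)) {
    set.seed(child_seed(seed, cell))
    pop <- if (is.null(population)) {
      draw_input_population(model, total_target = 200, rate = rate,
                            scale = scale)
    } else population
    sim <- simulate_cbn_population(params, pop, duration, dt = dt,
                                   keep_trains = TRUE)
    cbn <- spike_train(sim$spike_times, duration, source_id = "cbn")
    rows <- lapply(seq_len(nrow(pop$inputs)), function(j) {
      g <- pop$inputs$sync_group[j]
      cc <- cross_correlogram(sim$trains[[g]], cbn, window = window,
                              bin = bin)
      if (cc$n_ref < 1000)
        warning("fewer than 1000 reference spikes for input ", j,
                "; metrics will be noisy")
      m <- correlogram_metrics(cc)
      data.frame(cell = cell, input = j,
                 amplitude = pop$inputs$amplitude[j],
                 e = m$e, i = m$i, t_half = m$t_half, n_ref = cc$n_ref)
    })
    inputs[[cell]] <- do.call(rbind, rows)
    cells[[cell]] <- data.frame(cell = cell,
                                rate = firing_rate(sim),
                                n_inputs = nrow(pop$inputs),
                                total_nS = pop$total_conductance,
                                gI_mean = sim$gI_stats$mean,
                                gI_cv = sim$gI_stats$cv)
  }
  new_bundle(list(figure = "fig2", n_cells = n_cells, duration = duration,
                  scale = scale, rate = rate, seed = seed, dt = dt,
                  window = window, bin = bin, preset = "fig2"),
             inputs = do.call(rbind, inputs),
             cells = do.call(rbind, cells))
}

#' Firing rate versus inhibitory-conductance CV protocol
#'
#' Simulates cells with nonuniform populations drawn from the corrected
#' unitary distribution (80 Hz) and cells with uniform-size inputs
#' (sizes spanning 2.5-40 nS, counts keeping the total at 200 nS,
#' 100 Hz), fig4 preset, recording the firing rate and the CV of the
#' inhibitory conductance of each cell.
#'
#' @param n_nonuniform,n_uniform Cell counts for the two families (the
#'   full protocol used 100 and 200).
#' @param duration Seconds per cell (10, as in the protocol).
#' @param seed Master seed.
#' @param dt Integration step, s.
#' @param model Unitary conductance model.
#' @return Results bundle with \code{$cells}: provenance, firing rate,
#'   gI mean/CV per cell.
#' @export
run_fig4 <- function(n_nonuniform = 20, n_uniform = 20, duration = 10,
                     seed = 1, dt = 2e-5,
                     model = size_distribution_model()) {
  params <- neuron_params("fig4")
  sizes <- exp(seq(log(2.5), log(40), length.out = max(n_uniform, 1L)))
  rows <- list()
  for (cell in seq_len(n_nonuniform)) {
    set.seed(child_seed(seed, cell))
    pop <- draw_input_population(model, total_target = 200, rate = 80)
    sim <- simulate_cbn_population(params, pop, duration, dt = dt,
                                   burn_in = min(1, duration / 2))
    rows[[length(rows) + 1L]] <- data.frame(
      provenance = "nonuniform", cell = cell,
      rate = firing_rate(sim, burn_in = min(1, duration / 2)),
      n_inputs = nrow(pop$inputs), gI_mean = sim$gI_stats$mean,
      gI_cv = sim$gI_stats$cv)
  }
  for (cell in seq_len(n_uniform)) {
    set.seed(child_seed(seed, 10000 + cell))
    pop <- uniform_population(round(200 / sizes[cell]), sizes[cell],
                              rate = 100)
    sim <- simulate_cbn_population(params, pop, duration, dt = dt,
                                   burn_in = min(1, duration / 2))
    rows[[length(rows) + 1L]] <- data.frame(
      provenance = "uniform", cell = cell,
      rate = firing_rate(sim, burn_in = min(1, duration / 2)),
      n_inputs = nrow(pop$inputs), gI_mean = sim$gI_stats$mean,
      gI_cv = sim$gI_stats$cv)
  }
  new_bundle(list(figure = "fig4", n_nonuniform = n_nonuniform,
                  n_uniform = n_uniform, duration = duration, seed = seed,
                  dt = dt, preset = "fig4"),
             cells = do.call(rbind, rows))
}

#' Rate-code sweep protocol
#'
#' For each input of a population, sweeps that input's firing rate over
#' \code{rates} while the other inputs stay at \code{base_rate} (fig4
#' preset), recording the CbN output rate and the mean total inhibitory
#' conductance per condition, and the least-squares slope per input.
#'
#' @param population Optional fixed population; drawn at random when
#'   \code{NULL}.
#' @param inputs Indices of the inputs to sweep (default all).
#' @param rates Swept input rates, spikes/s (0 silences the input).
#' @param base_rate Rate of the non-swept inputs, spikes/s.
#' @param duration Seconds per condition.
#' @param seed Master seed.
#' @param dt Integration step, s.
#' @param model Unitary conductance model.
#' @return Results bundle with \code{$sweeps} (input, amplitude,
#'   input_rate, output_rate, gI_mean) and \code{$slopes}.
#' @export
run_fig5 <- function(population = NULL, inputs = NULL,
                     rates = c(0, 40, 80, 120, 160), base_rate = 80,
                     duration = 100, seed = 1, dt = 2e-5,
                     model = size_distribution_model()) {
  params <- neuron_params("fig4")
  set.seed(child_seed(seed, 0))
  pop <- if (is.null(population))
    draw_input_population(model, total_target = 200, rate = base_rate)
  else population
  if (is.null(inputs)) inputs <- seq_len(nrow(pop$inputs))
  rows <- list()
  cond <- 0L
  for (j in inputs) {
    for (r in rates) {
      cond <- cond + 1L
      pj <- pop
      pj$inputs$rate[j] <- r
      sim <- simulate_cbn_population(params, pj, duration, dt = dt,
                                     seed = child_seed(seed, cond))
      rows[[cond]] <- data.frame(input = j,
                                 amplitude = pop$inputs$amplitude[j],
                                 input_rate = r,
                                 output_rate = firing_rate(sim),
                                 gI_mean = sim$gI_stats$mean)
    }
  }
  sweeps <- do.call(rbind, rows)
  slopes <- do.call(rbind, lapply(split(sweeps, sweeps$input), function(d)
    data.frame(input = d$input[1L], amplitude = d$amplitude[1L],
               slope = rate_code_slope(d$input_rate, d$output_rate))))
  new_bundle(list(figure = "fig5", rates = rates, base_rate = base_rate,
                  duration = duration, seed = seed, dt = dt,
                  preset = "fig4"),
             sweeps = sweeps, slopes = slopes, population = pop$inputs)
}

#' Firing-rate change caused by synchronizing a set of inputs
#'
#' Simulates a population twice with matched settings - once with
#' all-singleton synchrony groups and once with the inputs in \code{idx}
#' sharing a single spike train - and reports the percent change in CbN
#' firing rate.
#'
#' @param pop An [input_population()].
#' @param idx Indices of the inputs to synchronize.
#' @param params Neuron preset (fig4 by default).
#' @param duration Seconds per condition.
#' @param seed Master seed (the two conditions use derived seeds).
#' @param dt Integration step, s.
#' @return List with \code{base_rate}, \code{sync_rate},
#'   \code{pct_change}, and the synchronized amplitude.
#' @export
synchrony_rate_change <- function(pop, idx, params = neuron_params("fig4"),
                                  duration = 200, seed = 1, dt = 2e-5) {
  stopifnot(length(idx) >= 2)
  base <- simulate_cbn_population(params, pop, duration, dt = dt,
                                  seed = child_seed(seed, 1))
  groups <- as.character(seq_len(nrow(pop$inputs)))
  groups[idx] <- "synced"
  sync <- simulate_cbn_population(params, apply_synchrony(pop, groups),
                                  duration, dt = dt,
                                  seed = child_seed(seed, 2))
  r0 <- firing_rate(base); r1 <- firing_rate(sync)
  list(base_rate = r0, sync_rate = r1,
       pct_change = 100 * (r1 - r0) / r0,
       sync_amplitude = sum(pop$inputs$amplitude[idx]))
}

#' Synchrony-sweep protocol
#'
#' Draws random 200 nS populations (or the 40 x 5 nS uniform set) at
#' 80 Hz and, for each of \code{n_subsets} random input subsets,
#' synchronizes the subset and records the firing rate, the percentage
#' of synchronized inputs, their total amplitude and the conductance CV
#' (fig4 preset).
#'
#' @param n_pops Number of populations.
#' @param n_subsets Random subsets per population.
#' @param duration Seconds per condition.
#' @param uniform Use the uniform 40 x 5 nS set instead of random draws.
#' @param seed Master seed.
#' @param dt Integration step, s.
#' @param model Unitary conductance model.
#' @return Results bundle with \code{$conditions} (one row per subset)
#'   and \code{$baseline} (unsynchronized rate per population).
#' @export
run_fig6 <- function(n_pops = 2, n_subsets = 10, duration = 200,
                     uniform = FALSE, seed = 1, dt = 2e-5,
                     model = size_distribution_model()) {
  params <- neuron_params("fig4")
  conditions <- list(); baseline <- list()
  cond <- 0L
  for (p in seq_len(n_pops)) {
    set.seed(child_seed(seed, p))
    pop <- if (uniform) simplified_population("uniform40")
    else draw_input_population(model, total_target = 200, rate = 80)
    n <- nrow(pop$inputs)
    base <- simulate_cbn_population(params, pop, duration, dt = dt)
    baseline[[p]] <- data.frame(pop = p, rate = firing_rate(base),
                                gI_cv = base$gI_stats$cv)
    for (s in seq_len(n_subsets)) {
      cond <- cond + 1L
      m <- sample(2:n, 1L)
      idx <- sample(n, m)
      groups <- as.character(seq_len(n))
      groups[idx] <- "synced"
      sim <- simulate_cbn_population(params, apply_synchrony(pop, groups),
                                     duration, dt = dt)
      conditions[[cond]] <- data.frame(
        pop = p, subset = s, n_synced = m,
        pct_synced = 100 * m / n,
        amp_synced = sum(pop$inputs$amplitude[idx]),
        rate = firing_rate(sim), gI_cv = sim$gI_stats$cv)
    }
  }
  new_bundle(list(figure = "fig6", n_pops = n_pops, n_subsets = n_subsets,
                  duration = duration, uniform = uniform, seed = seed,
                  dt = dt, preset = "fig4"),
             conditions = do.call(rbind, conditions),
             baseline = do.call(rbind, baseline))
}

#' Pause protocol
#'
#' Simulates a population with and without brief synchronous pauses
#' (spikes of the paused inputs deleted for \code{width} seconds at
#' \code{interval} spacing) and reports the overall firing-rate fold
#' change plus the pause-aligned normalized PSTH.
#'
#' @param population \code{"nonuniform"} (random 200 nS draw, fig8
#'   preset) or \code{"uniform"} (40 x 5 nS, fig8-uniform preset), or an
#'   [input_population()] used with the fig8 preset.
#' @param n_draws Number of population draws (nonuniform case).
#' @param duration Seconds per condition.
#' @param interval Pause period, s.
#' @param width Pause width, s.
#' @param paused Indices of paused inputs (default all).
#' @param seed Master seed.
#' @param dt Integration step, s.
#' @param model Unitary conductance model.
#' @return Results bundle with \code{$draws} (rate_base, rate_paused,
#'   fold, normalized peak and peak time per draw).
#' @export
run_fig8 <- function(population = c("nonuniform", "uniform"), n_draws = 1,
                     duration = 1600, interval = 0.020, width = 0.002,
                     paused = NULL, seed = 1, dt = 2e-5,
                     model = size_distribution_model()) {
  fixed_pop <- NULL
  if (inherits(population, "input_population")) {
    fixed_pop <- population
    population <- "custom"
  } else population <- match.arg(population)
  params <- neuron_params(if (population == "uniform") "fig8-uniform"
                          else "fig8")
  rows <- list()
  for (d in seq_len(if (population == "nonuniform") n_draws else 1L)) {
    set.seed(child_seed(seed, d))
    pop <- switch(population,
                  uniform = simplified_population("uniform40"),
                  nonuniform = draw_input_population(model,
                                                     total_target = 200,
                                                     rate = 80),
                  custom = fixed_pop)
    onsets <- periodic_onsets(duration, interval)
    grp <- if (is.null(paused)) NULL
           else unique(pop$inputs$sync_group[paused])
    base <- simulate_cbn_population(params, pop, duration, dt = dt,
                                    seed = child_seed(seed, 100 + d))
    paused_sim <- simulate_cbn_population(
      params, pop, duration, dt = dt, seed = child_seed(seed, 200 + d),
      pauses = list(onsets = onsets, width = width, groups = grp))
    r0 <- firing_rate(base); r1 <- firing_rate(paused_sim)
    ps <- pause_psth(paused_sim, onsets[onsets >= 1],
                     window = c(-10, min(15, interval * 1e3 - 2)))
    rows[[d]] <- data.frame(draw = d, n_inputs = nrow(pop$inputs),
                            total_nS = pop$total_conductance,
                            rate_base = r0, rate_paused = r1,
                            fold = r1 / r0, peak = ps$peak,
                            peak_time = ps$peak_time)
  }
  new_bundle(list(figure = "fig8", population = population,
                  n_draws = n_draws, duration = duration,
                  interval = interval, width = width, seed = seed,
                  dt = dt, preset = params$preset),
             draws = do.call(rbind, rows))
}
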