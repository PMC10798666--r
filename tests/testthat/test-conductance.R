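test_that("biexponential kernel peak and integral match quadrature", {
  k <- unitary_kernel(0.1, 2.5, 1)
  # closed-form peak time (tau_r tau_d/(tau_d - tau_r)) log(tau_d/tau_r)
  expect_equal(k$peak_time, 0.25 / 2.4 * log(25), tolerance = 1e-12)
  expect_equal(k$peak_time, 0.3353, tolerance = 1e-4)
  # independent quadrature oracle for the integral
  quad <- integrate(function(t) kernel_eval(k, t), 0, 0.1,
                    rel.tol = 1e-10)$value
  expect_equal(k$integral, quad, tolerance = 1e-8)
  expect_equal(k$integral * 1e3, 2.8589, tolerance = 1e-4)
  # peak value equals the declared amplitude
  expect_equal(kernel_eval(k, k$peak_time * 1e-3), 1, tolerance = 1e-12)
  expect_equal(kernel_eval(k, 0), 0)
  expect_equal(kernel_eval(k, -1e-3), 0)

  ke <- excitatory_kernel()
  quad_e <- integrate(function(t) kernel_eval(ke, t), 0, 0.1,
                      rel.tol = 1e-10)$value
  expect_equal(ke$integral, quad_e, tolerance = 1e-8)
  expect_equal(ke$integral * 1e3, 0.68373, tolerance = 1e-4)

  expect_error(unitary_kernel(2.5, 0.1), "smaller")
  expect_error(unitary_kernel(1, 1), "smaller")
})

test_that("a single spike reproduces the shifted kernel exactly", {
  k <- unitary_kernel(0.1, 2.5, 5)
  tr <- spike_train(0.1, 0.2)
  g <- conductance_from_train(tr, k, dt = 2e-5)
  tt <- (seq_along(g$values) - 1) * g$dt
  expect_equal(g$values, kernel_eval(k, tt - 0.1), tolerance = 1e-12)
  # sampled maximum is within one dt of the analytic peak
  expect_lte(max(g$values), k$amplitude)
  expect_gte(max(g$values), kernel_eval(k, (k$peak_time - 0.02) * 1e-3))
  # coarse dt warns
  expect_warning(conductance_from_train(tr, k, dt = 1e-4), "undersampled")
})

test_that("superposition is linear to floating tolerance", {
  k <- inhibitory_kernel(4)
  t1 <- sample_spike_train(isi_poisson_model(50), 2, seed = 1)
  t2 <- sample_spike_train(isi_poisson_model(70), 2, seed = 2)
  merged <- spike_train(sort(c(t1$times, t2$times)), 2)
  g12 <- conductance_from_train(merged, k)
  gsum <- conductance_from_train(t1, k)$values +
    conductance_from_train(t2, k)$values
  expect_lt(max(abs(g12$values - gsum)), 1e-9)
})

test_that("trace means obey Campbell's theorem", {
  k <- inhibitory_kernel(5)
  tr <- sample_spike_train(isi_lognormal_model(80), 120, seed = 3)
  g <- conductance_from_train(tr, k)
  expected <- 5 * 2.858825e-3 * 80
  expect_lt(abs(mean(g$values[-(1:5e4)]) - expected), 3 * chunk_se(g))

  pop <- simplified_population("uniform40")
  trains <- population_trains(pop, 120, seed = 4)
  gt <- total_inhibitory_conductance(pop, trains)
  expect_lt(abs(trace_stats(gt)$mean - 45.74), 3 * chunk_se(gt))
})

test_that("per-size-class components sum to the total conductance", {
  pop <- simplified_population("fig2")
  trains <- population_trains(pop, 10, seed = 5)
  g <- total_inhibitory_conductance(pop, trains, components = TRUE)
  comp_sum <- g$components$small$values + g$components$medium$values +
    g$components$large$values
  expect_lt(max(abs(comp_sum - g$values)), 1e-9)
  expect_true(all(g$values >= 0))
})

test_that("synchronized small inputs are bit-identical to one merged input", {
  shared <- sample_spike_train(isi_lognormal_model(80), 5, seed = 6)
  pop10 <- input_population(rep(5, 10), sync_group = rep("g", 10))
  g10 <- total_inhibitory_conductance(pop10, list(g = shared), duration = 5)
  pop1 <- input_population(50, sync_group = "g")
  g1 <- total_inhibitory_conductance(pop1, list(g = shared), duration = 5)
  expect_identical(g10$values, g1$values)
})

test_that("excitatory conductance matches its Campbell mean", {
  g0 <- excitatory_conductance(0, duration = 1)
  expect_true(all(g0$values == 0))
  g20 <- excitatory_conductance(20000, duration = 60, seed = 7)
  expect_lt(abs(trace_stats(g20)$mean - 13.67), 3 * chunk_se(g20))
  g23 <- excitatory_conductance(23650, duration = 60, seed = 8)
  expect_lt(abs(trace_stats(g23)$mean - 16.17), 3 * chunk_se(g23))
})

test_that("trace statistics handle constant and degenerate traces", {
  const <- cbnsim:::new_trace(rep(7, 1000), dt = 1e-2)
  s <- trace_stats(const, burn_in = 1)
  expect_equal(s$cv, 0)
  zero <- cbnsim:::new_trace(numeric(1000), dt = 1e-2)
  expect_true(is.na(trace_stats(zero, burn_in = 1)$cv))
  expect_error(trace_stats(const, burn_in = 20), "burn_in")
})

test_that("fewer, larger inputs give a larger conductance CV at matched mean", {
  dur <- 80
  big <- uniform_population(10, 20)
  small <- simplified_population("uniform40")
  g_big <- total_inhibitory_conductance(big, population_trains(big, dur, seed = 9))
  g_small <- total_inhibitory_conductance(small,
                                          population_trains(small, dur, seed = 10))
  expect_gt(trace_stats(g_big)$cv, trace_stats(g_small)$cv)
  # and the drawn nonuniform set beats uniform40 too
  pop <- draw_input_population(size_distribution_model(), 200, seed = 11)
  g_non <- total_inhibitory_conductance(pop, population_trains(pop, dur, seed = 11))
  expect_gt(trace_stats(g_non)$cv, trace_stats(g_small)$cv)
})

test_that("STA triggered on independent random times is flat at the mean", {
  pop <- simplified_population("uniform40")
  g <- total_inhibitory_conductance(pop, population_trains(pop, 60, seed = 12))
  set.seed(13)
  ref <- spike_train(sort(runif(2000, 0.1, 59.9)), 60)
  sta <- spike_triggered_average(g, ref)
  m <- trace_stats(g, burn_in = 0.05)$mean
  se <- sd(g$values) / sqrt(attr(sta, "n_ref"))
  expect_lt(max(abs(sta$g - m)), 5 * se)
})

test_that("pre-spike STA dip sharpens with firing rate and vanishes for Poisson", {
  dur <- 60
  sta_for <- function(variant, seed) {
    pop <- simplified_population(variant)
    trains <- population_trains(pop, dur, seed = seed)
    g <- total_inhibitory_conductance(pop, trains)
    spike_triggered_average(g, trains[[1]])
  }
  d49 <- sta_dip(sta_for("fig3-49", 14))
  d122 <- sta_dip(sta_for("fig3-122", 15))
  expect_gt(d122$depth, d49$depth)
  expect_lt(d122$width, d49$width)
  # Poisson inputs: no pre-spike decrease (flat before the triggering IPSG)
  pop <- simplified_population("fig3-poisson")
  trains <- population_trains(pop, dur, seed = 16)
  g <- total_inhibitory_conductance(pop, trains)
  sta <- spike_triggered_average(g, trains[[1]])
  pre <- sta$g[sta$lag_ms < -1]
  m <- mean(sta$g[abs(sta$lag_ms) > 7])
  se <- sd(g$values) / sqrt(attr(sta, "n_ref"))
  expect_lt(m - min(pre), 4 * se)
})
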