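test_that("staircase amplitudes recover the transduction line", {
  sp <- sensor_spec()
  ct <- short_staircase(sp)
  amps <- extract_cycle_amplitudes(ct)
  expect_equal(nrow(amps), 15)
  expect_equal(amps$amplitude[15], 1.038, tolerance = 0.005 / 1.038)
  expect_true(all(diff(amps$amplitude) > 0)) # monotone in pressure

  fit <- suppressWarnings(fit_sensitivity(amps$pressure_kpa / 1000,
                                          amps$amplitude))
  expect_equal(round(fit$slope, 2), 1.19)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-6)

  in_fit <- local({
    cti <- short_staircase(sensor_spec("in-insole"))
    a <- extract_cycle_amplitudes(cti)
    suppressWarnings(fit_sensitivity(a$pressure_kpa / 1000, a$amplitude))
  })
  expect_equal(round(in_fit$slope, 2), 0.55)

  # constant trace: all amplitudes zero
  const <- capacitance_trace(rep(sp$C0, length(ct$values)), ct$sample_rate,
                             c0 = sp$C0)
  attr(const, "protocol") <- attr(ct, "protocol")
  expect_equal(extract_cycle_amplitudes(const)$amplitude, rep(0, 15))

  short <- attr(ct, "protocol")
  short$duration_per_level <- 1.5 # one cycle only
  expect_error(extract_cycle_amplitudes(ct, short), "2 cycles")
})

test_that("sensitivity fit handles exact and degenerate input", {
  f <- suppressWarnings(fit_sensitivity(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)
  expect_error(fit_sensitivity(c(1, 1, 1), c(0, 1, 2)), "degenerate")
  expect_error(fit_sensitivity(c(0, 1), c(0, 1)), "3 points")
})

test_that("degree of hysteresis matches the analytic loop area", {
  expect_equal(degree_of_hysteresis(default_hysteresis_loop()), 9.8,
               tolerance = 0.1 / 9.8)

  # zero-gap loop
  p <- seq(1, 800, length.out = 200)
  flat <- hysteresis_loop(p, 1.19 * p / 1000, 1.19 * p / 1000)
  expect_equal(degree_of_hysteresis(flat), 0)

  # oracle: closed form 100 * alpha * p_max / (3 S) for random branch pairs
  set.seed(42)
  for (i in 1:20) {
    S <- runif(1, 0.3, 2); alpha <- runif(1, 0.05, 0.8)
    pm <- runif(1, 200, 872.4)
    sp <- sensor_spec(S = S, alpha = alpha, p_max = pm)
    dh <- degree_of_hysteresis(default_hysteresis_loop(sp, n = 1000))
    expect_equal(dh, 100 * alpha * (pm / 1000) / (3 * S), tolerance = 0.001)
  }

  expect_error(degree_of_hysteresis(hysteresis_loop(0:2, rep(0, 3), 0:2)),
               "undefined")
})

test_that("response and recovery estimators hit the printed timing", {
  sp <- sensor_spec()
  rt <- response_recovery_times(full_step(sp))
  expect_equal(rt$response_time * 1000, 142, tolerance = 2 / 142)
  expect_equal(rt$recovery_time * 1000, 160, tolerance = 2 / 160)

  # doubling both taus doubles both times (t = tau ln 9 scaling)
  sp2 <- sensor_spec(tau_rise = 2 * sp$tau_rise, tau_fall = 2 * sp$tau_fall)
  rt2 <- response_recovery_times(full_step(sp2))
  expect_equal(rt2$response_time, 2 * rt$response_time, tolerance = 0.02)
  expect_equal(rt2$recovery_time, 2 * rt$recovery_time, tolerance = 0.02)

  # scale invariance: thresholds are relative
  st <- full_step(sp)
  scaled <- capacitance_trace(st$values * 3.7e3, st$sample_rate)
  rts <- response_recovery_times(scaled)
  expect_equal(rts$response_time, rt$response_time)
  expect_equal(rts$recovery_time, rt$recovery_time)

  # instantaneous step: both within one sample interval
  inst <- capacitance_trace(c(rep(0, 50), rep(1, 50), rep(0, 50)), 1000)
  ri <- response_recovery_times(inst)
  expect_lte(ri$response_time, 1e-3)
  expect_lte(ri$recovery_time, 1e-3)

  expect_error(response_recovery_times(capacitance_trace(rep(1, 10), 100)),
               "edge")
})

test_that("steady-cycle amplitude is cadence-invariant for the default model", {
  sp <- sensor_spec()
  cadences <- c(30, 40, 50, 60, 70)
  traces <- lapply(cadences, function(cad) {
    simulate_capacitance_trace(periodic_loading(872.4, cad, n_cycles = 5),
                               sp, noise_sd = 0)
  })
  names(traces) <- cadences
  expect_lt(frequency_invariance(traces), 0.01)

  # identical traces at two cadences give zero deviation
  same <- traces[c("40", "40")]
  expect_equal(frequency_invariance(same, c(40, 40)), 0)

  # a slow recovery (10x tau_fall) is detected at high cadence
  slow <- sensor_spec(tau_fall = 10 * sp$tau_fall)
  traces_slow <- lapply(cadences, function(cad) {
    simulate_capacitance_trace(periodic_loading(872.4, cad, n_cycles = 5),
                               slow, noise_sd = 0)
  })
  names(traces_slow) <- cadences
  expect_gt(frequency_invariance(traces_slow), 0.05)

  expect_error(frequency_invariance(traces[1]), "two cadences")
})

test_that("durability drift is null for the stable model and sees injected drift", {
  sp <- sensor_spec()
  # scaled-down durability run: 200 cycles at 38 steps/min
  tr <- periodic_loading(872.4, 38, n_cycles = 200)
  ct <- simulate_capacitance_trace(tr, sp, noise_sd = 0)
  attr(ct, "protocol") <- attr(tr, "protocol")
  dd <- durability_drift(ct, window = 60)
  expect_equal(dd$c0_drift, 0, tolerance = 1e-6)
  expect_equal(dd$cf_drift, 0, tolerance = 1e-6)

  # +5% linear drift across the run
  total <- length(ct$values) / ct$sample_rate
  drifted <- ct
  drifted$values <- ct$values * (1 + 0.05 * trace_times(ct) / total)
  dd2 <- durability_drift(drifted, window = 60)
  expect_equal(dd2$c0_drift, 0.05, tolerance = 0.01 / 0.05)
  expect_equal(dd2$cf_drift, 0.05, tolerance = 0.01 / 0.05)

  # window of half the trace tiles it exactly
  dd3 <- durability_drift(ct, window = total / 2)
  expect_equal(dd3$c0_drift, 0, tolerance = 1e-6)
  expect_error(durability_drift(ct, window = total), "two windows")
})
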