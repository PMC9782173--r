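test_that("series capacitance matches the closed form and its limits", {
  stack <- dielectric_stack(plate_area = 1.65130e-4, d1 = 1.0e-3, k1 = 1.0,
                            d2 = 0.2e-3, k2 = 4.2)
  expect_equal(series_capacitance(stack), 1.3956e-12, tolerance = 1e-4)

  # single-dielectric limit: parallel-plate formula
  single <- dielectric_stack(1.65130e-4, d1 = 1.0e-3, k1 = 2.5, d2 = 0)
  expect_equal(series_capacitance(single),
               8.854e-12 * 1.65130e-4 * 2.5 / 1.0e-3)

  # linear in plate area
  doubled <- dielectric_stack(2 * 1.65130e-4, d1 = 1.0e-3, d2 = 0.2e-3)
  base <- dielectric_stack(1.65130e-4, d1 = 1.0e-3, d2 = 0.2e-3)
  expect_equal(series_capacitance(doubled), 2 * series_capacitance(base))

  # dimensional sanity: C scales as 1/thickness when both layers scale
  thick <- dielectric_stack(1.65130e-4, d1 = 3e-3, d2 = 0.6e-3)
  expect_equal(series_capacitance(thick), series_capacitance(base) / 3)

  # monotone in each parameter
  expect_gt(series_capacitance(dielectric_stack(1.65130e-4, k1 = 2)),
            series_capacitance(dielectric_stack(1.65130e-4, k1 = 1)))
  expect_lt(series_capacitance(dielectric_stack(1.65130e-4, d1 = 2e-3)),
            series_capacitance(dielectric_stack(1.65130e-4, d1 = 1e-3)))

  expect_error(dielectric_stack(0), "plate_area")
  expect_error(dielectric_stack(1e-4, d1 = 0, d2 = 0), "d1 \\+ d2")
})

test_that("mass to pressure reproduces the rig conversions", {
  expect_equal(round(mass_to_pressure(0.7), 1), 41.5)
  expect_equal(round(mass_to_pressure(14.7), 1), 872.4)
  expect_equal(mass_to_pressure(0), 0)
  expect_equal(round(mass_to_pressure(1.7) - mass_to_pressure(0.7), 2), 59.35)
  expect_error(mass_to_pressure(-1), "mass")
})

test_that("static response branches close the loop and order correctly", {
  sp <- sensor_spec(S = 1.19, alpha = 0.4010)
  expect_equal(static_response(0, sp, "loading"), 0)
  expect_equal(static_response(0, sp, "unloading", p_max_branch = 872.4), 0)
  expect_equal(static_response(872.4, sp, "unloading", p_max_branch = 872.4),
               static_response(872.4, sp, "loading"))

  expect_equal(static_response(436.2, sp, "loading"), 0.5191,
               tolerance = 1e-4)
  expect_equal(static_response(436.2, sp, "unloading", p_max_branch = 872.4),
               0.5954, tolerance = 1e-4)

  # unloading >= loading over the whole branch, strict inside
  p <- seq(0, 872.4, length.out = 101)
  lo <- static_response(p, sp, "loading")
  un <- static_response(p, sp, "unloading", p_max_branch = 872.4)
  expect_true(all(un >= lo))
  expect_true(all(un[2:100] > lo[2:100]))

  # strictly increasing on each branch for the default parameters
  expect_true(all(diff(lo) > 0))
  expect_true(all(diff(un) > 0))

  expect_error(static_response(1000, sp, "loading"), "range")
  expect_error(static_response(-1, sp, "loading"), "range")
})

test_that("first-order dynamics settle, bound, and time correctly", {
  sp <- sensor_spec()
  # constant input is a fixed point
  const <- apply_dynamics(rep(0.5, 100), sp, sample_rate = 1000, y0 = 0.5)
  expect_equal(const, rep(0.5, 100))

  # output bounded by input extrema
  x <- c(rep(0, 500), rep(1, 500), rep(0.2, 500))
  y <- apply_dynamics(x, sp, sample_rate = 1000)
  expect_true(all(y >= min(x) - 1e-12 & y <= max(x) + 1e-12))

  # 10-90% interval of a step is tau * ln 9
  step <- pressure_trace(c(rep(0, 1000), rep(872.4, 2000), rep(0, 2000)), 1000)
  resp <- apply_dynamics(step, sp)
  rt <- response_recovery_times(resp)
  expect_equal(rt$response_time, 0.142, tolerance = 2e-3 / 0.142)
  expect_equal(rt$recovery_time, 0.160, tolerance = 2e-3 / 0.160)
})

test_that("capacitance simulation is deterministic and exact when noiseless", {
  sp <- sensor_spec()
  zero <- pressure_trace(rep(0, 200), 1000)
  ct <- simulate_capacitance_trace(zero, sp, noise_sd = 0)
  expect_equal(ct$values, rep(sp$C0, 200))
  expect_identical(ct$units, "F")

  sq <- periodic_loading(872.4, 40, n_cycles = 4)
  a <- simulate_capacitance_trace(sq, sp, noise_sd = 0.01, seed = 11)
  b <- simulate_capacitance_trace(sq, sp, noise_sd = 0.01, seed = 11)
  expect_identical(a$values, b$values)
  expect_error(simulate_capacitance_trace(sq, sp, noise_sd = 0.01), "seed")

  # steady square-wave amplitude is S * P
  ct <- simulate_capacitance_trace(sq, sp, noise_sd = 0)
  rel <- ct$values / sp$C0 - 1
  expect_equal(max(rel), 1.19 * 0.8724, tolerance = 0.005)

  over <- pressure_trace(rep(900, 10), 1000)
  expect_error(simulate_capacitance_trace(over, sp, 0), "working range")
})

test_that("sensor spec validates its invariants and profiles", {
  expect_equal(sensor_spec("out-of-insole")$S, 1.19)
  expect_equal(sensor_spec("in-insole")$S, 0.55)
  expect_equal(sensor_spec()$alpha, 3 * 1.19 * 0.098 / 0.8724,
               tolerance = 1e-12)
  expect_equal(sensor_spec()$tau_rise, 0.142 / log(9))
  expect_error(sensor_spec(S = -1), "S")
  expect_error(sensor_spec(p_min = 900), "p_min")
})
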