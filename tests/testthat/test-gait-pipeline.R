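test_that("calibration inverts the linear transduction and flags the LoD", {
  sp <- sensor_spec("in-insole")
  # dC/C0 = 0.2475 at S = 0.55 is 450 kPa
  ids <- c("T1", "T2", "T3", "T4", "ME1", "ME2", "ME3", "ME4", "ME5",
           "M1", "M2", "M3", "M4", "H1", "H2", "H3")
  traces <- lapply(ids, function(id) {
    capacitance_trace(sp$C0 * c(1, 1.2475, 1.01), 100, c0 = sp$C0)
  })
  names(traces) <- ids
  cal <- calibrate(traces)
  expect_equal(unname(cal$frames[1, "H1"]), 0)
  expect_equal(unname(cal$frames[2, "H1"]), 450, tolerance = 1e-9)
  lod <- attr(cal, "below_lod")
  expect_false(lod[2, "H1"])
  expect_true(lod[3, "H1"]) # 18.2 kPa, below the 41.5 kPa LoD
  expect_error(calibrate(traces[1:3]), "16 channels")
})

test_that("center of pressure is the pressure-weighted centroid", {
  lay <- default_layout()
  frame <- setNames(rep(0, 16), lay$sensors$id)

  cop0 <- center_of_pressure(frame, lay)
  expect_false(cop0$valid) # total below 1 kPa

  f1 <- frame; f1["H1"] <- 100
  cop1 <- center_of_pressure(f1, lay)
  h1 <- lay$sensors[lay$sensors$id == "H1", ]
  expect_equal(c(cop1$x, cop1$y), c(h1$x, h1$y))

  f2 <- frame; f2["H1"] <- 80; f2["T1"] <- 80
  cop2 <- center_of_pressure(f2, lay)
  t1 <- lay$sensors[lay$sensors$id == "T1", ]
  expect_equal(cop2$x, (h1$x + t1$x) / 2)
  expect_equal(cop2$y, (h1$y + t1$y) / 2)

  # any valid CoP lies in the convex hull of the sensor coordinates
  set.seed(3)
  for (i in 1:20) {
    f <- setNames(runif(16, 0, 400), lay$sensors$id)
    cop <- center_of_pressure(f, lay)
    expect_true(cop$x >= min(lay$sensors$x) && cop$x <= max(lay$sensors$x))
    expect_true(cop$y >= min(lay$sensors$y) && cop$y <= max(lay$sensors$y))
  }
})

test_that("CoP advances heel to forefoot within each stance", {
  fr <- simulate_gait(gait_spec(), n_cycles = 3)
  cop <- cop_trajectory(fr)
  lay <- default_layout()
  hs <- fr$labels == "heel strike"
  ho <- fr$labels == "heel off"
  expect_true(all(cop$valid[hs]))
  expect_true(all(cop$y_mm[hs] <= 0.30 * lay$insole_length))
  expect_true(all(cop$y_mm[ho] >= 0.60 * lay$insole_length))
})

test_that("heatmap has 227 cells on the ten-level 0-450 kPa scale", {
  lay <- default_layout()
  grid <- insole_grid(lay)
  expect_equal(nrow(grid), 227)
  expect_true(all(grid$sensor_id %in% lay$sensors$id))

  frame <- setNames(rep(0, 16), lay$sensors$id)
  hm0 <- grid_heatmap(frame, lay)
  expect_equal(nrow(hm0), 227)
  expect_true(all(hm0$level == 0))

  f1 <- frame; f1["ME3"] <- 450
  hm1 <- grid_heatmap(f1, lay)
  expect_true(all(hm1$level[hm1$sensor_id == "ME3"] == 9))
  expect_true(all(hm1$level[hm1$sensor_id != "ME3"] == 0))
  # conservation: max cell pressure equals max sensor pressure
  expect_equal(max(hm1$pressure), max(f1))

  # saturation above the scale maximum still caps at 9
  f2 <- frame; f2["H1"] <- 800
  expect_true(all(grid_heatmap(f2, lay)$level <= 9))

  # nonzero-cell count is monotone in the number of active sensors
  f3 <- f1; f3["H1"] <- 300
  expect_gt(sum(grid_heatmap(f3, lay)$level > 0),
            sum(grid_heatmap(f1, lay)$level > 0))
})

test_that("segmentation recovers the ground-truth phases and boundaries", {
  fr <- simulate_gait(gait_spec(), n_cycles = 3, sample_rate = 100)
  seg <- segment_phases(fr)
  phases <- c("heel strike", "foot flat", "midstance", "heel off", "toe off",
              "swing")
  expect_equal(rle(seg$labels)$values, rep(phases, 3))
  expect_equal(length(seg$cycle_starts), 3)

  # phase boundaries within 2 frames of ground truth at 100 Hz
  gt_bounds <- cumsum(rle(fr$labels)$lengths)
  sg_bounds <- cumsum(rle(seg$labels)$lengths)
  expect_equal(length(gt_bounds), length(sg_bounds))
  expect_true(all(abs(gt_bounds - sg_bounds) <= 2))

  # heel-only frame is heel strike
  ids <- colnames(fr$frames)
  one <- setNames(rep(0, 16), ids)
  one[c("H1", "H2", "H3")] <- 200
  single <- pressure_frames(matrix(one, nrow = 1,
                                   dimnames = list(NULL, ids)), 100)
  expect_equal(segment_phases(single, median_window = 1)$labels, "heel strike")

  # all-zero series is all swing, with a warning
  zero <- pressure_frames(matrix(0, nrow = 20, ncol = 16,
                                 dimnames = list(NULL, ids)), 100)
  expect_warning(seg0 <- segment_phases(zero), "all-swing")
  expect_true(all(seg0$labels == "swing"))
})

test_that("zone summaries report peaks with phase of occurrence", {
  fr <- simulate_gait(gait_spec(), n_cycles = 3)
  summ <- zone_summaries(fr, segment_phases(fr))
  me5 <- summ$sensors[summ$sensors$sensor == "ME5", ]
  expect_equal(me5$peak_kpa, 380, tolerance = 0.01)
  # ME5 peak falls between the end of heel strike and the start of heel off
  expect_true(me5$phase %in% c("foot flat", "midstance"))
  expect_false(summ$arch_exceeds_150)
  expect_equal(summ$zones$peak_kpa[summ$zones$zone == "metatarsals"],
               me5$peak_kpa)

  zero <- pressure_frames(matrix(0, nrow = 5, ncol = 16,
                                 dimnames = list(NULL, colnames(fr$frames))),
                          100)
  expect_true(all(zone_summaries(zero)$sensors$peak_kpa == 0))
})
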