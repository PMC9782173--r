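# Synthetic gait generator: 16-channel plantar-pressure frame series over
# repeated gait cycles with ground-truth phase labels.

SENSOR_IDS <- c("T1", "T2", "T3", "T4",
                "ME1", "ME2", "ME3", "ME4", "ME5",
                "M1", "M2", "M3", "M4",
                "H1", "H2", "H3")

ZONES <- c(T1 = "phalanges", T2 = "phalanges", T3 = "phalanges",
           T4 = "phalanges",
           ME1 = "metatarsals", ME2 = "metatarsals", ME3 = "metatarsals",
           ME4 = "metatarsals", ME5 = "metatarsals",
           M1 = "arch", M2 = "arch", M3 = "arch", M4 = "arch",
           H1 = "calcaneus", H2 = "calcaneus", H3 = "calcaneus")

PHASES <- c("heel strike", "foot flat", "midstance", "heel off", "toe off",
            "swing")

#' Insole sensor layout
#'
#' Sixteen sensors in four anatomical zones (phalanges T1-T4, metatarsals
#' ME1-ME5, plantar arch M1-M4, calcaneus H1-H3) with planar coordinates
#' inside a 250 mm x 85 mm insole outline.
#'
#' @param sensors data.frame with columns `id`, `zone`, `x`, `y` (mm).
#' @param insole_length,insole_width outline bounding box in mm.
#' @param outline named list describing the outline (elliptical by default).
#' @param grid named list with the frozen heatmap raster (`pitch`, `ox`, `oy`).
#' @return An object of class `insole_layout`.
#' @export
insole_layout <- function(sensors, insole_length = 250, insole_width = 85,
                          outline = list(shape = "ellipse", cx = insole_width / 2,
                                         cy = insole_length / 2,
                                         rx = insole_width / 2,
                                         ry = insole_length / 2),
                          grid = list(pitch = 8.47, ox = 0.5, oy = 7.0)) {
  sensors <- as.data.frame(sensors)
  stopifnot(all(c("id", "zone", "x", "y") %in% names(sensors)))
  if (nrow(sensors) != 16L || !setequal(sensors$id, SENSOR_IDS)) {
    stop("layout must contain exactly the 16 sensors T1-T4, ME1-ME5, M1-M4, H1-H3",
         call. = FALSE)
  }
  sensors <- sensors[match(SENSOR_IDS, sensors$id), , drop = FALSE]
  rownames(sensors) <- NULL
  counts <- table(sensors$zone)
  expect <- c(phalanges = 4L, metatarsals = 5L, arch = 4L, calcaneus = 3L)
  if (!all(names(expect) %in% names(counts)) ||
      any(counts[names(expect)] != expect)) {
    stop("zones must partition the sensors 4/5/4/3", call. = FALSE)
  }
  if (any(sensors$x < 0 | sensors$x > insole_width |
          sensors$y < 0 | sensors$y > insole_length)) {
    stop("sensor coordinates outside the insole bounding box", call. = FALSE)
  }
  structure(list(sensors = sensors, insole_length = insole_length,
                 insole_width = insole_width, outline = outline, grid = grid),
            class = "insole_layout")
}

#' Default insole layout
#'
#' Reads the layout table shipped with the package (`extdata/layout.json`): a
#' fixed synthetic coordinate table placing the 16 sensors by anatomical zone
#' on a No. 39 EU outline, heel sensors in the posterior quarter and phalanges
#' in the anterior fifth of the length. All center-of-pressure results are
#' defined relative to this table.
#'
#' @return An [insole_layout()].
#' @export
default_layout <- function() {
  path <- system.file("extdata", "layout.json", package = "smartinsole",
                      mustWork = TRUE)
  read_layout(path)
}

#' @export
print.insole_layout <- function(x, ...) {
  cat(sprintf("<insole_layout: 16 sensors, %g x %g mm>\n",
              x$insole_length, x$insole_width))
  invisible(x)
}

# default per-sensor stance peaks, kPa
default_peak_table <- function() {
  c(T1 = 370, T2 = 0, T3 = 0, T4 = 127,
    ME1 = 320, ME2 = 300, ME3 = 310, ME4 = 340, ME5 = 380,
    M1 = 120, M2 = 100, M3 = 110, M4 = 90,
    H1 = 295, H2 = 250, H3 = 230)
}

# default fractional phase onsets within one gait cycle
default_phase_timing <- function() {
  c("heel strike" = 0, "foot flat" = 0.10, "midstance" = 0.25,
    "heel off" = 0.45, "toe off" = 0.55, "swing" = 0.62)
}

#' Gait-cycle specification
#'
#' Parameters of the synthetic gait generator: cadence, per-sensor stance peak
#' pressures, fractional phase onsets, noise level and seed. The defaults
#' emulate a normal gait cycle at 40 steps/min (1.5 s cycle, stance fraction
#' 0.62) with the per-sensor peak structure of the recorded subject: H1 = 295,
#' T1 = 370, ME5 = 380, T4 = 127 kPa; arch peaks below 150 kPa; middle-toe
#' sensors T2/T3 unloaded.
#'
#' @param cadence steps/min.
#' @param cycle_duration gait-cycle duration in s (default `60/cadence`).
#' @param stance_fraction fraction of the cycle in ground contact.
#' @param peak_table named numeric vector of per-sensor peak pressures in kPa
#'   (all 16 sensor ids).
#' @param phase_timing named numeric vector of fractional onsets for
#'   heel strike, foot flat, midstance, heel off, toe off and swing, strictly
#'   increasing.
#' @param noise_sd additive pressure noise SD in kPa (default 0, noiseless).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @return An object of class `gait_spec`.
#' @export
gait_spec <- function(cadence = 40, cycle_duration = 60 / cadence,
                      stance_fraction = 0.62,
                      peak_table = default_peak_table(),
                      phase_timing = default_phase_timing(),
                      noise_sd = 0, seed = NULL) {
  stopifnot(cadence > 0, cycle_duration > 0,
            stance_fraction > 0, stance_fraction < 1)
  if (!setequal(names(peak_table), SENSOR_IDS)) {
    stop("peak_table must name all 16 sensors", call. = FALSE)
  }
  peak_table <- peak_table[SENSOR_IDS]
  if (any(peak_table < 0)) stop("peaks must be >= 0", call. = FALSE)
  if (!setequal(names(phase_timing), PHASES)) {
    stop("phase_timing must name the six phases", call. = FALSE)
  }
  phase_timing <- phase_timing[PHASES]
  if (any(diff(phase_timing) <= 0) || phase_timing[1] < 0 ||
      phase_timing[length(phase_timing)] >= 1) {
    stop("phase onsets must be strictly increasing within [0, 1)",
         call. = FALSE)
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required for noisy gait simulation", call. = FALSE)
  }
  structure(list(cadence = cadence, cycle_duration = cycle_duration,
                 stance_fraction = stance_fraction, peak_table = peak_table,
                 phase_timing = phase_timing, noise_sd = noise_sd,
                 seed = seed),
            class = "gait_spec")
}

#' Time-indexed 16-channel pressure frames
#'
#' @param frames numeric matrix, one row per frame, 16 named columns (kPa).
#' @param sample_rate frame rate in Hz.
#' @param labels optional per-frame gait-phase labels.
#' @param start_time time of the first frame in s.
#' @return An object of class `pressure_frames`.
#' @export
pressure_frames <- function(frames, sample_rate, labels = NULL,
                            start_time = 0) {
  frames <- as.matrix(frames)
  stopifnot(ncol(frames) == 16L, sample_rate > 0)
  if (!setequal(colnames(frames), SENSOR_IDS)) {
    stop("frame columns must be the 16 sensor ids", call. = FALSE)
  }
  frames <- frames[, SENSOR_IDS, drop = FALSE]
  if (any(frames < 0)) stop("frame values must be >= 0", call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(frames)) {
    stop("labels must match the number of frames", call. = FALSE)
  }
  structure(list(frames = frames, sample_rate = sample_rate,
                 labels = labels, start_time = start_time),
            class = "pressure_frames")
}

#' @export
print.pressure_frames <- function(x, ...) {
  cat(sprintf("<pressure_frames: %d frames x 16 sensors @ %g Hz%s>\n",
              nrow(x$frames), x$sample_rate,
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

# Solve the raised-cosine window [a, b] (cycle fractions) whose value crosses
# `threshold` exactly at t_on and t_off for a bump of height `peak`. Bumps
# with peak <= 2*threshold never dominate; they use the active interval
# directly. Width capped below one cycle so consecutive bumps never overlap.
solve_bump_window <- function(t_on, t_off, peak, threshold) {
  span <- t_off - t_on
  if (peak <= 2 * threshold) return(c(t_on, t_off))
  u <- acos(1 - 2 * threshold / peak) / (2 * pi)
  w <- min(span / (1 - 2 * u), 0.95)
  mid <- (t_on + t_off) / 2
  c(mid - w / 2, mid + w / 2)
}

# raised-cosine bump evaluated at global cycle fraction fg for a per-cycle
# window [a, b]; bumps repeat every cycle (modulo folding), so a window
# reaching past the cycle boundary contributes its tail to the neighbours
bump_value <- function(fg, a, b, peak) {
  w <- b - a
  u <- ((fg - a) %% 1) / w
  ifelse(u <= 1, peak * 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Simulate a gait pressure-frame series
#'
#' Generates `n_cycles` gait cycles of 16-channel plantar pressure at the
#' requested frame rate. Each sensor follows one smooth raised-cosine bump per
#' cycle inside its zone's phase window (calcaneus early stance, arch and
#' metatarsals mid-stance, phalanges late stance); per-sensor maxima equal the
#' spec's `peak_table` in the noiseless case. Zone windows are solved so the
#' zone-mean pressure crosses the 45 kPa activation threshold exactly at the
#' ground-truth phase boundaries. Every frame carries a ground-truth phase
#' label. Deterministic for a fixed seed.
#'
#' @param spec a [gait_spec()].
#' @param layout an [insole_layout()].
#' @param n_cycles number of gait cycles (>= 1).
#' @param sample_rate frame rate in Hz.
#' @param threshold zone activation threshold in kPa used to align the bump
#'   windows with the phase boundaries (default 45, approximately the LoD).
#' @return A [pressure_frames()] with ground-truth `labels`.
#' @examples
#' fr <- simulate_gait(gait_spec(), n_cycles = 1)
#' max(fr$frames[, "H1"]) # ~295 kPa
#' @export
simulate_gait <- function(spec = gait_spec(), layout = default_layout(),
                          n_cycles = 3, sample_rate = 100, threshold = 45) {
  stopifnot(inherits(spec, "gait_spec"), inherits(layout, "insole_layout"),
            n_cycles >= 1)
  if (any(spec$peak_table > P_MAX_KPA)) {
    stop(sprintf("peak pressure exceeds the sensor working range (%g kPa)",
                 P_MAX_KPA), call. = FALSE)
  }
  on <- spec$phase_timing
  # zone active windows (zone mean above threshold), in cycle fractions
  zone_active <- list(
    calcaneus   = c(on[["heel strike"]], on[["midstance"]]),
    metatarsals = c(on[["foot flat"]], on[["toe off"]]),
    arch        = c(on[["foot flat"]], on[["heel off"]]),
    phalanges   = c(on[["heel off"]], on[["swing"]])
  )
  t_total <- n_cycles * spec$cycle_duration
  n <- round(t_total * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  fg <- t / spec$cycle_duration # global cycle fraction

  frames <- matrix(0, nrow = n, ncol = 16L,
                   dimnames = list(NULL, SENSOR_IDS))
  for (zone in names(zone_active)) {
    ids <- names(ZONES)[ZONES == zone]
    zone_peak <- mean(spec$peak_table[ids])
    win <- solve_bump_window(zone_active[[zone]][1], zone_active[[zone]][2],
                             zone_peak, threshold)
    for (id in ids) {
      pk <- spec$peak_table[[id]]
      if (pk > 0) frames[, id] <- bump_value(fg, win[1], win[2], pk)
    }
  }
  if (spec$noise_sd > 0) {
    frames <- with_seed(spec$seed, {
      pmax(frames + matrix(rnorm(length(frames), sd = spec$noise_sd),
                           nrow = n), 0)
    })
  }
  frac <- fg %% 1
  labels <- as.character(cut(frac, breaks = c(on, 1), labels = PHASES,
                             right = FALSE, include.lowest = TRUE))
  labels[is.na(labels)] <- "swing" # frames before a nonzero heel-strike onset
  pressure_frames(frames, sample_rate, labels = labels)
}

#' Convert pressure frames to per-channel capacitance traces
#'
#' Applies the forward sensor model channel by channel, closing the loop
#' synthetic gait -> raw capacitance signals -> analysis pipeline. By default
#' the in-insole sensor profile is used and only the linear static
#' transduction is applied (`dynamics = FALSE`, `hysteresis = FALSE`): at gait
#' time scales the measured 142/160 ms response constants would attenuate the
#' pressure bumps by several percent, and the hysteretic unloading branch is
#' not invertible by the linear calibration — either would break the sub-kPa
#' calibration round-trip this conversion guarantees (see the methods
#' vignette). Both effects can be switched on to emulate rawer signals.
#'
#' @param frames a [pressure_frames()].
#' @param specs list of 16 [sensor_spec()]s, one per channel (default:
#'   identical in-insole specs).
#' @param noise_sd additive noise SD on relative capacitance.
#' @param seed integer seed (required when `noise_sd > 0`); per-channel
#'   sub-seeds are derived deterministically.
#' @param dynamics apply the first-order lag (default `FALSE`).
#' @param hysteresis apply the hysteretic unloading branch (default `FALSE`).
#' @return Named list of 16 [capacitance_trace()]s.
#' @export
to_capacitance <- function(frames, specs = NULL, noise_sd = 0, seed = NULL,
                           dynamics = FALSE, hysteresis = FALSE) {
  stopifnot(inherits(frames, "pressure_frames"))
  if (is.null(specs)) {
    specs <- rep(list(sensor_spec("in-insole")), 16L)
    names(specs) <- SENSOR_IDS
  }
  if (length(specs) != 16L) {
    stop("configuration error: need exactly 16 sensor specs", call. = FALSE)
  }
  if (is.null(names(specs))) names(specs) <- SENSOR_IDS
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required for noisy conversion", call. = FALSE)
  }
  out <- lapply(seq_len(16L), function(i) {
    id <- SENSOR_IDS[i]
    sp <- specs[[id]]
    if (!hysteresis) sp$alpha <- 0
    pt <- pressure_trace(frames$frames[, id], frames$sample_rate,
                         start_time = frames$start_time)
    simulate_capacitance_trace(pt, sp, noise_sd = noise_sd,
                               seed = if (is.null(seed)) NULL else seed + i,
                               dynamics = dynamics)
  })
  names(out) <- SENSOR_IDS
  out
}
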