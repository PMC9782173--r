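# Sensor-performance metrics on capacitance/pressure traces: sensitivity and
# linearity, degree of hysteresis, 10-90% response/recovery times, loading
# frequency invariance, durability drift.

# relative-change values of a trace, using the trace's own c0 metadata or an
# estimate from the earliest `n_base` samples (pre-protocol baseline)
relative_values <- function(trace, n_base = NULL) {
  if (trace$units == "relative") return(trace$values)
  c0 <- trace$c0
  if (is.null(c0)) {
    if (is.null(n_base)) n_base <- max(1L, round(length(trace$values) * 0.001))
    c0 <- mean(trace$values[seq_len(min(n_base, length(trace$values)))])
  }
  trace$values / c0 - 1
}

# per-cycle (baseline, peak) statistics for a periodic block of a trace;
# cycle k spans [k*period, (k+1)*period) from `offset` seconds
cycle_stats <- function(values, sample_rate, period, n_cycles, offset = 0) {
  stats <- matrix(NA_real_, nrow = n_cycles, ncol = 2,
                  dimnames = list(NULL, c("baseline", "peak")))
  for (k in seq_len(n_cycles)) {
    i0 <- round((offset + (k - 1) * period) * sample_rate) + 1
    i1 <- round((offset + k * period) * sample_rate)
    i1 <- min(i1, length(values))
    if (i0 > i1) break
    seg <- values[i0:i1]
    stats[k, ] <- c(min(seg), max(seg))
  }
  stats[!is.na(stats[, 1]), , drop = FALSE]
}

#' Per-level cycle amplitudes of a staircase recording
#'
#' For each pressure level of a staircase protocol, computes the mean over
#' loading cycles of `(cycle peak - cycle baseline) / C0`, with the cycle
#' baseline the local pre-cycle minimum (robust to slow drift) and C0 the
#' pre-protocol baseline capacitance. The first cycle of every level is
#' discarded as transient.
#'
#' @param trace a [capacitance_trace()] recorded under `protocol`.
#' @param protocol the generating [loading_protocol()] (defaults to the
#'   `"protocol"` attribute left by [staircase_protocol()] if present on
#'   `trace`).
#' @return data.frame with columns `mass_kg`, `pressure_kpa`, `amplitude`
#'   (mean relative capacitance change per level).
#' @export
extract_cycle_amplitudes <- function(trace, protocol = attr(trace, "protocol")) {
  stopifnot(inherits(trace, "capacitance_trace"),
            inherits(protocol, "loading_protocol"),
            protocol$kind == "staircase")
  rel <- relative_values(trace)
  period <- 60 / protocol$steps_per_min
  n_cyc <- round(protocol$duration_per_level / period)
  if (n_cyc < 2) {
    stop("insufficient data: need at least 2 cycles per level", call. = FALSE)
  }
  amps <- vapply(seq_along(protocol$levels), function(lev) {
    offset <- (lev - 1) * protocol$duration_per_level
    st <- cycle_stats(rel, trace$sample_rate, period, n_cyc, offset)
    st <- st[-1, , drop = FALSE] # discard transient first cycle
    mean(st[, "peak"] - st[, "baseline"])
  }, numeric(1))
  data.frame(mass_kg = protocol$levels,
             pressure_kpa = mass_to_pressure(protocol$levels,
                                             protocol$diameter),
             amplitude = amps)
}

#' Least-squares sensitivity fit
#'
#' Ordinary least-squares line through relative-capacitance amplitude versus
#' pressure; the slope is the sensitivity Sc = (dC/C0)/dP in MPa^-1.
#'
#' @param pressures pressures in MPa (>= 3 points).
#' @param amplitudes relative capacitance change at each pressure.
#' @return List with `slope` (MPa^-1), `intercept`, `stderr` (standard error
#'   of the slope), `r_squared`.
#' @examples
#' fit_sensitivity(c(0, 1, 2), c(0, 1, 2)) # slope 1, r^2 = 1
#' @export
fit_sensitivity <- function(pressures, amplitudes) {
  stopifnot(length(pressures) == length(amplitudes))
  if (length(pressures) < 3) {
    stop("need at least 3 points for a sensitivity fit", call. = FALSE)
  }
  if (stats::var(pressures) <= 0) {
    stop("degenerate fit: pressures have no variance", call. = FALSE)
  }
  fit <- lm(amplitudes ~ pressures)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       stderr = unname(sm$coefficients[2, 2]),
       r_squared = sm$r.squared)
}

#' Loading/unloading hysteresis loop
#'
#' @param pressures strictly increasing pressure grid in kPa.
#' @param loading_values,unloading_values relative capacitance change on the
#'   loading and unloading branches at each grid pressure.
#' @return An object of class `hysteresis_loop`.
#' @export
hysteresis_loop <- function(pressures, loading_values, unloading_values) {
  stopifnot(length(pressures) == length(loading_values),
            length(pressures) == length(unloading_values))
  if (any(diff(pressures) <= 0)) {
    stop("pressures must be strictly increasing", call. = FALSE)
  }
  structure(list(pressures = pressures, loading_values = loading_values,
                 unloading_values = unloading_values),
            class = "hysteresis_loop")
}

#' Default hysteresis loop of a sensor
#'
#' Samples both static branches of `spec` on a uniform pressure grid from 0 to
#' the working maximum.
#'
#' @param spec a [sensor_spec()].
#' @param n number of grid points (default 1000).
#' @param p_max loop turning-point pressure in kPa.
#' @return A [hysteresis_loop()].
#' @export
default_hysteresis_loop <- function(spec = sensor_spec(), n = 1000,
                                    p_max = spec$p_max) {
  p <- seq(0, p_max, length.out = n)
  hysteresis_loop(p,
                  static_response(p, spec, "loading"),
                  static_response(p, spec, "unloading", p_max_branch = p_max))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Degree of hysteresis
#'
#' `DH(%) = 100 * (A_unloading - A_loading) / A_loading`, with both areas
#' under the branch curves computed by trapezoidal integration over the common
#' pressure grid. The sign is preserved (negative when the unloading branch
#' lies below the loading branch).
#'
#' @param loop a [hysteresis_loop()].
#' @return DH in percent.
#' @examples
#' degree_of_hysteresis(default_hysteresis_loop()) # 9.8
#' @export
degree_of_hysteresis <- function(loop) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  a_load <- trapz(loop$pressures, loop$loading_values)
  a_unl <- trapz(loop$pressures, loop$unloading_values)
  if (a_load == 0) {
    stop("undefined hysteresis: loading area is zero", call. = FALSE)
  }
  100 * (a_unl - a_load) / a_load
}

# first crossing time of `level` in direction `dir` ("up"/"down") at index
# >= from, linearly interpolated between samples; NA when absent
crossing_time <- function(values, times, level, dir, from = 1L) {
  n <- length(values)
  if (from >= n) return(list(t = NA_real_, i = NA_integer_))
  v0 <- values[from:(n - 1)]
  v1 <- values[(from + 1):n]
  hit <- if (dir == "up") v0 < level & v1 >= level else v0 > level & v1 <= level
  idx <- which(hit)
  if (!length(idx)) return(list(t = NA_real_, i = NA_integer_))
  i <- idx[1] + from - 1L
  frac <- (level - values[i]) / (values[i + 1] - values[i])
  list(t = times[i] + frac * (times[i + 1] - times[i]), i = i + 1L)
}

#' 10-90% response and recovery times
#'
#' Measures the time between the 10% and 90% threshold crossings of the signal
#' range on rising edges (response) and the 90%-to-10% interval on falling
#' edges (recovery), with linear interpolation between samples; results are
#' averaged when several edges qualify. Thresholds are relative to the trace's
#' own min/max, so the estimate is invariant to absolute scale.
#'
#' @param trace a [capacitance_trace()] (or [pressure_trace()]) containing at
#'   least one full rising or falling edge.
#' @return List with `response_time` and `recovery_time` in s (NA when the
#'   corresponding edge is absent; error when neither exists).
#' @export
response_recovery_times <- function(trace) {
  values <- trace$values
  times <- trace_times(trace)
  lo <- min(values) + 0.1 * diff(range(values))
  hi <- min(values) + 0.9 * diff(range(values))
  if (diff(range(values)) <= 0) {
    stop("no qualifying edge: trace is constant", call. = FALSE)
  }
  rises <- c(); falls <- c()
  i <- 1L
  repeat { # rising edges: lo-up followed by hi-up
    c_lo <- crossing_time(values, times, lo, "up", i)
    if (is.na(c_lo$t)) break
    c_hi <- crossing_time(values, times, hi, "up", c_lo$i - 1L)
    if (is.na(c_hi$t)) break
    rises <- c(rises, c_hi$t - c_lo$t)
    i <- c_hi$i
  }
  i <- 1L
  repeat { # falling edges: hi-down followed by lo-down
    c_hi <- crossing_time(values, times, hi, "down", i)
    if (is.na(c_hi$t)) break
    c_lo <- crossing_time(values, times, lo, "down", c_hi$i - 1L)
    if (is.na(c_lo$t)) break
    falls <- c(falls, c_lo$t - c_hi$t)
    i <- c_lo$i
  }
  if (!length(rises) && !length(falls)) {
    stop("no qualifying edge found", call. = FALSE)
  }
  list(response_time = if (length(rises)) mean(rises) else NA_real_,
       recovery_time = if (length(falls)) mean(falls) else NA_real_)
}

# steady-cycle amplitude of a periodic recording (first cycle discarded)
steady_cycle_amplitude <- function(trace, steps_per_min) {
  rel <- relative_values(trace)
  period <- 60 / steps_per_min
  n_cyc <- floor(length(rel) / trace$sample_rate / period)
  st <- cycle_stats(rel, trace$sample_rate, period, n_cyc)
  if (nrow(st) < 2) {
    stop("insufficient data: need at least 2 cycles", call. = FALSE)
  }
  st <- st[-1, , drop = FALSE]
  mean(st[, "peak"] - st[, "baseline"])
}

#' Loading-frequency invariance of the steady-cycle amplitude
#'
#' Computes the steady-cycle relative-capacitance amplitude at each cadence
#' and returns the maximum relative deviation from their mean; values below
#' 0.01 mirror a rate-independent sensor over the 30-70 steps/min gait range.
#'
#' @param traces named list of [capacitance_trace()]s recorded at the same
#'   peak pressure, one per cadence.
#' @param cadences cadences in steps/min (default: numeric names of `traces`).
#' @return Maximum of `|amp_i - mean| / mean` across cadences.
#' @export
frequency_invariance <- function(traces, cadences = as.numeric(names(traces))) {
  if (length(traces) < 2) {
    stop("insufficient data: need at least two cadences", call. = FALSE)
  }
  stopifnot(length(cadences) == length(traces), !any(is.na(cadences)))
  amps <- mapply(steady_cycle_amplitude, traces, cadences)
  max(abs(amps - mean(amps)) / mean(amps))
}

#' Durability drift of baseline and peak capacitance
#'
#' Compares the mean cycle baseline (C0) and mean cycle peak (Cf) between the
#' first and last `window` seconds of a long periodic recording.
#'
#' @param trace a [capacitance_trace()] of a periodic run.
#' @param window comparison window length in s (trace must span at least two
#'   windows).
#' @param steps_per_min cadence of the recording (default: from the trace's
#'   `"protocol"` attribute).
#' @return List with `c0_drift` and `cf_drift`, relative changes
#'   (last vs first window).
#' @export
durability_drift <- function(trace, window,
                             steps_per_min = attr(trace, "protocol")$steps_per_min) {
  stopifnot(inherits(trace, "capacitance_trace"), window > 0,
            !is.null(steps_per_min))
  total <- length(trace$values) / trace$sample_rate
  if (total < 2 * window) {
    stop("insufficient data: trace shorter than two windows", call. = FALSE)
  }
  period <- 60 / steps_per_min
  n_cyc <- floor(window / period)
  vals <- trace$values
  first <- cycle_stats(vals, trace$sample_rate, period, n_cyc, offset = 0)
  last <- cycle_stats(vals, trace$sample_rate, period, n_cyc,
                      offset = total - window)
  list(c0_drift = mean(last[, "baseline"]) / mean(first[, "baseline"]) - 1,
       cf_drift = mean(last[, "peak"]) / mean(first[, "peak"]) - 1)
}

#' Full characterization report for one sensor
#'
#' Runs the complete bench protocol on a simulated (or supplied) sensor:
#' staircase sensitivity fit, hysteresis loop, step response timing, cadence
#' sweep and durability drift.
#'
#' @param spec a [sensor_spec()].
#' @param noise_sd relative-capacitance noise SD (0 for the noiseless model).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param duration_per_level staircase dwell per level in s.
#' @param durability_cycles number of durability cycles (default 2280, the
#'   one-hour run at 38 steps/min).
#' @param durability_cadence cadence of the durability run in steps/min.
#' @param sample_rate rig sampling rate in Hz.
#' @return An object of class `characterization_report`: list with `slope`,
#'   `slope_stderr`, `intercept`, `r_squared`, `dh_percent`, `response_time`,
#'   `recovery_time`, `freq_invariance`, `c0_drift`, `cf_drift`.
#' @export
characterize_sensor <- function(spec = sensor_spec(), noise_sd = 0,
                                seed = NULL, duration_per_level = 60,
                                durability_cycles = 2280,
                                durability_cadence = 38,
                                sample_rate = 1000) {
  sub_seed <- function(k) if (is.null(seed)) NULL else seed + k
  stair <- staircase_protocol(duration_per_level = duration_per_level,
                              sample_rate = sample_rate)
  ctr <- simulate_capacitance_trace(stair, spec, noise_sd = noise_sd,
                                    seed = sub_seed(1))
  attr(ctr, "protocol") <- attr(stair, "protocol")
  amps <- extract_cycle_amplitudes(ctr)
  fit <- fit_sensitivity(amps$pressure_kpa / 1000, amps$amplitude)

  dh <- degree_of_hysteresis(default_hysteresis_loop(spec))

  step <- pressure_trace(c(rep(0, sample_rate), rep(spec$p_max, sample_rate),
                           rep(0, sample_rate)), sample_rate)
  st <- simulate_capacitance_trace(step, spec, noise_sd = 0)
  rt <- response_recovery_times(st)

  cadences <- c(30, 40, 50, 60, 70)
  sweeps <- lapply(seq_along(cadences), function(i) {
    tr <- periodic_loading(spec$p_max, cadences[i], n_cycles = 5,
                           sample_rate = sample_rate)
    simulate_capacitance_trace(tr, spec, noise_sd = noise_sd,
                               seed = sub_seed(10 + i))
  })
  names(sweeps) <- cadences
  fi <- frequency_invariance(sweeps)

  dur <- periodic_loading(spec$p_max, durability_cadence,
                          n_cycles = durability_cycles,
                          sample_rate = sample_rate)
  dtr <- simulate_capacitance_trace(dur, spec, noise_sd = noise_sd,
                                    seed = sub_seed(99))
  attr(dtr, "protocol") <- attr(dur, "protocol")
  dd <- durability_drift(dtr, window = 60)

  structure(list(slope = fit$slope, slope_stderr = fit$stderr,
                 intercept = fit$intercept, r_squared = fit$r_squared,
                 dh_percent = dh,
                 response_time = rt$response_time,
                 recovery_time = rt$recovery_time,
                 freq_invariance = fi,
                 c0_drift = dd$c0_drift, cf_drift = dd$cf_drift),
            class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("<characterization_report>\n")
  cat(sprintf("  sensitivity: %.3f +/- %.3f MPa^-1 (R^2 = %.4f)\n",
              x$slope, x$slope_stderr, x$r_squared))
  cat(sprintf("  degree of hysteresis: %.1f %%\n", x$dh_percent))
  cat(sprintf("  response/recovery: %.0f / %.0f ms\n",
              x$response_time * 1000, x$recovery_time * 1000))
  cat(sprintf("  cadence invariance: %.4f; drift C0 %.4f, Cf %.4f\n",
              x$freq_invariance, x$c0_drift, x$cf_drift))
  invisible(x)
}
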