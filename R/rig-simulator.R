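# Pressure protocols of the dynamic loading rig: staircase calibration,
# constant-pressure cadence sweeps, durability runs, quasi-static ramps.

#' Loading-protocol description
#'
#' Metadata describing a rig run, consumed by the characterization stage to
#' segment traces into levels and cycles.
#'
#' @param kind `"staircase"`, `"periodic"` or `"ramp_cycles"`.
#' @param levels masses in kg (staircase) or pressures in kPa (others).
#' @param steps_per_min cadence in steps/min (cadence protocols; the rig
#'   supports 30-70).
#' @param duration_per_level dwell per staircase level in s.
#' @param n_cycles number of loading/unloading cycles (periodic and ramps).
#' @param sample_rate sampling rate in Hz.
#' @param diameter sensor face diameter in m (for mass conversion).
#' @param ramp_duration single-leg ramp duration in s (ramp protocols).
#' @return An object of class `loading_protocol`.
#' @export
loading_protocol <- function(kind = c("staircase", "periodic", "ramp_cycles"),
                             levels = numeric(), steps_per_min = 40,
                             duration_per_level = 60, n_cycles = 1L,
                             sample_rate = 1000, diameter = 14.5e-3,
                             ramp_duration = 1) {
  kind <- match.arg(kind)
  stopifnot(sample_rate > 0, diameter > 0)
  if (kind != "ramp_cycles" &&
      (steps_per_min < 30 || steps_per_min > 70)) {
    warning(sprintf("cadence %g steps/min is outside the rig's 30-70 range",
                    steps_per_min), call. = FALSE)
  }
  structure(list(kind = kind, levels = levels, steps_per_min = steps_per_min,
                 duration_per_level = duration_per_level, n_cycles = n_cycles,
                 sample_rate = sample_rate, diameter = diameter,
                 ramp_duration = ramp_duration),
            class = "loading_protocol")
}

# 50% duty square wave of n_cycles periods: low quarter, high half, low
# quarter per cycle, so generated traces start and end unloaded and have one
# plateau (local maximum) per cycle.
square_wave <- function(peak, period, n_cycles, sample_rate, t0 = 0) {
  n <- round(n_cycles * period * sample_rate)
  frac <- (((seq_len(n) - 1) / sample_rate) %% period) / period
  ifelse(frac >= 0.25 & frac < 0.75, peak, 0)
}

#' Staircase calibration protocol
#'
#' Concatenated square-wave blocks, one per mass level, peak pressure given by
#' [mass_to_pressure()]. The default staircase is the rig's calibration run:
#' fifteen masses 0.7-14.7 kg in 1.0 kg steps (41.5-872.4 kPa in 59.35 kPa
#' increments) at 40 steps/min with one-minute dwell per level.
#'
#' @param masses masses in kg, sorted ascending.
#' @param steps_per_min loading cadence in steps/min.
#' @param duration_per_level dwell per level in s (a whole number of cycles).
#' @param diameter sensor face diameter in m.
#' @param sample_rate sampling rate in Hz.
#' @return A [pressure_trace()] with the generating [loading_protocol()]
#'   attached as attribute `"protocol"`.
#' @examples
#' tr <- staircase_protocol(duration_per_level = 6)
#' max(tr$values) # 872.4 kPa
#' @export
staircase_protocol <- function(masses = seq(0.7, 14.7, by = 1.0),
                               steps_per_min = 40, duration_per_level = 60,
                               diameter = 14.5e-3, sample_rate = 1000) {
  if (is.unsorted(masses, strictly = FALSE)) {
    stop("masses must be sorted ascending", call. = FALSE)
  }
  proto <- loading_protocol("staircase", levels = masses,
                            steps_per_min = steps_per_min,
                            duration_per_level = duration_per_level,
                            sample_rate = sample_rate, diameter = diameter)
  period <- 60 / steps_per_min
  n_cyc <- duration_per_level / period
  if (abs(n_cyc - round(n_cyc)) > 1e-9) {
    stop("duration_per_level must be a whole number of cycles", call. = FALSE)
  }
  vals <- unlist(lapply(masses, function(m) {
    square_wave(mass_to_pressure(m, diameter), period, round(n_cyc),
                sample_rate)
  }), use.names = FALSE)
  tr <- pressure_trace(if (is.null(vals)) numeric() else vals, sample_rate)
  attr(tr, "protocol") <- proto
  tr
}

#' Constant-pressure periodic loading
#'
#' Square wave of `n_cycles` loading/unloading periods at the requested
#' cadence; used for frequency sweeps and durability runs (e.g. 2280 cycles
#' at 872.4 kPa for the one-hour durability test).
#'
#' @param pressure peak pressure in kPa (<= 872.4).
#' @param steps_per_min cadence in steps/min.
#' @param n_cycles number of cycles (> 0).
#' @param sample_rate sampling rate in Hz.
#' @return A [pressure_trace()] with attribute `"protocol"`.
#' @export
periodic_loading <- function(pressure, steps_per_min = 40, n_cycles = 3,
                             sample_rate = 1000) {
  if (pressure > P_MAX_KPA * (1 + 1e-5)) {
    stop(sprintf("pressure exceeds the %g kPa working range", P_MAX_KPA),
         call. = FALSE)
  }
  if (n_cycles <= 0) stop("n_cycles must be positive", call. = FALSE)
  proto <- loading_protocol("periodic", levels = pressure,
                            steps_per_min = steps_per_min,
                            n_cycles = n_cycles, sample_rate = sample_rate)
  period <- 60 / steps_per_min
  tr <- pressure_trace(square_wave(pressure, period, n_cycles, sample_rate),
                       sample_rate)
  attr(tr, "protocol") <- proto
  tr
}

#' Quasi-static triangular loading-unloading ramps
#'
#' Symmetric triangular cycles 0 -> p_max -> 0, the protocol behind the
#' hysteresis measurement (default three consecutive cycles).
#'
#' @param p_max peak pressure in kPa (<= 872.4).
#' @param n_cycles number of cycles.
#' @param sample_rate sampling rate in Hz.
#' @param ramp_duration duration of one ramp leg in s (slope =
#'   `p_max / ramp_duration`).
#' @return A [pressure_trace()] with attribute `"protocol"`.
#' @export
ramp_cycle <- function(p_max, n_cycles = 3, sample_rate = 1000,
                       ramp_duration = 1) {
  if (p_max > P_MAX_KPA * (1 + 1e-5)) {
    stop(sprintf("p_max exceeds the %g kPa working range", P_MAX_KPA),
         call. = FALSE)
  }
  stopifnot(n_cycles >= 1, ramp_duration > 0)
  proto <- loading_protocol("ramp_cycles", levels = p_max,
                            n_cycles = n_cycles, sample_rate = sample_rate,
                            ramp_duration = ramp_duration)
  period <- 2 * ramp_duration
  n <- round(n_cycles * period * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  frac <- (t %% period) / period
  vals <- p_max * (1 - abs(2 * frac - 1))
  # close the final cycle at zero
  vals <- c(vals, 0)
  tr <- pressure_trace(vals, sample_rate)
  attr(tr, "protocol") <- proto
  tr
}
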