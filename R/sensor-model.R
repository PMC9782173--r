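# Single-sensor physics and signal model: static capacitance of the
# two-dielectric stack, linear pressure transduction with a hysteretic
# unloading branch, and asymmetric first-order response dynamics.

#' Two-layer dielectric stack of a capacitive pressure sensor
#'
#' Describes the plate area and the two stacked dielectrics (an air cavity and
#' a flexible printed polymer) between the electrodes of a capacitive sensor.
#'
#' @param plate_area plate area in m^2.
#' @param d1,d2 thicknesses of dielectric layers 1 and 2 in m (layer 1 is the
#'   air cavity, layer 2 the solid flexible dielectric). At least one must be
#'   positive.
#' @param k1,k2 relative permittivities of the two layers (>= 1).
#' @return An object of class `dielectric_stack`.
#' @seealso [series_capacitance()]
#' @export
dielectric_stack <- function(plate_area, d1 = 1.0e-3, k1 = 1.0,
                             d2 = 0.2e-3, k2 = 4.2) {
  stopifnot(is.numeric(plate_area), length(plate_area) == 1L)
  if (!is.finite(plate_area) || plate_area <= 0) {
    stop("invalid geometry: plate_area must be positive", call. = FALSE)
  }
  if (d1 < 0 || d2 < 0 || d1 + d2 <= 0) {
    stop("invalid geometry: layer thicknesses must be >= 0 with d1 + d2 > 0",
         call. = FALSE)
  }
  if (k1 < 1 || k2 < 1) {
    stop("relative permittivities must be >= 1", call. = FALSE)
  }
  structure(list(plate_area = plate_area, d1 = d1, k1 = k1, d2 = d2, k2 = k2),
            class = "dielectric_stack")
}

#' Capacitance of two dielectric layers in series
#'
#' Parallel-plate capacitance with two stacked dielectrics:
#' `C = eps0 * A / (d1/k1 + d2/k2)`, with `eps0 = 8.854e-12` F/m.
#'
#' @param stack a [dielectric_stack()].
#' @return Capacitance in farads.
#' @examples
#' stack <- dielectric_stack(plate_area = pi * (14.5e-3 / 2)^2)
#' series_capacitance(stack) # ~1.40 pF
#' @export
series_capacitance <- function(stack) {
  stopifnot(inherits(stack, "dielectric_stack"))
  gap <- stack$d1 / stack$k1 + stack$d2 / stack$k2
  if (gap <= 0) stop("invalid geometry: zero effective gap", call. = FALSE)
  EPS0 * stack$plate_area / gap
}

#' Full parameterization of one capacitive pressure sensor
#'
#' Bundles the geometry, dielectric stack, baseline capacitance, linear
#' sensitivity, hysteresis bump coefficient, response/recovery time constants
#' and working pressure range of one sensor. Two calibrated profiles are
#' provided: `"out-of-insole"` (bench characterization, S = 1.19 MPa^-1) and
#' `"in-insole"` (sensor mounted inside the printed insole, S = 0.55 MPa^-1,
#' the ~2.1-fold attenuation measured after integration).
#'
#' The hysteresis coefficient `alpha` defaults to `3 * S * 0.098 / p_max`
#' (p_max in MPa), which makes the loop's degree of hysteresis exactly 9.8%.
#' The time constants default to `0.142/ln 9` and `0.160/ln 9` s so that the
#' 10-90% estimators recover 142 ms response and 160 ms recovery.
#'
#' @param profile `"out-of-insole"` or `"in-insole"`; sets the default `S`.
#' @param diameter sensor face diameter in m.
#' @param stack a [dielectric_stack()]; defaults to a 1.0 mm air cavity over a
#'   0.2 mm flexible polymer (k = 4.2) on the face implied by `diameter`.
#' @param C0 baseline capacitance in F; defaults to [series_capacitance()] of
#'   `stack`.
#' @param S sensitivity in MPa^-1 (relative capacitance change per MPa).
#' @param alpha hysteresis bump coefficient in MPa^-2 (0 disables hysteresis).
#' @param tau_rise,tau_fall response/recovery time constants in s.
#' @param p_min lower reliable pressure bound (limit of detection) in kPa.
#' @param p_max upper working pressure in kPa.
#' @return An object of class `sensor_spec`.
#' @examples
#' sensor_spec()                       # bench profile, S = 1.19 MPa^-1
#' sensor_spec("in-insole")            # integrated profile, S = 0.55 MPa^-1
#' @export
sensor_spec <- function(profile = c("out-of-insole", "in-insole"),
                        diameter = 14.5e-3,
                        stack = dielectric_stack(pi * (diameter / 2)^2),
                        C0 = series_capacitance(stack),
                        S = NULL,
                        alpha = NULL,
                        tau_rise = 0.142 / log(9),
                        tau_fall = 0.160 / log(9),
                        p_min = P_MIN_KPA,
                        p_max = P_MAX_KPA) {
  profile <- match.arg(profile)
  if (is.null(S)) S <- if (profile == "out-of-insole") 1.19 else 0.55
  if (is.null(alpha)) alpha <- 3 * S * 0.098 / (p_max / 1000)
  stopifnot(diameter > 0, C0 > 0)
  if (S <= 0) stop("sensitivity S must be positive", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (tau_rise <= 0 || tau_fall <= 0) {
    stop("time constants must be positive", call. = FALSE)
  }
  if (!(p_min >= 0 && p_min < p_max)) {
    stop("need 0 <= p_min < p_max", call. = FALSE)
  }
  structure(list(profile = profile, diameter = diameter, stack = stack,
                 C0 = C0, S = S, alpha = alpha,
                 tau_rise = tau_rise, tau_fall = tau_fall,
                 p_min = p_min, p_max = p_max),
            class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor_spec: %s>\n", x$profile))
  cat(sprintf("  S = %.3f MPa^-1, alpha = %.4f MPa^-2, C0 = %.4g pF\n",
              x$S, x$alpha, x$C0 * 1e12))
  cat(sprintf("  tau_rise = %.1f ms, tau_fall = %.1f ms, range [%g, %g] kPa\n",
              x$tau_rise * 1000, x$tau_fall * 1000, x$p_min, x$p_max))
  invisible(x)
}

#' Uniformly sampled pressure time series
#'
#' @param values pressures in kPa (non-negative, finite).
#' @param sample_rate sampling rate in Hz.
#' @param start_time time of the first sample in s.
#' @return An object of class `pressure_trace` with fields `values`,
#'   `sample_rate`, `start_time`.
#' @export
pressure_trace <- function(values, sample_rate, start_time = 0) {
  values <- as.numeric(values)
  stopifnot(sample_rate > 0)
  if (length(values) && (any(!is.finite(values)) || any(values < 0))) {
    stop("pressure values must be finite and >= 0", call. = FALSE)
  }
  structure(list(values = values, sample_rate = sample_rate,
                 start_time = start_time),
            class = "pressure_trace")
}

#' Uniformly sampled capacitance time series
#'
#' @param values capacitance in F (`units = "F"`) or relative change
#'   `(C - C0)/C0` (`units = "relative"`, values >= -1).
#' @param sample_rate sampling rate in Hz.
#' @param start_time time of the first sample in s.
#' @param units `"F"` or `"relative"`.
#' @param c0 baseline capacitance in F if known (carried as metadata).
#' @return An object of class `capacitance_trace`.
#' @export
capacitance_trace <- function(values, sample_rate, start_time = 0,
                              units = c("F", "relative"), c0 = NULL) {
  units <- match.arg(units)
  values <- as.numeric(values)
  stopifnot(sample_rate > 0)
  if (length(values) && any(!is.finite(values))) {
    stop("capacitance values must be finite", call. = FALSE)
  }
  if (units == "relative" && length(values) && any(values < -1)) {
    stop("relative-change values must be >= -1", call. = FALSE)
  }
  structure(list(values = values, sample_rate = sample_rate,
                 start_time = start_time, units = units, c0 = c0),
            class = "capacitance_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace: %d samples @ %g Hz, %.4g-%.4g kPa>\n",
              length(x$values), x$sample_rate,
              if (length(x$values)) min(x$values) else NA,
              if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

#' @export
print.capacitance_trace <- function(x, ...) {
  cat(sprintf("<capacitance_trace: %d samples @ %g Hz, units = %s>\n",
              length(x$values), x$sample_rate, x$units))
  invisible(x)
}

#' Time stamps of a trace
#' @param trace a `pressure_trace` or `capacitance_trace`.
#' @return Numeric vector of sample times in s.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1) / trace$sample_rate
}

#' Rig mass-to-pressure conversion
#'
#' Converts an applied mass on the loading shaft to the pressure on the sensor
#' face: `P = m g / (pi (d/2)^2)` with `g = 9.8` m/s^2, returned in kPa.
#' Reproduces the rig's printed endpoints: 0.7 kg -> 41.5 kPa and
#' 14.7 kg -> 872.4 kPa on the 14.5 mm face.
#'
#' @param mass applied mass in kg (vectorized, >= 0).
#' @param diameter sensor face diameter in m.
#' @return Pressure in kPa.
#' @examples
#' round(mass_to_pressure(c(0.7, 14.7)), 1) # 41.5, 872.4
#' @export
mass_to_pressure <- function(mass, diameter = 14.5e-3) {
  if (any(mass < 0)) stop("mass must be >= 0", call. = FALSE)
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  mass * G_RIG / (pi * (diameter / 2)^2) / 1000
}

#' Static hysteretic pressure-to-capacitance transduction
#'
#' Relative capacitance change at a given pressure. The loading branch is
#' linear, `S * P` (P in MPa); the unloading branch adds a quadratic bump,
#' `S * P + alpha * P * (p_max_branch - P)`, which closes the loop at both the
#' origin and the cycle's turning point and places the unloading curve above
#' the loading curve.
#'
#' @param pressure pressure in kPa (vectorized), within `[0, spec$p_max]`.
#' @param spec a [sensor_spec()].
#' @param branch `"loading"` or `"unloading"`.
#' @param p_max_branch turning-point pressure of the current cycle in kPa
#'   (required for the unloading branch).
#' @return Relative capacitance change (dimensionless).
#' @examples
#' sp <- sensor_spec()
#' static_response(436.2, sp, "loading")                    # ~0.519
#' static_response(436.2, sp, "unloading", p_max_branch = 872.4) # ~0.595
#' @export
static_response <- function(pressure, spec,
                            branch = c("loading", "unloading"),
                            p_max_branch = spec$p_max) {
  branch <- match.arg(branch)
  stopifnot(inherits(spec, "sensor_spec"))
  # the nominal range bound is the rounded rig conversion (14.7 kg ->
  # 872.4 kPa), so allow a small relative slack
  if (any(pressure < 0 | pressure > spec$p_max * (1 + 1e-5))) {
    stop(sprintf("pressure outside working range [0, %g] kPa", spec$p_max),
         call. = FALSE)
  }
  p <- pressure / 1000 # MPa
  if (branch == "loading") {
    spec$S * p
  } else {
    pm <- p_max_branch / 1000
    spec$S * p + spec$alpha * p * (pm - p)
  }
}

#' Asymmetric first-order response dynamics
#'
#' Passes a uniformly sampled signal through the sensor's first-order lag
#' `dy/dt = (x - y)/tau`, with `tau = tau_rise` while the output chases the
#' input upward and `tau = tau_fall` downward (exact discrete exponential
#' update). Works on a `pressure_trace`, a `capacitance_trace`, or a plain
#' numeric vector (then `sample_rate` is required).
#'
#' @param x input trace or numeric vector.
#' @param spec a [sensor_spec()] providing `tau_rise`/`tau_fall`.
#' @param sample_rate sampling rate in Hz (taken from the trace if omitted).
#' @param y0 initial output value; defaults to the first input sample.
#' @return Same type as the input, filtered.
#' @export
apply_dynamics <- function(x, spec, sample_rate = NULL, y0 = NULL) {
  stopifnot(inherits(spec, "sensor_spec"))
  is_trace <- inherits(x, "pressure_trace") || inherits(x, "capacitance_trace")
  vals <- if (is_trace) x$values else as.numeric(x)
  if (is_trace) sample_rate <- x$sample_rate
  if (is.null(sample_rate)) {
    stop("sample_rate required for plain numeric input", call. = FALSE)
  }
  if (length(vals) == 0) return(x)
  if (is.null(y0)) y0 <- vals[1]
  out <- asym_lowpass_cpp(vals, 1 / sample_rate, spec$tau_rise, spec$tau_fall,
                          y0)
  if (is_trace) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Simulate the capacitance signal of one sensor under a pressure waveform
#'
#' Composes the static hysteretic transduction, the first-order response
#' dynamics and additive Gaussian noise on the relative capacitance:
#' `C(t) = C0 * (1 + y(t) + noise)`. Deterministic for a fixed `seed`;
#' `noise_sd = 0` yields the noiseless model exactly.
#'
#' @param pressure a [pressure_trace()] within `[0, spec$p_max]`.
#' @param spec a [sensor_spec()].
#' @param noise_sd additive noise SD on the relative capacitance
#'   (dimensionless); default 0.01.
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param dynamics apply the first-order lag (default `TRUE`).
#' @return A [capacitance_trace()] in farads with `c0` metadata set.
#' @export
simulate_capacitance_trace <- function(pressure, spec, noise_sd = 0.01,
                                       seed = NULL, dynamics = TRUE) {
  stopifnot(inherits(pressure, "pressure_trace"), inherits(spec, "sensor_spec"))
  if (length(pressure$values) &&
      any(pressure$values > spec$p_max * (1 + 1e-5))) {
    stop(sprintf("pressure exceeds working range (%g kPa)", spec$p_max),
         call. = FALSE)
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required for stochastic simulation", call. = FALSE)
  }
  r <- hysteresis_transduce_cpp(pressure$values / 1000, spec$S, spec$alpha)
  if (dynamics && length(r)) {
    r <- asym_lowpass_cpp(r, 1 / pressure$sample_rate,
                          spec$tau_rise, spec$tau_fall, r[1])
  }
  if (noise_sd > 0) {
    r <- r + with_seed(seed, rnorm(length(r), sd = noise_sd))
  }
  capacitance_trace(spec$C0 * (1 + r), pressure$sample_rate,
                    start_time = pressure$start_time, units = "F",
                    c0 = spec$C0)
}
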