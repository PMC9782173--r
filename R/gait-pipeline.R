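# Analysis pipeline for the insole: capacitance-to-pressure calibration,
# center-of-pressure trajectories, 227-cell heatmap, rule-based gait-phase
# segmentation, per-zone peak summaries.

#' Convert 16 capacitance traces to pressure frames
#'
#' Inverts the linear transduction per sensor: `P = ((C/C0) - 1) / S`
#' (S in MPa^-1, result reported in kPa). Negative estimates are floored at 0;
#' values below the sensor's limit of detection are flagged in the
#' `"below_lod"` attribute (logical matrix) rather than clipped.
#'
#' @param traces named list of 16 [capacitance_trace()]s (one per sensor id).
#' @param specs list of 16 [sensor_spec()]s providing C0 and S per channel
#'   (default: identical in-insole specs).
#' @return A [pressure_frames()] with attribute `"below_lod"`.
#' @export
calibrate <- function(traces, specs = NULL) {
  if (length(traces) != 16L) {
    stop("calibration error: need exactly 16 channels", call. = FALSE)
  }
  if (is.null(names(traces))) names(traces) <- SENSOR_IDS
  if (is.null(specs)) {
    specs <- rep(list(sensor_spec("in-insole")), 16L)
    names(specs) <- SENSOR_IDS
  }
  if (is.null(names(specs))) names(specs) <- SENSOR_IDS
  n <- length(traces[[1]]$values)
  rate <- traces[[1]]$sample_rate
  mat <- matrix(0, nrow = n, ncol = 16L, dimnames = list(NULL, SENSOR_IDS))
  lod <- matrix(FALSE, nrow = n, ncol = 16L,
                dimnames = list(NULL, SENSOR_IDS))
  for (id in SENSOR_IDS) {
    tr <- traces[[id]]
    sp <- specs[[id]]
    stopifnot(inherits(tr, "capacitance_trace"), inherits(sp, "sensor_spec"))
    if (length(tr$values) != n || tr$sample_rate != rate) {
      stop("calibration error: channels disagree in length or rate",
           call. = FALSE)
    }
    rel <- if (tr$units == "relative") tr$values else {
      c0 <- if (!is.null(tr$c0)) tr$c0 else sp$C0
      if (is.null(c0)) stop("calibration error: missing C0", call. = FALSE)
      tr$values / c0 - 1
    }
    p <- pmax(rel / sp$S * 1000, 0)
    mat[, id] <- p
    lod[, id] <- p < sp$p_min
  }
  out <- pressure_frames(mat, rate, start_time = traces[[1]]$start_time)
  attr(out, "below_lod") <- lod
  out
}

#' Center of pressure of one frame
#'
#' Pressure-weighted centroid of the sensor coordinates,
#' `(sum p_i x_i / sum p_i, sum p_i y_i / sum p_i)`. A frame with total
#' pressure below 1 kPa has no meaningful centroid and is flagged invalid.
#'
#' @param frame named numeric 16-vector of pressures in kPa.
#' @param layout an [insole_layout()].
#' @return List with `x`, `y` (mm) and `valid`.
#' @export
center_of_pressure <- function(frame, layout = default_layout()) {
  stopifnot(inherits(layout, "insole_layout"))
  frame <- frame[layout$sensors$id]
  total <- sum(frame)
  if (!is.finite(total) || total < 1) {
    return(list(x = NA_real_, y = NA_real_, valid = FALSE))
  }
  list(x = sum(frame * layout$sensors$x) / total,
       y = sum(frame * layout$sensors$y) / total,
       valid = TRUE)
}

#' Center-of-pressure trajectory of a frame series
#'
#' @param frames a [pressure_frames()].
#' @param layout an [insole_layout()].
#' @return data.frame with `time_s`, `x_mm`, `y_mm`, `valid`, one row per
#'   frame.
#' @export
cop_trajectory <- function(frames, layout = default_layout()) {
  stopifnot(inherits(frames, "pressure_frames"))
  t <- frames$start_time + (seq_len(nrow(frames$frames)) - 1) /
    frames$sample_rate
  cops <- apply(frames$frames, 1, center_of_pressure, layout = layout)
  data.frame(time_s = t,
             x_mm = vapply(cops, `[[`, numeric(1), "x"),
             y_mm = vapply(cops, `[[`, numeric(1), "y"),
             valid = vapply(cops, `[[`, logical(1), "valid"))
}

# point-in-outline test (elliptical outline)
inside_outline <- function(x, y, outline) {
  stopifnot(identical(outline$shape, "ellipse"))
  ((x - outline$cx) / outline$rx)^2 + ((y - outline$cy) / outline$ry)^2 <= 1
}

#' The 227-cell heatmap tessellation of an insole layout
#'
#' Cells are the members of a fixed square raster over the insole bounding box
#' whose centers fall inside the outline; the raster pitch and origin shipped
#' in the layout are frozen so that exactly 227 cells qualify. Each cell is
#' assigned to its nearest sensor.
#'
#' @param layout an [insole_layout()].
#' @return data.frame with `cell_id`, `x`, `y` (cell centers, mm),
#'   `sensor_id`.
#' @export
insole_grid <- function(layout = default_layout()) {
  stopifnot(inherits(layout, "insole_layout"))
  g <- layout$grid
  xs <- seq(g$ox, layout$insole_width, by = g$pitch)
  ys <- seq(g$oy, layout$insole_length, by = g$pitch)
  cells <- expand.grid(x = xs, y = ys)
  cells <- cells[inside_outline(cells$x, cells$y, layout$outline), ,
                 drop = FALSE]
  d2 <- outer(cells$x, layout$sensors$x, "-")^2 +
    outer(cells$y, layout$sensors$y, "-")^2
  nearest <- apply(d2, 1, which.min)
  data.frame(cell_id = seq_len(nrow(cells)), x = cells$x, y = cells$y,
             sensor_id = layout$sensors$id[nearest])
}

#' Pressure heatmap of one frame on the 227-cell grid
#'
#' Each cell inherits the pressure of its assigned sensor and a color level
#' `floor(10 * clip(p, 0, 450) / 450)` capped at 9 — the ten-level 0-450 kPa
#' scale of the display.
#'
#' @param frame named numeric 16-vector of pressures in kPa.
#' @param layout an [insole_layout()].
#' @return An object of class `heatmap_grid`: data.frame with `cell_id`, `x`,
#'   `y`, `sensor_id`, `pressure`, `level`.
#' @export
grid_heatmap <- function(frame, layout = default_layout()) {
  grid <- insole_grid(layout)
  p <- unname(frame[grid$sensor_id])
  level <- pmin(floor(10 * pmin(pmax(p, 0), 450) / 450), 9)
  out <- cbind(grid, pressure = p, level = as.integer(level))
  class(out) <- c("heatmap_grid", class(out))
  out
}

# running median of integer-coded labels; window must be odd
median_filter_labels <- function(codes, window) {
  if (window <= 1 || length(codes) < window) return(codes)
  half <- window %/% 2
  out <- codes
  for (i in (half + 1):(length(codes) - half)) {
    out[i] <- median(codes[(i - half):(i + half)])
  }
  out
}

#' Rule-based gait-phase segmentation
#'
#' Classifies every frame from its zone activations (zone mean pressure above
#' `threshold`): heel only -> heel strike; heel + metatarsals -> foot flat;
#' metatarsals (with or without arch) and no heel or toes -> midstance;
#' metatarsals + toes without heel -> heel off; toes only -> toe off; nothing
#' active -> swing. A running median over `median_window` frames removes label
#' chatter; cycle boundaries are placed at swing -> heel-strike transitions.
#'
#' @param frames a [pressure_frames()] (>= 50 Hz recommended).
#' @param layout an [insole_layout()].
#' @param threshold zone activation threshold in kPa (default 45,
#'   approximately the sensor LoD).
#' @param median_window label median-filter width in frames (odd; default 5).
#' @return An object of class `phase_segmentation`: list with `labels`
#'   (per-frame phase), `cycle_starts` (frame indices of heel strikes) and
#'   `sample_rate`.
#' @export
segment_phases <- function(frames, layout = default_layout(), threshold = 45,
                           median_window = 5) {
  stopifnot(inherits(frames, "pressure_frames"))
  zones <- c("calcaneus", "metatarsals", "arch", "phalanges")
  zmean <- sapply(zones, function(z) {
    ids <- names(ZONES)[ZONES == z]
    rowMeans(frames$frames[, ids, drop = FALSE])
  })
  if (nrow(frames$frames) == 1L) zmean <- matrix(zmean, nrow = 1,
                                                 dimnames = list(NULL, zones))
  # inclusive with a float tolerance: simulated zone means touch the
  # threshold exactly at phase boundaries
  act <- zmean >= threshold - 1e-6
  heel <- act[, "calcaneus"]; met <- act[, "metatarsals"]
  arch <- act[, "arch"]; toe <- act[, "phalanges"]
  lab <- rep("swing", nrow(act))
  lab[heel & !met & !toe] <- "heel strike"
  lab[heel & met] <- "foot flat"
  lab[!heel & met & !toe] <- "midstance"
  lab[!heel & !met & arch & !toe] <- "midstance" # arch-only fallback
  lab[!heel & met & toe] <- "heel off"
  lab[!heel & !met & toe] <- "toe off"
  lab[heel & !met & toe] <- "foot flat" # degenerate heel+toe fallback
  if (all(lab == "swing")) {
    warning("no zone activation anywhere; returning all-swing segmentation",
            call. = FALSE)
  }
  codes <- match(lab, PHASES) # ordinal within the cycle, swing last
  codes <- median_filter_labels(codes, median_window)
  lab <- PHASES[codes]
  starts <- which(lab == "heel strike" &
                    c("swing", lab[-length(lab)]) == "swing")
  structure(list(labels = lab, cycle_starts = starts,
                 sample_rate = frames$sample_rate),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation: %d frames, %d cycles>\n",
              length(x$labels), length(x$cycle_starts)))
  invisible(x)
}

#' Per-sensor and per-zone peak pressures
#'
#' Reports each sensor's maximum pressure with the time and gait phase at
#' which it occurs, per-zone maxima, and a flag raised when the plantar-arch
#' peak reaches 150 kPa (in normal gait the arch stays below that bound).
#'
#' @param frames a [pressure_frames()].
#' @param segmentation optional [segment_phases()] result (or `NULL` to use
#'   the frames' own ground-truth labels, if any).
#' @return List with `sensors` (data.frame `sensor`, `zone`, `peak_kpa`,
#'   `time_s`, `phase`), `zones` (data.frame `zone`, `peak_kpa`, `sensor`),
#'   and `arch_exceeds_150`.
#' @export
zone_summaries <- function(frames, segmentation = NULL) {
  stopifnot(inherits(frames, "pressure_frames"))
  labels <- if (!is.null(segmentation)) segmentation$labels else frames$labels
  t <- frames$start_time + (seq_len(nrow(frames$frames)) - 1) /
    frames$sample_rate
  peak_i <- apply(frames$frames, 2, which.max)
  peaks <- frames$frames[cbind(peak_i, seq_len(16L))]
  sensors <- data.frame(
    sensor = SENSOR_IDS,
    zone = unname(ZONES[SENSOR_IDS]),
    peak_kpa = unname(peaks),
    time_s = t[peak_i],
    phase = if (is.null(labels)) NA_character_ else labels[peak_i]
  )
  zones <- do.call(rbind, lapply(unique(sensors$zone), function(z) {
    sub <- sensors[sensors$zone == z, ]
    sub <- sub[which.max(sub$peak_kpa), ]
    data.frame(zone = z, peak_kpa = sub$peak_kpa, sensor = sub$sensor)
  }))
  list(sensors = sensors, zones = zones,
       arch_exceeds_150 = zones$peak_kpa[zones$zone == "arch"] >= 150)
}
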