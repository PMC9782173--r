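# Readers/writers for the package's plain-text formats: trace CSV (with JSON
# metadata sidecar), wide frames CSV, layout JSON, protocol JSON.

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a trace to CSV with a JSON metadata sidecar
#'
#' CSV dialect: header `time_s,value`, UTF-8, '.' decimal separator, at least
#' nine significant digits. Sample rate, units and an optional sensor id go to
#' a JSON sidecar of the same stem.
#'
#' @param trace a [pressure_trace()] or [capacitance_trace()].
#' @param path output CSV path.
#' @param sensor_id optional sensor id recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, sensor_id = NULL) {
  stopifnot(inherits(trace, "pressure_trace") ||
              inherits(trace, "capacitance_trace"))
  df <- data.frame(time_s = trace_times(trace), value = trace$values)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("time_s,value", con)
  if (nrow(df)) {
    writeLines(sprintf("%.10g,%.10g", df$time_s, df$value), con)
  }
  meta <- list(schema = "smartinsole/trace/1",
               sample_rate = trace$sample_rate,
               start_time = trace$start_time,
               kind = if (inherits(trace, "pressure_trace")) "pressure"
                      else "capacitance",
               units = if (inherits(trace, "pressure_trace")) "kPa"
                       else trace$units)
  if (!is.null(sensor_id)) meta$sensor_id <- sensor_id
  if (inherits(trace, "capacitance_trace") && !is.null(trace$c0)) {
    meta$c0 <- trace$c0
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace CSV (with its JSON sidecar)
#'
#' Validates the header, the time monotonicity and the sampling uniformity
#' (jitter above 1% of the nominal interval is a format error).
#'
#' @param path CSV path written by [write_trace()] (or conforming to the
#'   dialect).
#' @return A [pressure_trace()] or [capacitance_trace()] according to the
#'   sidecar's `kind`.
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(header, "time_s,value")) {
    stop(sprintf("format error in %s line 1: expected header 'time_s,value'",
                 path), call. = FALSE)
  }
  df <- read.csv(path, colClasses = "numeric")
  meta_path <- sidecar_path(path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  if (nrow(df) == 0) {
    warning(sprintf("%s contains a header only; returning an empty trace",
                    path), call. = FALSE)
    rate <- if (!is.null(meta$sample_rate)) meta$sample_rate else 1
  } else if (nrow(df) == 1) {
    rate <- if (!is.null(meta$sample_rate)) meta$sample_rate else 1
  } else {
    dt <- diff(df$time_s)
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 2L # +1 for header, +1 for second sample
      stop(sprintf("format error in %s line %d: non-monotone time", path, bad),
           call. = FALSE)
    }
    if (any(abs(dt - median(dt)) > 0.01 * median(dt))) {
      bad <- which(abs(dt - median(dt)) > 0.01 * median(dt))[1] + 2L
      stop(sprintf("format error in %s line %d: non-uniform sampling", path,
                   bad), call. = FALSE)
    }
    rate <- 1 / median(dt)
    if (!is.null(meta$sample_rate)) rate <- meta$sample_rate
  }
  start <- if (nrow(df)) df$time_s[1] else 0
  kind <- if (!is.null(meta$kind)) meta$kind else "capacitance"
  if (kind == "pressure") {
    pressure_trace(df$value, rate, start_time = start)
  } else {
    units <- if (!is.null(meta$units) && meta$units == "relative") "relative"
             else "F"
    capacitance_trace(df$value, rate, start_time = start, units = units,
                      c0 = meta$c0)
  }
}

#' Write a pressure-frame series to wide CSV
#'
#' Columns `time_s,T1,...,H3`; ground-truth labels, if present, are appended
#' as a final `phase` column.
#'
#' @param frames a [pressure_frames()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(inherits(frames, "pressure_frames"))
  t <- frames$start_time + (seq_len(nrow(frames$frames)) - 1) /
    frames$sample_rate
  df <- data.frame(time_s = t, frames$frames, check.names = FALSE)
  if (!is.null(frames$labels)) df$phase <- frames$labels
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide frames CSV
#'
#' @param path CSV with columns `time_s,T1,...,H3` and optional `phase`.
#' @return A [pressure_frames()].
#' @export
read_frames <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("time_s", SENSOR_IDS) %in% names(df))) {
    stop(sprintf("format error in %s: expected columns time_s,%s", path,
                 paste(SENSOR_IDS, collapse = ",")), call. = FALSE)
  }
  if (nrow(df) < 2) stop("frames file needs at least two rows", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("format error: non-monotone time", call. = FALSE)
  labels <- if ("phase" %in% names(df)) as.character(df$phase) else NULL
  pressure_frames(as.matrix(df[, SENSOR_IDS]), 1 / median(dt),
                  labels = labels, start_time = df$time_s[1])
}

#' Read an insole layout JSON
#' @param path layout JSON (schema `smartinsole/layout/1`).
#' @return An [insole_layout()].
#' @export
read_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  insole_layout(j$sensors, insole_length = j$insole_length,
                insole_width = j$insole_width,
                outline = as.list(j$outline), grid = as.list(j$grid))
}

#' Write an insole layout JSON
#' @param layout an [insole_layout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "insole_layout"))
  jsonlite::write_json(list(schema = "smartinsole/layout/1",
                            insole_length = layout$insole_length,
                            insole_width = layout$insole_width,
                            outline = layout$outline, grid = layout$grid,
                            sensors = layout$sensors),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write a loading protocol JSON
#' @param path JSON path.
#' @return A [loading_protocol()].
#' @export
read_protocol <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  loading_protocol(kind = j$kind, levels = j$levels,
                   steps_per_min = j$steps_per_min %||% 40,
                   duration_per_level = j$duration_per_level %||% 60,
                   n_cycles = j$n_cycles %||% 1L,
                   sample_rate = j$sample_rate %||% 1000,
                   diameter = j$diameter %||% 14.5e-3,
                   ramp_duration = j$ramp_duration %||% 1)
}

#' @rdname read_protocol
#' @param protocol a [loading_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "loading_protocol"))
  jsonlite::write_json(c(list(schema = "smartinsole/protocol/1"),
                         unclass(protocol)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
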