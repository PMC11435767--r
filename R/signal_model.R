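# Domain containers and CSV/JSON plumbing.
#
# Conventions fixed here and relied on everywhere else:
#   * acceleration is stored in m/s^2 (SI); CSV inputs declared in g are
#     multiplied by the standard gravity 9.80665,
#   * sample indices are 1-based (R convention); the time of sample k is
#     t0 + (k - 1) / fs,
#   * CSV files are comma-separated with a header row, '.' decimal.

.STANDARD_GRAVITY <- 9.80665

#' Accelerometer sensor description
#'
#' @param sample_rate_hz Sampling rate, Hz. The detection cascade was tuned
#'   for 200 Hz; other rates are accepted with a warning because the
#'   wavelet-level-to-frequency-band mapping then changes.
#' @param range_g Full-scale measurement range, g.
#' @param axis_convention Label naming the forward (surge) axis.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(sample_rate_hz = 200, range_g = 16,
                        axis_convention = "x-forward") {
  stopifnot(sample_rate_hz > 0, range_g > 0)
  structure(
    list(
      sample_rate_hz = sample_rate_hz, range_g = range_g,
      axis_convention = axis_convention
    ),
    class = "sensor_spec"
  )
}

#' Tri-axial hull acceleration trace
#'
#' @param ax,ay,az Equal-length numeric vectors, m/s^2. `ax` is the forward
#'   (surge) axis used for stroke detection.
#' @param fs Sampling rate, Hz; must equal `spec$sample_rate_hz`.
#' @param t0 Timestamp of the first sample, seconds.
#' @param spec A [sensor_spec()].
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(ax, ay = NULL, az = NULL, fs = 200, t0 = 0,
                        spec = sensor_spec(sample_rate_hz = fs)) {
  if (is.null(ay)) ay <- numeric(length(ax))
  if (is.null(az)) az <- numeric(length(ax))
  if (!(length(ax) >= 1 && length(ay) == length(ax) && length(az) == length(ax))) {
    stop("ax, ay, az must have equal length >= 1", call. = FALSE)
  }
  if (!all(is.finite(ax), is.finite(ay), is.finite(az))) {
    stop("acceleration values must be finite", call. = FALSE)
  }
  if (!isTRUE(all.equal(fs, spec$sample_rate_hz))) {
    stop("fs must match spec$sample_rate_hz", call. = FALSE)
  }
  if (abs(fs - 200) > 1e-9) {
    warning("accelerometer sampled at ", fs,
            " Hz, not the 200 Hz the detection cascade was designed for; ",
            "wavelet levels map to different frequency bands", call. = FALSE)
  }
  structure(
    list(t0 = t0, fs = fs, ax = as.numeric(ax), ay = as.numeric(ay),
         az = as.numeric(az), spec = spec),
    class = "accel_trace"
  )
}

#' Multi-gate oarlock horizontal force trace
#'
#' @param gates Numeric matrix (samples x gates) or list of equal-length
#'   numeric vectors, newtons, one column per instrumented oarlock.
#' @param fs Sampling rate, Hz (50 for the reference system).
#' @param t0 Timestamp of the first sample, seconds.
#' @return An object of class `force_trace`; `gates` is stored as a matrix
#'   with one column per gate, in input order.
#' @export
force_trace <- function(gates, fs = 50, t0 = 0) {
  if (is.list(gates)) {
    len <- unique(lengths(gates))
    if (length(len) != 1L) stop("gate series must have equal length", call. = FALSE)
    gates <- do.call(cbind, gates)
  }
  gates <- as.matrix(gates)
  if (ncol(gates) < 1L || nrow(gates) < 1L) {
    stop("force_trace needs >= 1 gate with >= 1 sample", call. = FALSE)
  }
  stopifnot(fs > 0)
  if (is.null(colnames(gates))) {
    colnames(gates) <- paste0("gate", seq_len(ncol(gates)))
  }
  structure(list(t0 = t0, fs = fs, gates = gates), class = "force_trace")
}

#' Per-stroke event triples
#'
#' Holds the ordered (cycle start, drive start, drive end) sample indices of
#' each detected stroke. Indices are 1-based; the time of index k is
#' `t0 + (k - 1) / fs`.
#'
#' @param cycle_start,drive_start,drive_end Equal-length integer vectors of
#'   sample indices satisfying, within each stroke,
#'   `cycle_start <= drive_start < drive_end`, and across strokes
#'   `drive_end[i] < cycle_start[i + 1]`.
#' @param fs Sampling rate of the source trace, Hz.
#' @param t0 Timestamp of the first sample, seconds.
#' @return An object of class `stroke_events`.
#' @export
stroke_events <- function(cycle_start, drive_start, drive_end, fs, t0 = 0) {
  n <- length(cycle_start)
  if (length(drive_start) != n || length(drive_end) != n) {
    stop("event vectors must have equal length", call. = FALSE)
  }
  cycle_start <- as.integer(cycle_start)
  drive_start <- as.integer(drive_start)
  drive_end <- as.integer(drive_end)
  if (n > 0) {
    if (any(cycle_start > drive_start) || any(drive_start >= drive_end)) {
      stop("each stroke must satisfy cycle_start <= drive_start < drive_end",
           call. = FALSE)
    }
    if (n > 1 && any(drive_end[-n] >= cycle_start[-1])) {
      stop("strokes must not overlap: drive_end[i] < cycle_start[i+1]",
           call. = FALSE)
    }
  }
  stopifnot(fs > 0)
  structure(
    list(cycle_start = cycle_start, drive_start = drive_start,
         drive_end = drive_end, fs = fs, t0 = t0),
    class = "stroke_events"
  )
}

#' @export
length.stroke_events <- function(x) length(x$drive_start)

#' @export
print.stroke_events <- function(x, ...) {
  cat(sprintf("%d stroke(s) at fs = %g Hz\n", length(x), x$fs))
  if (length(x)) {
    print(utils::head(as.data.frame(x), 5))
    if (length(x) > 5) cat("...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.stroke_events <- function(x, ...) {
  data.frame(
    stroke = seq_along(x$drive_start),
    cycle_start = x$cycle_start,
    drive_start = x$drive_start,
    drive_end = x$drive_end,
    cycle_start_s = x$t0 + (x$cycle_start - 1) / x$fs,
    drive_start_s = x$t0 + (x$drive_start - 1) / x$fs,
    drive_end_s = x$t0 + (x$drive_end - 1) / x$fs
  )
}

#' Read an IMU acceleration export
#'
#' Reads a comma-separated export with a timestamp column and three
#' acceleration columns, validates sampling uniformity, and returns an
#' [accel_trace()] in m/s^2.
#'
#' @param path CSV file path.
#' @param spec Expected [sensor_spec()]; the rate inferred from timestamps
#'   must match `spec$sample_rate_hz` within 1%.
#' @param column_map Named character vector mapping the roles `time`, `ax`,
#'   `ay`, `az` to CSV column names.
#' @param units Units of the acceleration columns: `"m/s2"` or `"g"`
#'   (converted with standard gravity 9.80665).
#' @param jitter_tol Maximum tolerated relative deviation of any timestamp
#'   step from the median step (default 1%).
#' @return An [accel_trace()].
#' @export
read_imu_csv <- function(path, spec = sensor_spec(),
                         column_map = c(time = "time", ax = "ax",
                                        ay = "ay", az = "az"),
                         units = c("m/s2", "g"), jitter_tol = 0.01) {
  units <- match.arg(units)
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(column_map), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tm <- df[[column_map[["time"]]]]
  if (length(tm) < 2L) stop("need >= 2 samples", call. = FALSE)
  dt <- diff(tm)
  step <- stats::median(dt)
  if (step <= 0 || any(abs(dt - step) > jitter_tol * step)) {
    stop("non-uniform sampling in ", path,
         ": timestamp steps deviate by more than ", jitter_tol * 100,
         "% from the median step", call. = FALSE)
  }
  fs <- 1 / step
  if (abs(fs - spec$sample_rate_hz) > 0.01 * spec$sample_rate_hz) {
    stop(sprintf("inferred rate %.3f Hz does not match spec (%g Hz) within 1%%",
                 fs, spec$sample_rate_hz), call. = FALSE)
  }
  scale <- if (units == "g") .STANDARD_GRAVITY else 1
  accel_trace(
    ax = df[[column_map[["ax"]]]] * scale,
    ay = df[[column_map[["ay"]]]] * scale,
    az = df[[column_map[["az"]]]] * scale,
    fs = spec$sample_rate_hz, t0 = tm[1], spec = spec
  )
}

#' Read a multi-gate oarlock force export
#'
#' @param path CSV file path.
#' @param gate_columns Character vector of gate column names (newtons),
#'   preserved in order.
#' @param time_column Timestamp column name, seconds.
#' @return A [force_trace()].
#' @export
read_force_csv <- function(path, gate_columns, time_column = "time") {
  if (length(gate_columns) < 1L) stop("gate_columns must be non-empty", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c(time_column, gate_columns), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tm <- df[[time_column]]
  if (length(tm) < 2L) stop("need >= 2 samples", call. = FALSE)
  fs <- 1 / stats::median(diff(tm))
  force_trace(as.matrix(df[gate_columns]), fs = fs, t0 = tm[1])
}

#' Write / read detected stroke events as CSV
#'
#' One row per stroke with each event as a 1-based sample index and in
#' seconds. An empty event set produces a header-only file. The round trip
#' is lossless for indices.
#'
#' @param events A [stroke_events()] object.
#' @param path Output CSV path.
#' @return `write_events_csv` returns `path` invisibly; `read_events_csv`
#'   returns a [stroke_events()].
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "stroke_events"))
  df <- as.data.frame(events)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param fs,t0 Sampling rate and origin to attach on read; default taken
#'   from the seconds columns if `NULL`.
#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, fs = NULL, t0 = NULL) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) {
    return(stroke_events(integer(0), integer(0), integer(0),
                         fs = if (is.null(fs)) 200 else fs,
                         t0 = if (is.null(t0)) 0 else t0))
  }
  if (is.null(fs)) {
    fs <- (df$drive_end[1] - df$drive_start[1]) /
      (df$drive_end_s[1] - df$drive_start_s[1])
  }
  if (is.null(t0)) t0 <- df$drive_start_s[1] - (df$drive_start[1] - 1) / fs
  stroke_events(df$cycle_start, df$drive_start, df$drive_end, fs = fs, t0 = t0)
}

#' Write / read an agreement report as JSON
#'
#' Serialises nested report lists losslessly (full double precision).
#'
#' @param report A named list (e.g. from [build_report()]).
#' @param path Output JSON path.
#' @return `write_report_json` returns `path` invisibly; `read_report_json`
#'   returns the parsed list.
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "agreement_report")) report <- unclass(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
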