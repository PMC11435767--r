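# Stroke feature detection on the forward hull-acceleration axis.
#
# Cascade: 9-level bior4.4 undecimated decomposition; drive starts are the
# troughs of the level-3 approximation (peaks of its negation); consecutive
# drive starts segment the session; the cycle start of each stroke is the
# last prominent peak of cA3 before its catch trough (the "first peak" of
# the time-reversed segment); the drive end is the first local minimum of
# the level-2 approximation after the in-window drive-peak acceleration.
# Detection is fully deterministic; plateau ties resolve to the earliest
# sample.

#' Detect drive starts from the level-3 approximation
#'
#' The catch trough — the deep negative spike at the recovery-to-drive
#' transition — is the most robust landmark of hull acceleration. The
#' level-3 approximation is negated and its peaks located subject to the
#' configuration's separation and relative-prominence constraints.
#'
#' @param cA3 Level-3 approximation coefficient (from [approximation()]).
#' @param fs Sampling rate, Hz.
#' @param cfg A [peak_config()].
#' @return Sorted integer vector of drive-start sample indices; empty for
#'   constant or featureless input.
#' @export
detect_drive_starts <- function(cA3, fs, cfg = peak_config()) {
  stopifnot(fs > 0)
  neg <- -cA3
  find_peaks(
    neg,
    min_separation = cfg$min_separation_s * fs,
    min_prominence = .relative_prominence(neg, cfg)
  )
}

#' Segment a session into strokes between consecutive drive starts
#'
#' @param drive_starts Sorted integer vector of drive-start indices.
#' @param n_samples Trace length (bounds check only).
#' @return List of length `length(drive_starts) - 1`, each element
#'   `c(start, end)` describing the half-open interval `[start, end)`;
#'   empty list for fewer than two drive starts.
#' @export
segment_strokes <- function(drive_starts, n_samples) {
  if (is.unsorted(drive_starts, strictly = TRUE)) {
    stop("drive_starts must be strictly increasing", call. = FALSE)
  }
  if (length(drive_starts) && (drive_starts[1] < 1 ||
      drive_starts[length(drive_starts)] > n_samples)) {
    stop("drive_starts out of range", call. = FALSE)
  }
  if (length(drive_starts) < 2L) return(list())
  Map(c, drive_starts[-length(drive_starts)], drive_starts[-1])
}

#' Detect the cycle start within one stroke segment
#'
#' The cycle start is the local acceleration peak immediately preceding the
#' catch trough: the first peak of the time-reversed segment, i.e. the last
#' prominent local maximum of `cA3` inside `[segment[1], segment[2])`. It is
#' assigned to the stroke whose trough terminates the segment.
#'
#' @param cA3 Level-3 approximation (full trace).
#' @param segment `c(start, end)` half-open window between consecutive
#'   drive starts.
#' @param cfg A [peak_config()]; only the prominence fraction is used, taken
#'   relative to the segment's amplitude span.
#' @return Absolute sample index of the cycle start. If the segment has no
#'   prominent peak (degenerate input), falls back to `segment[2] - 1` with
#'   a warning.
#' @export
detect_cycle_start <- function(cA3, segment, cfg = peak_config()) {
  lo <- segment[1]
  hi <- segment[2] - 1L
  seg <- cA3[lo:hi]
  pk <- find_peaks(seg, min_prominence = .relative_prominence(seg, cfg))
  if (!length(pk)) {
    warning("no cycle-start peak in segment [", lo, ", ", segment[2],
            "); falling back to segment end", call. = FALSE)
    return(as.integer(hi))
  }
  as.integer(lo + pk[length(pk)] - 1L)
}

#' Detect the drive end within one stroke window
#'
#' Finds the drive-peak acceleration (global maximum of the level-2
#' approximation inside `[window[1], window[2])`) and returns the first
#' local minimum after it — the valley marking blade extraction.
#'
#' @param cA2 Level-2 approximation (full trace).
#' @param window `c(start, end)` half-open window, anchored at the stroke's
#'   cycle start and ending at the next stroke's cycle start.
#' @param cfg A [peak_config()]; the first minimum must clear the
#'   configuration's prominence fraction (relative to the window's
#'   amplitude span) so residual measurement noise on the descending drive
#'   slope cannot trigger it early.
#' @param fs Sampling rate, Hz (converts the refinement half-width to
#'   samples).
#' @return Absolute sample index of the drive end. If the signal never
#'   turns upward before the window closes, falls back to the window
#'   midpoint with a warning.
#' @export
detect_drive_end <- function(cA2, window, cfg = peak_config(), fs = 200) {
  lo <- window[1]
  hi <- window[2] - 1L
  seg <- cA2[lo:hi]
  m <- which.max(seg)
  after <- seg[m:length(seg)]
  # first sufficiently prominent local minimum after the drive peak
  mins <- find_peaks(-after, min_prominence = .relative_prominence(-seg, cfg))
  if (!length(mins)) {
    warning("no drive-end minimum in window [", lo, ", ", window[2],
            "); falling back to window midpoint", call. = FALSE)
    return(as.integer(lo + (hi - lo) %/% 2))
  }
  i0 <- as.integer(lo + (m - 1L) + mins[1] - 1L)
  # localise the broad valley to its vertex; the raw first-minimum index
  # jitters with residual noise on the flat valley floor
  r <- as.integer(round(cfg$refine_halfwidth_s * fs))
  .refine_extremum(cA2, i0, r, lo = lo + m, hi = hi, minimum = TRUE)
}

#' Detect all stroke events in an acceleration trace
#'
#' Runs the full cascade: undecimated decomposition, drive-start peaks on
#' negated cA3, segmentation, per-stroke cycle start on reversed cA3, and
#' drive end on cA2. The first and last incomplete cycles are discarded (a
#' stroke needs a complete neighbouring trough on each side).
#'
#' @param trace An [accel_trace()]; detection runs on `trace$ax`.
#' @param cfg A [peak_config()].
#' @param levels,wavelet Decomposition depth and family (defaults 9,
#'   `"bior4.4"`).
#' @return A [stroke_events()] object.
#' @export
detect_stroke_events <- function(trace, cfg = peak_config(), levels = 9L,
                                 wavelet = "bior4.4") {
  stopifnot(inherits(trace, "accel_trace"))
  d <- uwt_decompose(trace$ax, levels = levels, wavelet = wavelet)
  cA3 <- approximation(d, 3)
  cA2 <- approximation(d, 2)

  ds <- detect_drive_starts(cA3, trace$fs, cfg)
  if (length(ds) < 2L) {
    stop("no strokes: fewer than 2 drive starts detected", call. = FALSE)
  }
  segs <- segment_strokes(ds, length(cA3))
  # cycle start of stroke i (trough ds[i]) lives in the segment ending at
  # ds[i]; the first trough has no preceding segment and is discarded.
  cs <- vapply(segs, function(s) detect_cycle_start(cA3, s, cfg), numeric(1))
  # drive end of stroke i is searched in [cs[i], cs[i+1]); the last trough
  # has no following cycle start and is discarded.
  m <- length(ds)                      # strokes 2..m have a cycle start
  keep <- seq_len(m - 2L)              # strokes 2..m-1 are complete
  de <- vapply(keep, function(i) {
    detect_drive_end(cA2, c(cs[i], cs[i + 1L]), cfg, fs = trace$fs)
  }, numeric(1))

  cs_k <- as.integer(cs[keep])
  ds_k <- as.integer(ds[keep + 1L])
  ok <- cs_k <= ds_k & ds_k < de
  if (length(ok) > 1L) {
    ok[-length(ok)] <- ok[-length(ok)] & de[-length(de)] < cs_k[-1L]
  }
  if (any(!ok)) {
    warning(sum(!ok), " stroke(s) dropped for violating event ordering",
            call. = FALSE)
  }
  stroke_events(cs_k[ok], ds_k[ok], as.integer(de[ok]),
                fs = trace$fs, t0 = trace$t0)
}

#' Per-stroke timing metrics
#'
#' Drive time is the elapsed time from drive start to drive end of the same
#' stroke; stroke time is the elapsed time between consecutive drive ends
#' (there is one fewer stroke time than strokes).
#'
#' @param events A non-empty [stroke_events()].
#' @return An object of class `stroke_metrics`: list with `drive_time`
#'   (seconds, one per stroke), `stroke_time` (seconds, one per consecutive
#'   pair), `drive_end_s` (absolute drive-end times) and `fs`.
#' @export
compute_metrics <- function(events) {
  stopifnot(inherits(events, "stroke_events"))
  if (!length(events)) stop("empty event set", call. = FALSE)
  dt <- (events$drive_end - events$drive_start) / events$fs
  st <- diff(events$drive_end) / events$fs
  structure(
    list(drive_time = dt, stroke_time = st,
         drive_end_s = events$t0 + (events$drive_end - 1) / events$fs,
         fs = events$fs),
    class = "stroke_metrics"
  )
}
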