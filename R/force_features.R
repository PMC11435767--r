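# Oarlock-force reference procedure: gate summation, per-stroke peak
# detection, positive-to-negative zero-crossing drive ends (sub-sample
# interpolated), force stroke times, and a configurable threshold-crossing
# drive-time surrogate for the proprietary oarlock-system algorithm.

#' Sum horizontal gate forces into a total system force
#'
#' @param force A [force_trace()] or a numeric matrix (samples x gates).
#' @return Numeric vector: elementwise sum across gates (total horizontal
#'   force on the hull-rowers system), newtons.
#' @export
sum_gate_forces <- function(force) {
  g <- if (inherits(force, "force_trace")) force$gates else as.matrix(force)
  rowSums(g)
}

#' Detect per-stroke force peaks
#'
#' Simple peak detection on the summed force trace, constrained by the
#' configuration's separation and relative prominence so each drive
#' contributes exactly one dominant peak.
#'
#' @param f_tx Numeric vector, summed horizontal force (newtons).
#' @param fs Sampling rate, Hz.
#' @param cfg A [peak_config()].
#' @return Sorted integer vector of peak indices (possibly empty).
#' @export
detect_force_peaks <- function(f_tx, fs, cfg = peak_config()) {
  stopifnot(fs > 0)
  find_peaks(
    f_tx,
    min_separation = cfg$min_separation_s * fs,
    min_prominence = .relative_prominence(f_tx, cfg)
  )
}

#' Force-derived drive end: first positive-to-negative zero crossing
#'
#' Scans forward from a force peak for the first sign change from
#' non-negative to negative and returns the crossing time, linearly
#' interpolated between the bracketing samples to sub-sample resolution.
#'
#' @param f_tx Numeric vector, summed horizontal force.
#' @param peak_idx Index of the stroke's force peak; `f_tx[peak_idx]` must
#'   be positive.
#' @param fs Sampling rate, Hz.
#' @param t0 Timestamp of sample 1, seconds.
#' @return Crossing time in seconds, or `NA_real_` (with a warning) when
#'   the trace never turns negative before it ends.
#' @export
detect_force_drive_end <- function(f_tx, peak_idx, fs, t0 = 0) {
  stopifnot(fs > 0, peak_idx >= 1, peak_idx <= length(f_tx))
  if (!(f_tx[peak_idx] > 0)) {
    warning("force at peak_idx is not positive; no drive end", call. = FALSE)
    return(NA_real_)
  }
  n <- length(f_tx)
  if (peak_idx >= n) {
    warning("no positive-to-negative crossing after peak", call. = FALSE)
    return(NA_real_)
  }
  seg <- f_tx[peak_idx:n]
  k <- which(seg[-length(seg)] >= 0 & seg[-1] < 0)
  if (!length(k)) {
    warning("no positive-to-negative crossing after peak", call. = FALSE)
    return(NA_real_)
  }
  i <- peak_idx + k[1] - 1L                 # f_tx[i] >= 0 > f_tx[i+1]
  frac <- f_tx[i] / (f_tx[i] - f_tx[i + 1L])
  t0 + (i - 1 + frac) / fs
}

#' Detect all force events in a session
#'
#' Convenience wrapper: sums the gates, finds per-stroke peaks, and derives
#' each stroke's zero-crossing drive end. Strokes whose crossing cannot be
#' found are dropped.
#'
#' @param force A [force_trace()].
#' @param cfg A [peak_config()].
#' @return An object of class `force_events`: list with `peaks` (indices),
#'   `peak_time_s`, `drive_end_s` (interpolated times), `fs`, `t0`.
#' @export
detect_force_events <- function(force, cfg = peak_config()) {
  stopifnot(inherits(force, "force_trace"))
  f_tx <- sum_gate_forces(force)
  pk <- detect_force_peaks(f_tx, force$fs, cfg)
  de <- vapply(pk, function(p) {
    suppressWarnings(detect_force_drive_end(f_tx, p, force$fs, force$t0))
  }, numeric(1))
  ok <- !is.na(de)
  if (any(!ok)) {
    warning(sum(!ok), " stroke(s) without a zero-crossing drive end dropped",
            call. = FALSE)
  }
  structure(
    list(peaks = pk[ok], peak_time_s = force$t0 + (pk[ok] - 1) / force$fs,
         drive_end_s = de[ok], fs = force$fs, t0 = force$t0),
    class = "force_events"
  )
}

#' Force-derived stroke times
#'
#' @param drive_end_s Strictly increasing vector of force-derived drive-end
#'   times, seconds.
#' @return Numeric vector of consecutive differences (one fewer element).
#' @export
force_stroke_times <- function(drive_end_s) {
  if (length(drive_end_s) < 2L) return(numeric(0))
  if (is.unsorted(drive_end_s, strictly = TRUE)) {
    stop("drive-end times must be strictly increasing", call. = FALSE)
  }
  diff(drive_end_s)
}

# Interpolated time where seg crosses `thr` going up (dir = 1) or down
# (dir = -1), searching forward from `from`; NA when never crossed.
.cross_time <- function(x, thr, from, to, dir, fs, t0) {
  idx <- from:(to - 1L)
  if (dir > 0) {
    hit <- which(x[idx] < thr & x[idx + 1L] >= thr)
  } else {
    hit <- which(x[idx] >= thr & x[idx + 1L] < thr)
  }
  if (!length(hit)) return(NA_real_)
  i <- idx[hit[1]]
  frac <- (thr - x[i]) / (x[i + 1L] - x[i])
  t0 + (i - 1 + frac) / fs
}

#' Threshold-crossing drive time (surrogate for the proprietary algorithm)
#'
#' For each stroke and gate, the drive is delimited by the last upward
#' crossing of `rise_threshold_N` before the gate's in-stroke force peak and
#' the first downward crossing of `fall_threshold_N` after it; both times
#' are linearly interpolated. Per-stroke system drive time is the mean over
#' gates with a valid crossing pair. The true thresholds of the commercial
#' oarlock system are proprietary; these defaults are non-canonical.
#'
#' @param force A [force_trace()].
#' @param rise_threshold_N,fall_threshold_N Crossing thresholds per gate,
#'   newtons (> 0).
#' @param cfg A [peak_config()] used to find per-stroke windows on the
#'   summed force.
#' @return List with `per_gate` (strokes x gates matrix of drive times,
#'   `NA` where a gate never crossed), `drive_time` (per-stroke mean over
#'   gates), `rise_time_s`/`fall_time_s` (per-gate matrices) and
#'   `peak_time_s` (stroke anchor times from the summed force).
#' @export
threshold_drive_time <- function(force, rise_threshold_N = 30,
                                 fall_threshold_N = 30, cfg = peak_config()) {
  stopifnot(inherits(force, "force_trace"),
            rise_threshold_N > 0, fall_threshold_N > 0)
  f_tx <- sum_gate_forces(force)
  pk <- detect_force_peaks(f_tx, force$fs, cfg)
  ns <- length(pk)
  ng <- ncol(force$gates)
  per_gate <- rise <- fall <- matrix(NA_real_, ns, ng)
  if (ns == 0) {
    return(list(per_gate = per_gate, drive_time = numeric(0),
                rise_time_s = rise, fall_time_s = fall,
                peak_time_s = numeric(0)))
  }
  # stroke windows: midpoints between consecutive summed-force peaks
  bounds <- c(1L, as.integer(floor((pk[-ns] + pk[-1]) / 2)), length(f_tx))
  for (s in seq_len(ns)) {
    lo <- bounds[s]
    hi <- bounds[s + 1L]
    for (g in seq_len(ng)) {
      fg <- force$gates[, g]
      gp <- lo - 1L + which.max(fg[lo:hi])
      if (!(fg[gp] > max(rise_threshold_N, fall_threshold_N))) next
      r <- .cross_time(fg, rise_threshold_N, lo, gp, 1, force$fs, force$t0)
      f <- .cross_time(fg, fall_threshold_N, gp, hi, -1, force$fs, force$t0)
      rise[s, g] <- r
      fall[s, g] <- f
      if (!is.na(r) && !is.na(f)) per_gate[s, g] <- f - r
    }
  }
  list(
    per_gate = per_gate,
    drive_time = rowMeans(per_gate, na.rm = TRUE),
    rise_time_s = rise, fall_time_s = fall,
    peak_time_s = force$t0 + (pk - 1) / force$fs
  )
}

#' Pair strokes across measurement systems by drive-end proximity
#'
#' Greedy nearest matching of accelerometer drive-end times to
#' force-derived drive-end times, one-to-one, within a tolerance of half
#' the median force stroke time (unambiguous for rates up to 60 spm).
#'
#' @param accel_de_s,force_de_s Drive-end times from each system, seconds.
#' @param tol_s Matching tolerance; default `0.5 * median(diff(force_de_s))`.
#' @return List with `a`, `b` (matched index vectors into the two inputs,
#'   in increasing time order) and `n_unmatched`.
#' @export
pair_strokes <- function(accel_de_s, force_de_s, tol_s = NULL) {
  if (is.null(tol_s)) {
    if (length(force_de_s) < 2L) {
      stop("need >= 2 force strokes to derive the pairing tolerance",
           call. = FALSE)
    }
    tol_s <- 0.5 * stats::median(diff(force_de_s))
  }
  cand <- expand.grid(a = seq_along(accel_de_s), b = seq_along(force_de_s))
  cand$d <- abs(accel_de_s[cand$a] - force_de_s[cand$b])
  cand <- cand[cand$d <= tol_s, , drop = FALSE]
  cand <- cand[order(cand$d, cand$a), , drop = FALSE]
  used_a <- logical(length(accel_de_s))
  used_b <- logical(length(force_de_s))
  sel_a <- sel_b <- integer(0)
  for (r in seq_len(nrow(cand))) {
    ia <- cand$a[r]
    ib <- cand$b[r]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
      sel_a <- c(sel_a, ia)
      sel_b <- c(sel_b, ib)
    }
  }
  ord <- order(sel_a)
  list(a = sel_a[ord], b = sel_b[ord],
       n_unmatched = sum(!used_a) + sum(!used_b))
}
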