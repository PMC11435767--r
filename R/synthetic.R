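# Ground-truth generator of paired hull-acceleration (200 Hz) and oarlock
# force (50 Hz) sessions.
#
# The acceleration waveform is a per-stroke sum of narrow Gaussian bumps on
# a zero baseline, one per landmark of the stereotyped stroke profile:
# recovery hump (cycle start), deep catch trough (drive start), positive
# drive peak, and post-drive valley (drive end) -- the "three peaks, three
# valleys" topology of hull acceleration. Bumps are kept several sigma
# apart so, without noise, the extrema of the composite coincide with the
# landmark centres to within a sample. Each gate's force is a half-sine
# drive pulse spanning [drive start, drive end] that continues smoothly
# negative past its zero crossing before settling at a small negative
# recovery baseline, so the positive-to-negative crossing is well defined
# and sub-sample interpolation across it is accurate.

#' Parameters of a synthetic paired session
#'
#' Defaults describe a plausible elite small-boat session: ~32 strokes/min
#' with ~1.5 spm stroke-to-stroke variability, 42% of the cycle spent in
#' the drive with mild independent variability, acceleration landmark
#' amplitudes of a few m/s^2, 0.3 m/s^2 white measurement noise, and
#' 800 N peak horizontal gate force.
#'
#' @param n_strokes Number of strokes (>= 2).
#' @param stroke_rate_spm Mean stroke rate, strokes/min (20-60).
#' @param stroke_rate_sd_spm SD of the per-stroke rate draw.
#' @param drive_fraction Mean fraction of the cycle spent in the drive.
#' @param drive_fraction_sd Per-stroke SD of the drive fraction
#'   (independent of the rate draw; drive and recovery durations vary
#'   semi-independently in real rowing).
#' @param trough_depth,drive_peak,drive_end_valley,recovery_hump Landmark
#'   amplitudes, m/s^2 (trough and valley negative).
#' @param noise_sd Additive Gaussian noise on the acceleration, m/s^2.
#' @param n_gates Number of instrumented oarlocks.
#' @param gate_force_peak_N Peak per-gate horizontal force, newtons.
#' @param gate_timing_jitter_s SD of per-gate, per-stroke onset jitter, s.
#' @param force_baseline_N Recovery-phase gate force, newtons (negative so
#'   the positive-to-negative crossing exists).
#' @param fs_accel,fs_force Sampling rates, Hz.
#' @param seed Integer seed; every stochastic draw is derived from it.
#' @return An object of class `session_params`.
#' @export
session_params <- function(n_strokes = 100, stroke_rate_spm = 32,
                           stroke_rate_sd_spm = 1.5,
                           drive_fraction = 0.42, drive_fraction_sd = 0.015,
                           trough_depth = -4, drive_peak = 2.5,
                           drive_end_valley = -1, recovery_hump = 1.5,
                           noise_sd = 0.3, n_gates = 1,
                           gate_force_peak_N = 800,
                           gate_timing_jitter_s = 0.005,
                           force_baseline_N = -5,
                           fs_accel = 200, fs_force = 50, seed = 1L) {
  stopifnot(
    n_strokes >= 2,
    stroke_rate_spm >= 20, stroke_rate_spm <= 60,
    drive_fraction > 0, drive_fraction < 1,
    noise_sd >= 0, n_gates >= 1, gate_force_peak_N > 0,
    gate_timing_jitter_s >= 0, force_baseline_N < 0,
    fs_accel > 0, fs_force > 0,
    trough_depth < 0, drive_end_valley < 0,
    drive_peak > 0, recovery_hump > 0
  )
  structure(as.list(environment()), class = "session_params")
}

# Landmark times (seconds) of every stroke, given per-stroke periods and
# drive fractions. Stroke i occupies [start_i, start_i + T_i); its catch
# trough is at start_i, its cycle start (recovery hump of the previous
# cycle) precedes the trough by a fixed fraction of the previous period.
.landmark_times <- function(periods, drive_frac, hump_lead_frac = 0.12) {
  lead_in <- periods[1]
  ds <- lead_in + cumsum(c(0, periods[-length(periods)]))
  drv <- drive_frac * periods
  prev_period <- c(periods[1], periods[-length(periods)])
  list(
    cycle_start = ds - hump_lead_frac * prev_period,
    drive_start = ds,
    drive_peak = ds + 0.45 * drv,
    drive_end = ds + drv
  )
}

#' Generate a synthetic acceleration session with ground truth
#'
#' @param p A [session_params()].
#' @return List with `trace` (an [accel_trace()]), `truth` (a
#'   [stroke_events()] holding the landmark-centre sample indices),
#'   `truth_times` (the continuous landmark times in seconds) and `params`.
#' @export
generate_accel_session <- function(p) {
  stopifnot(inherits(p, "session_params"))
  set.seed(p$seed)
  rate <- pmin(pmax(stats::rnorm(p$n_strokes, p$stroke_rate_spm,
                                 p$stroke_rate_sd_spm), 20), 60)
  periods <- 60 / rate
  dfrac <- pmin(pmax(stats::rnorm(p$n_strokes, p$drive_fraction,
                                  p$drive_fraction_sd), 0.25), 0.65)
  lm_ <- .landmark_times(periods, dfrac)

  dur <- lm_$drive_start[p$n_strokes] + periods[p$n_strokes] * 1.5
  t <- seq(0, dur, by = 1 / p$fs_accel)

  # widths scale with the local period; neighbours stay >= 3 sigma apart
  sig_t <- 0.035 * rep(periods, 1)
  bump <- function(centers, amps, sigmas) {
    y <- numeric(length(t))
    for (i in seq_along(centers)) {
      y <- y + amps[i] * exp(-(t - centers[i])^2 / (2 * sigmas[i]^2))
    }
    y
  }
  prev_period <- c(periods[1], periods[-length(periods)])
  ax <- bump(lm_$cycle_start, rep(p$recovery_hump, p$n_strokes), 0.035 * prev_period) +
    bump(lm_$drive_start, rep(p$trough_depth, p$n_strokes), sig_t) +
    bump(lm_$drive_peak, rep(p$drive_peak, p$n_strokes), 0.045 * periods) +
    bump(lm_$drive_end, rep(p$drive_end_valley, p$n_strokes), 0.045 * periods)
  if (p$noise_sd > 0) ax <- ax + stats::rnorm(length(t), 0, p$noise_sd)

  idx <- function(ts) as.integer(round(ts * p$fs_accel)) + 1L
  truth <- stroke_events(idx(lm_$cycle_start), idx(lm_$drive_start),
                         idx(lm_$drive_end), fs = p$fs_accel, t0 = 0)
  trace <- suppressWarnings(accel_trace(
    ax,
    ay = stats::rnorm(length(t), 0, p$noise_sd / 3),
    az = stats::rnorm(length(t), 0, p$noise_sd / 3),
    fs = p$fs_accel, t0 = 0,
    spec = sensor_spec(sample_rate_hz = p$fs_accel)
  ))
  list(trace = trace, truth = truth, truth_times = lm_, params = p)
}

#' Generate the paired oarlock force session
#'
#' Builds per-gate force from the acceleration ground truth: a half-sine
#' pulse over each drive `[drive_start, drive_end]` (peak
#' `gate_force_peak_N`), extended along the same sinusoid slightly past its
#' positive-to-negative zero crossing, then ramped to and held at the
#' negative recovery baseline until just before the next catch. Per-gate,
#' per-stroke onset jitter emulates imperfect crew synchronisation.
#'
#' @param p A [session_params()].
#' @param accel Output of [generate_accel_session()] (its `truth_times`
#'   anchor the pulses).
#' @return A [force_trace()] with `p$n_gates` gates at `p$fs_force` Hz.
#' @export
generate_force_session <- function(p, accel) {
  stopifnot(inherits(p, "session_params"))
  tt <- accel$truth_times
  set.seed(p$seed + 1000003L)
  n_acc <- length(accel$trace$ax)
  dur <- (n_acc - 1) / p$fs_accel
  t <- seq(0, dur, by = 1 / p$fs_force)
  ramp_s <- 0.10                       # baseline settle time after the pulse
  gates <- matrix(p$force_baseline_N, nrow = length(t), ncol = p$n_gates)
  for (g in seq_len(p$n_gates)) {
    fg <- rep(p$force_baseline_N, length(t))
    jit <- stats::rnorm(p$n_strokes, 0, p$gate_timing_jitter_s)
    undershoot <- 0.2                # post-extraction dip, fraction of peak
    for (s in seq_len(p$n_strokes)) {
      on <- tt$drive_start[s] + jit[s]
      d <- tt$drive_end[s] - tt$drive_start[s]
      # the sine continues past its zero crossing at on + d down to a brief
      # negative undershoot (blade extraction), so the crossing sits on a
      # smooth inflection and interpolates to sub-millisecond accuracy even
      # at 50 Hz; it then relaxes linearly to the recovery baseline
      ext <- d / pi * asin(undershoot)
      in_pulse <- t >= on & t <= on + d + ext
      fg[in_pulse] <- p$gate_force_peak_N * sin(pi * (t[in_pulse] - on) / d)
      in_ramp <- t > on + d + ext & t <= on + d + ext + ramp_s
      u0 <- -undershoot * p$gate_force_peak_N
      fg[in_ramp] <- u0 + (p$force_baseline_N - u0) *
        (t[in_ramp] - (on + d + ext)) / ramp_s
      # pre-onset rise from baseline to zero over a short ramp
      pre <- t >= on - ramp_s & t < on
      fg[pre] <- p$force_baseline_N * (on - t[pre]) / ramp_s
    }
    gates[, g] <- fg
  }
  force_trace(gates, fs = p$fs_force, t0 = 0)
}

#' Boat-class presets
#'
#' Stroke-rate distributions and stroke counts of the three boat classes of
#' a race-simulation cohort (women's eight, coxless four, single scull),
#' with one instrumented gate per oar.
#'
#' @param stroke_scale Multiplier on the per-class stroke counts (use
#'   e.g. 0.1 for quick tests).
#' @return Named list of [session_params()] argument lists.
#' @export
boat_class_presets <- function(stroke_scale = 1) {
  list(
    `W8+` = list(n_strokes = max(2, round(221 * stroke_scale)),
                 stroke_rate_spm = 37.88, stroke_rate_sd_spm = 1.46,
                 n_gates = 8),
    `W4-` = list(n_strokes = max(2, round(183 * stroke_scale)),
                 stroke_rate_spm = 36.72, stroke_rate_sd_spm = 1.90,
                 n_gates = 4),
    W1x = list(n_strokes = max(2, round(181 * stroke_scale)),
               stroke_rate_spm = 31.90, stroke_rate_sd_spm = 1.61,
               n_gates = 2)
  )
}

#' Generate a paired multi-class cohort
#'
#' One paired acceleration/force session per preset, with per-class seeds
#' derived from `seed`.
#'
#' @param presets Output of [boat_class_presets()] (or a compatible named
#'   list of parameter lists).
#' @param seed Base seed.
#' @param ... Overrides forwarded to every [session_params()] call.
#' @return Named list (one element per class) of lists with `accel`,
#'   `force`, `params`.
#' @export
generate_cohort <- function(presets = boat_class_presets(), seed = 1L, ...) {
  stopifnot(length(presets) >= 1)
  out <- lapply(seq_along(presets), function(i) {
    args <- utils::modifyList(presets[[i]],
                              c(list(seed = seed + i * 101L), list(...)))
    p <- do.call(session_params, args)
    accel <- generate_accel_session(p)
    force <- generate_force_session(p, accel)
    list(accel = accel, force = force, params = p)
  })
  names(out) <- names(presets)
  out
}
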