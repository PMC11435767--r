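# End-to-end comparison of the accelerometer-derived stroke metrics with
# the oarlock-force reference on one paired session.

#' Compare accelerometer and force-derived stroke metrics
#'
#' Runs stroke detection on the acceleration trace and the force reference
#' procedure on the gate trace, pairs strokes across systems by drive-end
#' proximity, and assembles the agreement report for drive time
#' (accelerometer vs gate-averaged threshold-crossing drive time) and
#' stroke time (accelerometer vs zero-crossing force stroke time).
#'
#' @param trace An [accel_trace()].
#' @param force The paired [force_trace()].
#' @param cfg A [peak_config()] shared by both detectors.
#' @param rise_threshold_N,fall_threshold_N Thresholds for the
#'   drive-time surrogate (see [threshold_drive_time()]).
#' @param group Cohort label attached to the report blocks.
#' @param icc_model Default ICC variant for the report.
#' @return List with `events` ([stroke_events()]), `metrics`,
#'   `force_events`, `threshold_dt`, `pairs` (stroke matching),
#'   `paired` (the [paired_measures()] fed to the report) and `report`
#'   (an `agreement_report`).
#' @export
compare_systems <- function(trace, force, cfg = peak_config(),
                            rise_threshold_N = 30, fall_threshold_N = 30,
                            group = "all",
                            icc_model = c("two_way_random", "one_way")) {
  icc_model <- match.arg(icc_model)
  ev <- detect_stroke_events(trace, cfg)
  met <- compute_metrics(ev)
  fe <- detect_force_events(force, cfg)
  th <- threshold_drive_time(force, rise_threshold_N, fall_threshold_N, cfg)
  th_row <- match(fe$peak_time_s, th$peak_time_s)

  pairs <- pair_strokes(met$drive_end_s, fe$drive_end_s)
  if (length(pairs$a) < 3L) {
    stop("fewer than 3 matched strokes between systems", call. = FALSE)
  }

  dt_a <- met$drive_time[pairs$a]
  dt_b <- th$drive_time[th_row[pairs$b]]
  keep <- is.finite(dt_b)

  # stroke times need consecutive matched strokes in both systems
  r <- seq_len(length(pairs$a) - 1L)
  consec <- pairs$a[r + 1L] == pairs$a[r] + 1L &
    pairs$b[r + 1L] == pairs$b[r] + 1L
  st_a <- met$stroke_time[pairs$a[r][consec]]
  st_f <- force_stroke_times(fe$drive_end_s)
  st_b <- st_f[pairs$b[r][consec]]

  paired <- list(
    drive_time = paired_measures(dt_a[keep], dt_b[keep],
                                 label = "drive_time", group = group),
    stroke_time = paired_measures(st_a, st_b,
                                  label = "stroke_time", group = group)
  )
  list(
    events = ev, metrics = met, force_events = fe, threshold_dt = th,
    pairs = pairs, paired = paired,
    report = build_report(paired, icc_model = icc_model)
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the paired cohort, runs [compare_systems()] per class, and
#' merges the per-class report blocks.
#'
#' @param presets See [generate_cohort()].
#' @param seed Base seed for the generator.
#' @param cfg,rise_threshold_N,fall_threshold_N Detection parameters.
#' @param ... Session-parameter overrides forwarded to [generate_cohort()].
#' @return List with `sessions` (per-class [compare_systems()] outputs) and
#'   `report` (merged `agreement_report`).
#' @export
run_cohort_comparison <- function(presets = boat_class_presets(), seed = 1L,
                                  cfg = peak_config(),
                                  rise_threshold_N = 30,
                                  fall_threshold_N = 30, ...) {
  cohort <- generate_cohort(presets, seed = seed, ...)
  sessions <- lapply(names(cohort), function(cls) {
    s <- cohort[[cls]]
    compare_systems(s$accel$trace, s$force, cfg = cfg,
                    rise_threshold_N = rise_threshold_N,
                    fall_threshold_N = fall_threshold_N, group = cls)
  })
  names(sessions) <- names(cohort)
  blocks <- do.call(c, lapply(sessions, function(s) unclass(s$report)))
  names(blocks) <- sub("^[^.]*\\.", "", names(blocks))
  list(sessions = sessions,
       report = structure(blocks, class = "agreement_report"),
       cohort = cohort)
}
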