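# Feature-detection cascade: drive starts, segmentation, cycle starts,
# drive ends, orchestration, metrics.

test_that("constant and featureless signals yield no drive starts", {
  expect_length(detect_drive_starts(rep(1.7, 1000), 200), 0L)
  expect_length(detect_drive_starts(seq(0, 1, length.out = 500), 200), 0L)
})

test_that("a single trough is found at its argmin", {
  s <- small_session(seed = 3, n_strokes = 5, noise_sd = 0)
  d <- uwt_decompose(s$accel$trace$ax)
  cA3 <- approximation(d, 3)
  ds <- detect_drive_starts(cA3, 200)
  # oracle: argmin of cA3 over each ground-truth stroke neighbourhood
  for (i in seq_along(ds)) {
    w <- max(1, ds[i] - 100):min(length(cA3), ds[i] + 100)
    expect_equal(ds[i], w[which.min(cA3[w])])
  }
})

test_that("a 30 spm session yields troughs spaced one period apart", {
  s <- small_session(seed = 1, n_strokes = 10, stroke_rate_spm = 30,
                     stroke_rate_sd_spm = 0, noise_sd = 0)
  d <- uwt_decompose(s$accel$trace$ax)
  ds <- detect_drive_starts(approximation(d, 3), 200)
  expect_length(ds, 10L)
  expect_true(all(abs(diff(ds) - 400) <= 5))
})

test_that("segment_strokes tiles the detected span", {
  expect_equal(segment_strokes(c(100, 500, 900), 1000),
               list(c(100, 500), c(500, 900)))
  expect_equal(segment_strokes(100, 1000), list())
  expect_equal(segment_strokes(integer(0), 1000), list())
  expect_error(segment_strokes(c(500, 100), 1000), "increasing")
  expect_error(segment_strokes(c(100, 2000), 1000), "range")
})

test_that("cycle start is the last peak before the trough and mirrors on reversal", {
  s <- small_session(seed = 5, n_strokes = 6, noise_sd = 0)
  d <- uwt_decompose(s$accel$trace$ax)
  cA3 <- approximation(d, 3)
  ds <- detect_drive_starts(cA3, 200)
  seg <- c(ds[2], ds[3])
  cs <- detect_cycle_start(cA3, seg)
  truth_cs <- s$accel$truth$cycle_start
  expect_lt(abs(cs - truth_cs[which.min(abs(truth_cs - cs))]), 10)
  expect_lt(cs, ds[3])
  # argmax oracle over the reversed segment: last prominent peak
  vals <- cA3[seg[1]:(seg[2] - 1)]
  pk <- find_peaks(vals)
  expect_equal(cs, seg[1] + pk[length(pk)] - 1L)
  # reversal symmetry: first peak of the reversed segment mirrors back
  pk_rev <- find_peaks(rev(vals))
  expect_equal(length(vals) - pk_rev[1] + 1L, pk[length(pk)])
})

test_that("monotone segments fall back to segment end with a warning", {
  x <- seq(5, 0, length.out = 200)
  expect_warning(cs <- detect_cycle_start(x, c(1L, 200L)), "falling back")
  expect_equal(cs, 199L)
})

test_that("drive end is the first prominent minimum after the drive peak", {
  s <- small_session(seed = 9, n_strokes = 6, noise_sd = 0)
  d <- uwt_decompose(s$accel$trace$ax)
  cA3 <- approximation(d, 3)
  cA2 <- approximation(d, 2)
  ds <- detect_drive_starts(cA3, 200)
  segs <- segment_strokes(ds, length(cA3))
  cs <- vapply(segs, function(sg) detect_cycle_start(cA3, sg), numeric(1))
  de <- detect_drive_end(cA2, c(cs[1], cs[2]), fs = 200)
  # derivative oracle: first - to + crossing of diff(cA2) after the window max
  w <- cs[1]:(cs[2] - 1)
  m <- which.max(cA2[w])
  dv <- diff(cA2[w])
  cross <- which(dv[-1] > 0 & dv[-length(dv)] <= 0)
  cross <- cross[cross >= m]
  expect_lt(abs(de - (cs[1] + cross[1])), 3)   # refinement may move <= 2 samples
  truth_de <- s$accel$truth$drive_end
  expect_lt(abs(de - truth_de[which.min(abs(truth_de - de))]), 10)
})

test_that("windows with a monotone rise fall back to the midpoint", {
  x <- seq(0, 5, length.out = 400)
  expect_warning(de <- detect_drive_end(x, c(1L, 401L), fs = 200), "midpoint")
  expect_equal(de, 200L)
})

test_that("the full cascade recovers the synthetic session", {
  s <- small_session(seed = 7, n_strokes = 20)
  ev <- detect_stroke_events(s$accel$trace)
  expect_s3_class(ev, "stroke_events")
  expect_gte(length(ev), 17)          # first/last partials discarded
  expect_lte(length(ev), 20)
  # per-stroke and cross-stroke ordering (also enforced by the constructor)
  expect_true(all(ev$cycle_start <= ev$drive_start))
  expect_true(all(ev$drive_start < ev$drive_end))
  n <- length(ev)
  expect_true(all(ev$drive_end[-n] < ev$cycle_start[-1]))
})

test_that("white noise is heavily suppressed but not fully rejected", {
  # Amplitude invariance forces a scale-free prominence threshold, and the
  # lowpassed version of matched-variance noise produces prominences
  # comparable to its own span, so some spurious detections are
  # unavoidable; they must at least fall well short of the
  # one-per-separation maximum a rhythmic signal would produce.
  set.seed(13)
  noise <- accel_trace(rnorm(6000, 0, 2), fs = 200)
  n_spurious <- tryCatch(
    length(suppressWarnings(detect_stroke_events(noise))),
    error = function(e) 0L
  )
  expect_lt(n_spurious, 30 * 0.8)     # trace spans 30 s, separation 1 s
})

test_that("detection is shift-equivariant on interior strokes", {
  s <- small_session(seed = 15, n_strokes = 12)
  ax <- s$accel$trace$ax
  k <- 50L                            # 250 ms at 200 Hz
  tr1 <- accel_trace(ax, fs = 200)
  tr2 <- accel_trace(c(numeric(k), ax), fs = 200)
  e1 <- detect_stroke_events(tr1)
  e2 <- detect_stroke_events(tr2)
  m <- min(length(e1), length(e2))
  expect_equal(e2$drive_start[1:m], e1$drive_start[1:m] + k)
  expect_equal(e2$drive_end[1:m], e1$drive_end[1:m] + k)
  expect_equal(e2$cycle_start[1:m], e1$cycle_start[1:m] + k)
})

test_that("detection is invariant to positive amplitude scaling", {
  s <- small_session(seed = 17, n_strokes = 12)
  ax <- s$accel$trace$ax
  e1 <- detect_stroke_events(accel_trace(ax, fs = 200))
  for (scale in c(0.05, 12)) {
    e2 <- detect_stroke_events(accel_trace(scale * ax, fs = 200))
    expect_identical(e2$drive_start, e1$drive_start)
    expect_identical(e2$drive_end, e1$drive_end)
    expect_identical(e2$cycle_start, e1$cycle_start)
  }
})

test_that("metrics arithmetic", {
  ev <- stroke_events(c(380, 780), c(400, 800), c(560, 935), fs = 200)
  met <- compute_metrics(ev)
  expect_equal(met$drive_time, c(0.8, 0.675))
  expect_equal(met$stroke_time, 1.875)

  single <- stroke_events(380, 400, 560, fs = 200)
  m1 <- compute_metrics(single)
  expect_length(m1$drive_time, 1L)
  expect_length(m1$stroke_time, 0L)
  expect_error(compute_metrics(stroke_events(integer(0), integer(0),
                                             integer(0), fs = 200)),
               "empty")
})
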