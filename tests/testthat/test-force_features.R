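# Force reference procedure: summation, peaks, zero-crossing drive ends,
# stroke times, threshold drive-time surrogate, cross-system pairing.

half_sine_train <- function(n_pulses = 6, period_s = 1.875, dur_s = 0.8,
                            amp = 800, fs = 50, baseline = -5) {
  t <- seq(0, n_pulses * period_s + 1, by = 1 / fs)
  f <- rep(baseline, length(t))
  onsets <- period_s * (seq_len(n_pulses) - 1) + 0.5
  for (on in onsets) {
    ext <- dur_s / pi * asin(min(1, -baseline / amp))
    in_p <- t >= on & t <= on + dur_s + ext
    f[in_p] <- amp * sin(pi * (t[in_p] - on) / dur_s)
    pre <- t >= on - 0.1 & t < on
    f[pre] <- baseline * (on - t[pre]) / 0.1
  }
  list(t = t, f = f, onsets = onsets, dur = dur_s, amp = amp, fs = fs)
}

test_that("gate summation is elementwise, linear, permutation-invariant", {
  expect_equal(sum_gate_forces(cbind(c(1, 2, 3), c(4, 5, 6))), c(5, 7, 9))
  g <- matrix(rnorm(60), ncol = 1)
  expect_equal(sum_gate_forces(g), g[, 1])                # single gate
  g8 <- matrix(rep(g, 8), ncol = 8)
  expect_equal(sum_gate_forces(g8), 8 * g[, 1])           # linearity
  gp <- cbind(g, 2 * g, -g)
  expect_equal(sum_gate_forces(gp), sum_gate_forces(gp[, c(3, 1, 2)]))
})

test_that("one dominant peak per half-sine pulse, at the pulse centre", {
  hs <- half_sine_train()
  pk <- detect_force_peaks(hs$f, hs$fs)
  expect_length(pk, 6L)
  centres <- hs$onsets + hs$dur / 2
  expect_true(all(abs((pk - 1) / hs$fs - centres) <= 1.5 / hs$fs))
  expect_length(detect_force_peaks(numeric(200), 50), 0L)
})

test_that("amplitude jitter does not change the pulse count", {
  hs <- half_sine_train()
  set.seed(4)
  scale <- rep(1, length(hs$f))
  for (i in seq_along(hs$onsets)) {
    in_p <- hs$t >= hs$onsets[i] & hs$t <= hs$onsets[i] + hs$dur
    scale[in_p] <- 1 + runif(1, -0.1, 0.1)
  }
  expect_length(detect_force_peaks(hs$f * scale, hs$fs), 6L)
})

test_that("zero-crossing drive end matches the analytic root", {
  hs <- half_sine_train(n_pulses = 1, dur_s = 0.8)
  pk <- detect_force_peaks(hs$f, hs$fs)
  de <- detect_force_drive_end(hs$f, pk[1], hs$fs)
  expect_lt(abs(de - (hs$onsets[1] + 0.8)), 1 / (10 * hs$fs))
})

test_that("degenerate traces yield missing drive ends with a warning", {
  pos <- rep(5, 100)
  pos[50] <- 10
  expect_warning(de <- detect_force_drive_end(pos, 50L, 50), "no positive")
  expect_true(is.na(de))
  # sign-flipped pulse on a zero baseline: the global maximum is not
  # positive, so no positive-to-negative crossing can follow it
  neg <- -800 * sin(pi * seq(0, 1, by = 1 / 50))
  neg <- c(neg, numeric(20))
  expect_warning(de2 <- detect_force_drive_end(neg, which.max(neg), 50),
                 "not positive")
  expect_true(is.na(de2))
})

test_that("force stroke times are consecutive differences", {
  expect_equal(force_stroke_times(c(1.0, 2.875, 4.75)), c(1.875, 1.875))
  expect_equal(force_stroke_times(3.2), numeric(0))
  expect_error(force_stroke_times(c(2, 1, 3)), "increasing")
})

test_that("synthetic session force stroke times track the rate", {
  s <- small_session(seed = 19, n_strokes = 15, stroke_rate_spm = 32,
                     stroke_rate_sd_spm = 0, drive_fraction_sd = 0,
                     gate_timing_jitter_s = 0)
  fe <- detect_force_events(s$force)
  st <- force_stroke_times(fe$drive_end_s)
  expect_true(all(abs(st - 1.875) < 0.02))
})

test_that("threshold drive time at half amplitude equals 2d/3", {
  # analytic: A*sin(pi*t/d) crosses A/2 at t = d/6 and 5d/6
  d <- 0.9
  amp <- 800
  fs <- 50
  t <- seq(0, 3, by = 1 / fs)
  f <- ifelse(t >= 1 & t <= 1 + d, amp * sin(pi * (t - 1) / d), -5)
  ft <- force_trace(cbind(f), fs = fs)
  th <- threshold_drive_time(ft, amp / 2, amp / 2)
  expect_length(th$drive_time, 1L)
  expect_lt(abs(th$drive_time[1] - 2 * d / 3), 0.004)
  # threshold above the peak -> missing
  th2 <- threshold_drive_time(ft, 2 * amp, 2 * amp)
  expect_true(all(is.na(th2$per_gate)))
  # two identical gates average to the single-gate value
  ft2 <- force_trace(cbind(f, f), fs = fs)
  th3 <- threshold_drive_time(ft2, amp / 2, amp / 2)
  expect_equal(th3$drive_time, th$drive_time)
})

test_that("per-stroke ordering: rise < peak < fall and peak < drive end", {
  s <- small_session(seed = 23, n_strokes = 12)
  fe <- detect_force_events(s$force)
  expect_true(all(fe$drive_end_s > fe$peak_time_s))
  th <- threshold_drive_time(s$force)
  ok <- !is.na(th$rise_time_s) & !is.na(th$fall_time_s)
  expect_true(any(ok))
  expect_true(all(th$rise_time_s[ok] < th$fall_time_s[ok]))
})

test_that("paired synthetic stroke times agree across systems within 40 ms", {
  s <- small_session(seed = 29, n_strokes = 30)
  ev <- detect_stroke_events(s$accel$trace)
  met <- compute_metrics(ev)
  fe <- detect_force_events(s$force)
  pairs <- pair_strokes(met$drive_end_s, fe$drive_end_s)
  r <- seq_len(length(pairs$a) - 1)
  consec <- pairs$a[r + 1] == pairs$a[r] + 1 & pairs$b[r + 1] == pairs$b[r] + 1
  st_a <- met$stroke_time[pairs$a[r][consec]]
  st_b <- force_stroke_times(fe$drive_end_s)[pairs$b[r][consec]]
  expect_gte(mean(abs(st_a - st_b) < 0.040), 0.95)
})

test_that("pair_strokes matches one-to-one within half a period", {
  a <- c(1.0, 2.9, 4.8, 9.2)
  b <- c(0.95, 2.95, 4.75, 6.7, 8.6)
  pr <- pair_strokes(a, b)
  expect_equal(pr$a, c(1, 2, 3, 4))
  expect_equal(pr$b, c(1, 2, 3, 5))   # a[4]=9.2 pairs with b[5]=8.6
  expect_equal(pr$n_unmatched, 1)     # b[4]=6.7 has no counterpart
  # tightening the tolerance drops the distant pair
  pr2 <- pair_strokes(a, b, tol_s = 0.3)
  expect_equal(pr2$a, c(1, 2, 3))
  expect_equal(pr2$n_unmatched, 3)
})
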