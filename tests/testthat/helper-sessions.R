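# Shared synthetic fixtures, generated in code at test time.

small_session <- function(seed = 7, n_strokes = 20, ...) {
  p <- session_params(n_strokes = n_strokes, seed = seed, ...)
  accel <- generate_accel_session(p)
  force <- generate_force_session(p, accel)
  list(params = p, accel = accel, force = force)
}

# Match each detected event index to the nearest ground-truth index.
match_truth <- function(detected, truth) {
  vapply(detected, function(i) truth[which.min(abs(truth - i))], numeric(1))
}
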