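# Undecimated (stationary / a-trous) wavelet transform.
#
# Every level is a circular convolution of the running approximation with
# the analysis filters upsampled by 2^(level-1) ("a trous": holes between
# taps).  Nothing is ever decimated, so coefficients keep the input's length
# and, after phase compensation, its timing -- the property the stroke
# detector relies on.

# y[n] = sum_k f[k] x[(n - k*step) mod N], sparse in the filter taps.
.circ_conv_up <- function(x, f, step) {
  n <- length(x)
  idx <- 0:(n - 1L)
  y <- numeric(n)
  for (k in seq_along(f)) {
    v <- f[k]
    if (v == 0) next
    y <- y + v * x[((idx - (k - 1L) * step) %% n) + 1L]
  }
  y
}

# Circular left rotation by k samples: result[n] = x[n + k].
.circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(k + 1L):n], x[1:k])
}

# Half-point symmetric (mirror) extension of x to length m >= length(x),
# appended on the right.  Tiles ...x[n-1], x[n], x[n-1], x[n-2]...
.pad_symmetric <- function(x, m) {
  n <- length(x)
  if (m <= n) return(x[seq_len(m)])
  period <- 2L * n
  k <- (n:(m - 1L)) %% period
  refl <- ifelse(k < n, k, period - 1L - k)
  c(x, x[refl + 1L])
}

#' Analytic phase-compensation shifts for the a-trous cascade
#'
#' A causal circular convolution with a linear-phase filter delays the
#' signal by the filter's symmetry centre. At level `L` the lowpass cascade
#' delay is `center_lo * (2^L - 1)` and the bandpass (detail) path delay is
#' `center_lo * (2^(L-1) - 1) + center_hi * 2^(L-1)`. Shifting each
#' coefficient array left by these amounts makes the transform effectively
#' zero-phase, i.e. time-aligned with the input.
#'
#' @param levels Number of decomposition levels.
#' @param wavelet Wavelet family identifier (see [wavelet_filters()]).
#' @return A data frame with columns `level`, `approx_shift`, `detail_shift`
#'   (samples of left rotation).
#' @export
uwt_alignment_shifts <- function(levels, wavelet = "bior4.4") {
  f <- wavelet_filters(wavelet)
  L <- seq_len(levels)
  data.frame(
    level = L,
    approx_shift = f$center_lo * (2^L - 1),
    detail_shift = f$center_lo * (2^(L - 1) - 1) + f$center_hi * 2^(L - 1)
  )
}

#' Apply phase-compensation shifts to raw a-trous coefficients
#'
#' @param approx,detail Lists of raw (causal-convolution) per-level
#'   coefficient vectors, level 1 first.
#' @param wavelet Wavelet family identifier.
#' @return A list with shifted `approx` and `detail` lists and the `shifts`
#'   data frame that was applied.
#' @export
align_coefficients <- function(approx, detail, wavelet = "bior4.4") {
  shifts <- uwt_alignment_shifts(length(approx), wavelet)
  list(
    approx = Map(.circ_shift, approx, shifts$approx_shift),
    detail = Map(.circ_shift, detail, shifts$detail_shift),
    shifts = shifts
  )
}

#' Undecimated wavelet decomposition
#'
#' Decomposes a uniformly sampled signal with the a-trous stationary wavelet
#' transform. All coefficient arrays have the input's length (no
#' decimation), are phase-compensated so features stay time-aligned with the
#' input, and approximations are DC-normalised (divided by `2^(L/2)`) so a
#' constant signal maps to itself at every level.
#'
#' @param x Numeric vector, finite, length >= 2.
#' @param levels Number of decomposition levels (default 9).
#' @param wavelet Wavelet family identifier (default `"bior4.4"`).
#' @param padding `"symmetric"` (default) mirror-extends the signal to the
#'   next multiple of `2^levels` before the circular transform, confining
#'   wrap-around to the reflected tail; `"periodic"` transforms the signal
#'   as-is, giving exact circular shift-equivariance.
#' @return An object of class `uwt_decomposition` with accessors
#'   [approximation()] and [detail()], and fields `n`, `levels`, `wavelet`,
#'   `padding`, `alignment_shifts`.
#' @seealso [uwt_reconstruct()] for the inverse transform.
#' @examples
#' x <- sin(2 * pi * seq(0, 5, by = 1 / 200))
#' d <- uwt_decompose(x, levels = 9)
#' length(approximation(d, 3)) == length(x)
#' @export
uwt_decompose <- function(x, levels = 9L, wavelet = "bior4.4",
                          padding = c("symmetric", "periodic")) {
  padding <- match.arg(padding)
  if (!is.numeric(x) || length(x) < 2L) {
    stop("x must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("x contains non-finite values", call. = FALSE)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1", call. = FALSE)
  n <- length(x)

  xp <- if (padding == "symmetric") {
    block <- 2^levels
    .pad_symmetric(x, as.integer(ceiling(n / block) * block))
  } else {
    x
  }

  f <- wavelet_filters(wavelet)
  approx <- vector("list", levels)
  detail <- vector("list", levels)
  ca <- xp
  for (j in seq_len(levels)) {
    step <- 2L^(j - 1L)
    detail[[j]] <- .circ_conv_up(ca, f$dec_hi, step)
    ca <- .circ_conv_up(ca, f$dec_lo, step)
    approx[[j]] <- ca
  }

  al <- align_coefficients(approx, detail, wavelet)
  gains <- 2^(seq_len(levels) / 2)
  approx <- Map(`/`, al$approx, gains)

  structure(
    list(
      n = n, levels = levels, wavelet = wavelet, padding = padding,
      n_padded = length(xp),
      approx = approx, detail = al$detail,
      alignment_shifts = al$shifts, approx_gains = gains
    ),
    class = "uwt_decomposition"
  )
}

#' Extract a phase-compensated approximation coefficient
#'
#' Returns the full-length, time-aligned, DC-normalised level-`level`
#' approximation (the lowpass band), trimmed to the original signal length.
#'
#' @param d A `uwt_decomposition`.
#' @param level Level in `1:d$levels`. Level 3 carries the stroke-scale
#'   band used for drive-start/cycle-start detection at 200 Hz; level 2 the
#'   slightly wider band used for drive-end detection.
#' @return Numeric vector of length `d$n`.
#' @export
approximation <- function(d, level) {
  stopifnot(inherits(d, "uwt_decomposition"))
  level <- as.integer(level)
  if (level < 1L || level > d$levels) {
    stop("level must be in 1..", d$levels, call. = FALSE)
  }
  d$approx[[level]][seq_len(d$n)]
}

#' Extract a phase-compensated detail coefficient
#'
#' @inheritParams approximation
#' @return Numeric vector of length `d$n` (bandpass band, not
#'   DC-normalised: its DC gain is zero by construction).
#' @export
detail <- function(d, level) {
  stopifnot(inherits(d, "uwt_decomposition"))
  level <- as.integer(level)
  if (level < 1L || level > d$levels) {
    stop("level must be in 1..", d$levels, call. = FALSE)
  }
  d$detail[[level]][seq_len(d$n)]
}

#' Inverse undecimated wavelet transform
#'
#' Reconstructs the input from the deepest approximation plus all detail
#' bands by the redundant synthesis identity
#' `x = shift((cA * rec_lo_up + cD * rec_hi_up) / 2)` applied level by
#' level. In periodic mode reconstruction is exact to machine precision at
#' every sample; in symmetric mode samples within a cascade filter length of
#' the splice between signal and reflected tail inherit the padding, so only
#' interior samples are guaranteed.
#'
#' @param d A `uwt_decomposition`.
#' @return Numeric vector of length `d$n`.
#' @export
uwt_reconstruct <- function(d) {
  stopifnot(inherits(d, "uwt_decomposition"))
  f <- wavelet_filters(d$wavelet)
  sh <- d$alignment_shifts
  ca <- .circ_shift(d$approx[[d$levels]] * d$approx_gains[d$levels],
                    -sh$approx_shift[d$levels])
  for (j in d$levels:1L) {
    step <- 2L^(j - 1L)
    cd <- .circ_shift(d$detail[[j]], -sh$detail_shift[j])
    ca <- .circ_shift(
      (.circ_conv_up(ca, f$rec_lo, step) + .circ_conv_up(cd, f$rec_hi, step)) / 2,
      f$pr_delay * step
    )
  }
  ca[seq_len(d$n)]
}

#' @export
print.uwt_decomposition <- function(x, ...) {
  cat(sprintf(
    "Undecimated wavelet decomposition: %d levels of '%s', n = %d (%s padding to %d)\n",
    x$levels, x$wavelet, x$n, x$padding, x$n_padded
  ))
  invisible(x)
}
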