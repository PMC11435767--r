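# Local-maximum search with prominence and minimum-separation filtering.
# Deliberately dependency-free: the detector must be deterministic and its
# tie-breaking (earliest sample of a plateau) explicit.

#' Peak-detection configuration
#'
#' @param min_separation_s Minimum spacing between accepted peaks, seconds.
#'   Defaults to one full cycle at `max_stroke_rate_spm`, i.e.
#'   `60 / max_stroke_rate_spm`.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   signal's robust amplitude (5th-95th percentile span). Scale-free, so
#'   detection is invariant to positive rescaling of the input.
#' @param max_stroke_rate_spm Fastest stroke rate the separation default
#'   should admit (strokes per minute).
#' @param refine_halfwidth_s Half-width (seconds) of the least-squares
#'   parabola fit used to localise broad extrema (the drive-end valley) to
#'   their vertex; `0` disables refinement.
#' @return An object of class `peak_config`.
#' @export
peak_config <- function(min_separation_s = NULL, min_prominence_frac = 0.25,
                        max_stroke_rate_spm = 60,
                        refine_halfwidth_s = 0.125) {
  if (is.null(min_separation_s)) min_separation_s <- 60 / max_stroke_rate_spm
  stopifnot(
    min_separation_s > 0,
    min_prominence_frac > 0, min_prominence_frac < 1,
    refine_halfwidth_s >= 0
  )
  structure(
    list(
      min_separation_s = min_separation_s,
      min_prominence_frac = min_prominence_frac,
      max_stroke_rate_spm = max_stroke_rate_spm,
      refine_halfwidth_s = refine_halfwidth_s
    ),
    class = "peak_config"
  )
}

# Vertex of a least-squares parabola fit to x over [i0 - r, i0 + r]
# (clipped to [lo, hi]), rounded to the nearest sample. Falls back to i0
# when the fit is not convex (sign per `minimum`) or the vertex leaves the
# fit window. Reduces the noise-induced jitter of broad extrema.
.refine_extremum <- function(x, i0, r, lo = 1L, hi = length(x),
                             minimum = TRUE) {
  if (r <= 0) return(i0)
  a <- max(lo, i0 - r)
  b <- min(hi, i0 + r)
  if (b - a < 4L) return(i0)
  k <- a:b
  kc <- k - i0
  fit <- stats::lm.fit(cbind(1, kc, kc^2), x[k])
  c2 <- fit$coefficients[3]
  if (!is.finite(c2) || (minimum && c2 <= 0) || (!minimum && c2 >= 0)) {
    return(i0)
  }
  v <- i0 - fit$coefficients[2] / (2 * c2)
  if (v < a || v > b) return(i0)
  as.integer(floor(v + 0.5))
}

# All local maxima of x; plateaus report their earliest sample.
.local_maxima <- function(x) {
  dx <- diff(x)
  nz <- which(dx != 0)
  if (length(nz) < 2L) return(integer(0))
  s <- sign(dx[nz])
  turn <- which(s[-length(s)] == 1 & s[-1] == -1)
  nz[turn] + 1L
}

# Topographic prominence of peak p: height above the higher of the two
# saddle minima reached before a strictly taller sample (or the boundary).
.prominence <- function(x, p) {
  h <- x[p]
  left <- which(x[seq_len(p - 1L)] > h)
  lmin <- min(x[(if (length(left)) max(left) + 1L else 1L):p])
  n <- length(x)
  right <- if (p < n) which(x[(p + 1L):n] > h) + p else integer(0)
  rmin <- min(x[p:(if (length(right)) min(right) - 1L else n)])
  h - max(lmin, rmin)
}

#' Find peaks with prominence and separation constraints
#'
#' @param x Numeric vector.
#' @param min_separation Minimum index spacing between accepted peaks
#'   (samples); when two candidates are closer, the taller survives.
#' @param min_prominence Absolute prominence threshold; candidates below it
#'   are dropped. `0` keeps all local maxima.
#' @return Sorted integer vector of peak indices (1-based). Constant or
#'   monotone input yields `integer(0)`.
#' @export
find_peaks <- function(x, min_separation = 0, min_prominence = 0) {
  cand <- .local_maxima(x)
  if (!length(cand)) return(integer(0))
  if (min_prominence > 0) {
    prom <- vapply(cand, function(p) .prominence(x, p), numeric(1))
    cand <- cand[prom >= min_prominence]
    if (!length(cand)) return(integer(0))
  }
  if (min_separation > 0 && length(cand) > 1L) {
    ord <- cand[order(-x[cand], cand)]   # tallest first, earliest on ties
    keep <- integer(0)
    for (p in ord) {
      if (!length(keep) || all(abs(keep - p) >= min_separation)) {
        keep <- c(keep, p)
      }
    }
    cand <- sort(keep)
  }
  as.integer(cand)
}

# Prominence threshold implied by a peak_config for a given signal.
.relative_prominence <- function(x, cfg) {
  span <- diff(as.numeric(stats::quantile(x, c(0.05, 0.95), names = FALSE)))
  cfg$min_prominence_frac * span
}
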