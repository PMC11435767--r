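# Biorthogonal 4/4 analysis/synthesis filter bank (spline wavelet family).
# Taps are the standard published values; the decomposition lowpass sums to
# sqrt(2) so an L-level lowpass cascade has DC gain 2^(L/2).

.BIOR44 <- list(
  dec_lo = c(
    0,
    0.03782845550726404,
    -0.023849465019556843,
    -0.11062440441843718,
    0.37740285561283066,
    0.85269867900889385,
    0.37740285561283066,
    -0.11062440441843718,
    -0.023849465019556843,
    0.03782845550726404
  ),
  dec_hi = c(
    0,
    -0.064538882628697058,
    0.040689417609164058,
    0.41809227322161724,
    -0.7884856164055829,
    0.41809227322161724,
    0.040689417609164058,
    -0.064538882628697058,
    0,
    0
  ),
  rec_lo = c(
    0,
    -0.064538882628697058,
    -0.040689417609164058,
    0.41809227322161724,
    0.7884856164055829,
    0.41809227322161724,
    -0.040689417609164058,
    -0.064538882628697058,
    0,
    0
  ),
  rec_hi = c(
    0,
    -0.03782845550726404,
    -0.023849465019556843,
    0.11062440441843718,
    0.37740285561283066,
    -0.85269867900889385,
    0.37740285561283066,
    0.11062440441843718,
    -0.023849465019556843,
    -0.03782845550726404
  )
)

# Symmetry centre (0-based tap index) of a linear-phase FIR filter, or NA if
# the filter is not symmetric/antisymmetric about an integer tap.
.filter_center <- function(f, tol = 1e-12) {
  n <- length(f)
  supp <- which(abs(f) > tol) - 1L          # 0-based taps with mass
  for (c0 in 0:(n - 1)) {
    mirror <- 2L * c0 - supp
    if (any(mirror < 0L | mirror > (n - 1L))) next
    fm <- f[mirror + 1L]
    fs <- f[supp + 1L]
    if (max(abs(fs - fm)) < tol || max(abs(fs + fm)) < tol) return(c0)
  }
  NA_integer_
}

#' Retrieve a wavelet filter bank by name
#'
#' Returns the analysis (`dec_lo`, `dec_hi`) and synthesis (`rec_lo`,
#' `rec_hi`) filters together with derived alignment metadata: the
#' linear-phase symmetry centre of each analysis filter (the per-level group
#' delay of a causal circular convolution) and the delay of the combined
#' analysis/synthesis perfect-reconstruction identity
#' `conv(dec_lo, rec_lo) + conv(dec_hi, rec_hi) = 2 * delta`.
#'
#' @param name Wavelet family identifier. Only `"bior4.4"` is provided: the
#'   biorthogonal 4/4 spline wavelet whose linear-phase (symmetric) filters
#'   make exact integer phase compensation possible.
#' @return A list with elements `name`, `dec_lo`, `dec_hi`, `rec_lo`,
#'   `rec_hi`, `center_lo`, `center_hi` (0-based tap indices) and `pr_delay`
#'   (0-based index of the `2*delta` term above).
#' @examples
#' f <- wavelet_filters("bior4.4")
#' sum(f$dec_lo) # sqrt(2)
#' @export
wavelet_filters <- function(name = "bior4.4") {
  if (!identical(name, "bior4.4")) {
    stop("unsupported wavelet '", name, "'; available: bior4.4", call. = FALSE)
  }
  f <- .BIOR44
  pr <- convolve(f$dec_lo, rev(f$rec_lo), type = "open") +
    convolve(f$dec_hi, rev(f$rec_hi), type = "open")
  d <- which.max(abs(pr)) - 1L
  stopifnot(abs(pr[d + 1L] - 2) < 1e-9, max(abs(pr[-(d + 1L)])) < 1e-9)
  list(
    name = name,
    dec_lo = f$dec_lo, dec_hi = f$dec_hi,
    rec_lo = f$rec_lo, rec_hi = f$rec_hi,
    center_lo = .filter_center(f$dec_lo),
    center_hi = .filter_center(f$dec_hi),
    pr_delay = d
  )
}
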