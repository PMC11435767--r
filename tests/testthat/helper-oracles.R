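# Independent brute-force oracles. Deliberately naive (scalar loops,
# explicit sums, normal equations) so they share no code path with the
# package implementations they check.

# Plain O(n * taps) circular convolution with an upsampled filter,
# scalar accumulation.
oracle_circ_conv <- function(x, f, step) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(f)) {
      j <- ((i - 1L - (k - 1L) * step) %% n) + 1L
      acc <- acc + f[k] * x[j]
    }
    y[i] <- acc
  }
  y
}

# Raw (unaligned, unnormalised) a-trous cascade up to `levels`.
oracle_atrous <- function(x, levels, f) {
  approx <- detail <- vector("list", levels)
  ca <- x
  for (j in seq_len(levels)) {
    step <- 2L^(j - 1L)
    detail[[j]] <- oracle_circ_conv(ca, f$dec_hi, step)
    ca <- oracle_circ_conv(ca, f$dec_lo, step)
    approx[[j]] <- ca
  }
  list(approx = approx, detail = detail)
}

# One-way and two-way ANOVA mean squares by explicit summation over the
# n x 2 rating matrix, plus the resulting average-measure ICCs.
oracle_icc <- function(a, b) {
  n <- length(a)
  k <- 2
  x <- cbind(a, b)
  grand <- sum(x) / (n * k)
  ssr <- ssc <- sse <- ssw <- 0
  rowm <- numeric(n)
  for (i in seq_len(n)) rowm[i] <- (x[i, 1] + x[i, 2]) / k
  colm <- c(sum(x[, 1]) / n, sum(x[, 2]) / n)
  for (i in seq_len(n)) {
    ssr <- ssr + k * (rowm[i] - grand)^2
    for (j in 1:k) {
      sse <- sse + (x[i, j] - rowm[i] - colm[j] + grand)^2
      ssw <- ssw + (x[i, j] - rowm[i])^2
    }
  }
  for (j in 1:k) ssc <- ssc + n * (colm[j] - grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  msw <- ssw / (n * (k - 1))
  list(
    msr = unname(msr), msc = unname(msc), mse = unname(mse),
    msw = unname(msw),
    icc1k = unname((msr - msw) / msr),
    icc2k = unname((msr - mse) / (msr + (msc - mse) / n))
  )
}

# OLS of y on x via the closed-form normal equations, with the slope
# t-test p-value from first principles.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum((y - sy / n)^2)
  se_slope <- sqrt(sse / (n - 2) / (sxx - sx^2 / n))
  tstat <- slope / se_slope
  list(slope = slope, intercept = intercept,
       r_squared = 1 - sse / sst,
       p = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
}

# Mean / sd of differences by direct arithmetic.
oracle_bland_altman <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(bias = m, sd = s, loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s)
}
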