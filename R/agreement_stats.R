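# Agreement battery for paired two-system measurements: intraclass
# correlation (one-way and two-way random, average of k = 2 raters, with F
# test and exact F-distribution confidence bounds per McGraw & Wong),
# Bland-Altman bias and limits of agreement, and OLS regression.

#' Paired measurements from two systems
#'
#' @param a,b Equal-length finite numeric vectors: method A (accelerometer
#'   convention) and method B (force reference). All difference-based
#'   statistics use the direction `a - b`.
#' @param label Metric name, e.g. `"drive_time"`.
#' @param group Cohort/boat-class label.
#' @return An object of class `paired_measures`.
#' @export
paired_measures <- function(a, b, label = "metric", group = "all") {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("a and b must have equal length >= 3", call. = FALSE)
  }
  if (!all(is.finite(a), is.finite(b))) {
    stop("paired measures must be finite", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 label = label, group = group),
            class = "paired_measures")
}

# Two-way ANOVA mean squares of the n x 2 rating matrix.
.mean_squares <- function(a, b) {
  x <- cbind(a, b)
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  rm_ <- rowMeans(x)
  cm_ <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  msw <- sum((x - rm_)^2) / (n * (k - 1))
  list(n = n, k = k, msr = msr, msc = msc, mse = mse, msw = msw)
}

#' Intraclass correlation for average measures over two systems
#'
#' Computes ICC(1,k) (one-way random effects) or ICC(2,k) (two-way random
#' effects, absolute agreement) for k = 2 raters from the ANOVA mean
#' squares, with the F statistic, degrees of freedom, p-value and 95%
#' confidence interval from F-distribution bounds (Satterthwaite degrees of
#' freedom for the two-way model).
#'
#' @param p A [paired_measures()].
#' @param model `"two_way_random"` (ICC(2,k), default) or `"one_way"`
#'   (ICC(1,k)).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `value`, `model`, `k`, `n`, `F`, `df1`, `df2`, `p`,
#'   `ci` (length-2), `interpretation` and `defined` (FALSE when
#'   between-subject variance is zero and the ICC is undefined).
#' @export
icc_average_raters <- function(p, model = c("two_way_random", "one_way"),
                               conf_level = 0.95) {
  stopifnot(inherits(p, "paired_measures"))
  model <- match.arg(model)
  ms <- .mean_squares(p$a, p$b)
  n <- ms$n
  k <- ms$k
  alpha <- 1 - conf_level
  tol <- .Machine$double.eps^0.75 * max(1, ms$msr)

  if (ms$msr <= tol && (if (model == "one_way") ms$msw else ms$mse) <= tol) {
    return(list(value = NA_real_, model = model, k = k, n = n,
                F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                ci = c(NA_real_, NA_real_),
                interpretation = NA_character_, defined = FALSE))
  }

  if (model == "one_way") {
    icc <- (ms$msr - ms$msw) / ms$msr
    fobs <- ms$msr / ms$msw
    df1 <- n - 1
    df2 <- n * (k - 1)
    if (is.finite(fobs)) {
      fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
      fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
      ci <- c(1 - 1 / fl, 1 - 1 / fu)
    } else {
      ci <- c(1, 1)
    }
    pval <- stats::pf(fobs, df1, df2, lower.tail = FALSE)
  } else {
    denom <- ms$msr + (ms$msc - ms$mse) / n
    icc <- (ms$msr - ms$mse) / denom
    fobs <- ms$msr / ms$mse
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    if (ms$mse <= tol && ms$msc <= tol) {
      ci <- c(1, 1)
      fobs <- Inf
      pval <- 0
    } else {
      icc1 <- (ms$msr - ms$mse) /
        (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
      aa <- k * icc1 / (n * (1 - icc1))
      bb <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
      v <- (aa * ms$msc + bb * ms$mse)^2 /
        ((aa * ms$msc)^2 / (k - 1) + (bb * ms$mse)^2 / ((n - 1) * (k - 1)))
      f1 <- stats::qf(1 - alpha / 2, n - 1, v)
      f2 <- stats::qf(1 - alpha / 2, v, n - 1)
      l1 <- n * (ms$msr - f1 * ms$mse) /
        (f1 * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
      u1 <- n * (f2 * ms$msr - ms$mse) /
        (k * ms$msc + (k * n - k - n) * ms$mse + n * f2 * ms$msr)
      sb <- function(r) k * r / (1 + (k - 1) * r)   # Spearman-Brown
      ci <- c(sb(l1), sb(u1))
      pval <- stats::pf(fobs, df1, df2, lower.tail = FALSE)
    }
  }

  list(value = icc, model = model, k = k, n = n,
       F = fobs, df1 = df1, df2 = df2, p = pval, ci = ci,
       interpretation = interpret_icc(icc), defined = TRUE)
}

#' Qualitative band of an intraclass correlation
#'
#' Bands: below 0.50 poor, 0.50 to below 0.75 moderate, 0.75 through 0.90
#' good, above 0.90 excellent (0.90 exactly is "good" under the literal
#' reading of the cut-offs).
#'
#' @param value ICC in `[-1, 1]`.
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
interpret_icc <- function(value) {
  stopifnot(is.numeric(value), value >= -1, value <= 1)
  vapply(value, function(v) {
    if (v < 0.50) "poor"
    else if (v < 0.75) "moderate"
    else if (v <= 0.90) "good"
    else "excellent"
  }, character(1))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as `a - b` (accelerometer minus force reference).
#'
#' @param p A [paired_measures()].
#' @return List with `bias` (mean difference), `sd` (sample SD of the
#'   differences), `loa_lower`, `loa_upper` (`bias -/+ 1.96 * sd`), `n`,
#'   and `mean`/`diff` vectors for plotting.
#' @export
bland_altman <- function(p) {
  stopifnot(inherits(p, "paired_measures"))
  d <- p$a - p$b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       n = length(d), mean = (p$a + p$b) / 2, diff = d)
}

#' Agreement regression between two systems
#'
#' Ordinary least squares of method A (accelerometer) on method B (force
#' reference): `a = intercept + slope * b`. Perfect agreement corresponds
#' to slope 1, intercept 0, r-squared 1.
#'
#' @param p A [paired_measures()]; `var(b)` must be positive.
#' @return List with `slope`, `intercept`, `r_squared` and `p` (slope
#'   t-test).
#' @export
regression_agreement <- function(p) {
  stopifnot(inherits(p, "paired_measures"))
  if (stats::var(p$b) <= 0) {
    stop("predictor (method B) has zero variance", call. = FALSE)
  }
  fit <- stats::lm(a ~ b, data = list(a = p$a, b = p$b))
  # exact agreement triggers lm's "essentially perfect fit" warning; the
  # slope/intercept/r-squared are still what callers need
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  pval <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p = pval)
}

#' Assemble the full agreement report
#'
#' One block per metric/group pairing, each holding the ICC (both the
#' two-way random default and the one-way variant), Bland-Altman and
#' regression summaries. The result is JSON-serialisable via
#' [write_report_json()].
#'
#' @param pairs A [paired_measures()] or a list of them.
#' @param icc_model Default ICC variant reported in the `icc` slot.
#' @return An object of class `agreement_report`: named list of blocks
#'   (names `"<group>.<label>"`), each with `label`, `group`, `n`, `icc`,
#'   `icc_one_way`, `bland_altman`, `regression`.
#' @export
build_report <- function(pairs, icc_model = c("two_way_random", "one_way")) {
  icc_model <- match.arg(icc_model)
  if (inherits(pairs, "paired_measures")) pairs <- list(pairs)
  blocks <- lapply(pairs, function(p) {
    stopifnot(inherits(p, "paired_measures"))
    ba <- bland_altman(p)
    list(
      label = p$label, group = p$group, n = length(p$a),
      icc = icc_average_raters(p, model = icc_model),
      icc_one_way = icc_average_raters(p, model = "one_way"),
      bland_altman = ba[c("bias", "sd", "loa_lower", "loa_upper", "n")],
      regression = regression_agreement(p)
    )
  })
  names(blocks) <- vapply(pairs, function(p) paste(p$group, p$label, sep = "."),
                          character(1))
  structure(blocks, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  for (nm in names(x)) {
    b <- x[[nm]]
    cat(sprintf(
      "%-28s n=%4d  ICC=%.3f (%s)  bias=%+.4f s  LoA=[%+.4f, %+.4f]  r2=%.3f\n",
      nm, b$n, b$icc$value, b$icc$interpretation, b$bland_altman$bias,
      b$bland_altman$loa_lower, b$bland_altman$loa_upper,
      b$regression$r_squared
    ))
  }
  invisible(x)
}
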