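#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression for comparing two measurement methods. The slope
#' is the shifted median of all pairwise slopes `(y_j - y_i)/(x_j - x_i)`:
#' slopes exactly equal to -1 are excluded and the median index is offset by
#' `K`, the number of slopes below -1, which makes the estimate invariant to
#' swapping the methods. The intercept is `median(y - slope * x)`. Confidence
#' bounds come from the asymptotic rank formula; deviation from linearity is
#' assessed with a cusum test over the signs of the residuals.
#'
#' @param x Measurements from the first method (e.g. measured performance).
#' @param y Measurements from the second method (e.g. model-estimated
#'   performance), same length as `x`.
#' @param conf.level Confidence level for the slope/intercept bounds
#'   (default 0.95).
#' @return A `passing_bablok` object with elements `slope`, `intercept`,
#'   `ci_slope`, `ci_intercept`, `linearity` (cusum statistic and p-value),
#'   `n` and `n_slopes`. Supports [generics::tidy()], [generics::glance()]
#'   and [ggplot2::autoplot()].
#' @examples
#' x <- c(51, 60, 75, 89, 104, 120)
#' passing_bablok(x, 2 * x + 3)
#' @export
passing_bablok <- function(x, y, conf.level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)

  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  defined <- !(dx == 0 & dy == 0)
  slopes <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)[defined]
  slopes <- slopes[slopes != -1] # exclude exact -1 per the original method
  if (length(slopes) == 0 || all(is.infinite(slopes))) {
    stop("degenerate input: pairwise slopes undefined (vertical data)", call. = FALSE)
  }
  S <- sort(slopes)
  N <- length(S)
  K <- sum(S < -1)

  idx <- function(i) S[max(1L, min(N, i))]
  half <- (N + 1) / 2
  slope <- if (N %% 2 == 1) {
    idx(half + K)
  } else {
    (idx(N / 2 + K) + idx(N / 2 + 1 + K)) / 2
  }

  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  C_gamma <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C_gamma) / 2)
  M2 <- N - M1 + 1
  slope_lo <- idx(M1 + K)
  slope_hi <- idx(M2 + K)

  intercept <- stats::median(y - slope * x)
  intercept_lo <- stats::median(y - slope_hi * x)
  intercept_hi <- stats::median(y - slope_lo * x)

  structure(
    list(
      slope = slope, intercept = intercept,
      ci_slope = c(slope_lo, slope_hi),
      ci_intercept = c(intercept_lo, intercept_hi),
      conf.level = conf.level,
      linearity = pb_cusum_test(x, y, slope, intercept),
      n = n, n_slopes = N,
      data = tibble::tibble(x = x, y = y)
    ),
    class = "passing_bablok"
  )
}

# Cusum linearity test: residual signs, weighted so the cusum is a random
# walk with zero drift under H0, accumulated along the fitted line and
# compared against the Kolmogorov-Smirnov distribution.
pb_cusum_test <- function(x, y, slope, intercept) {
  resid <- y - (intercept + slope * x)
  l <- sum(resid > 0)
  L <- sum(resid < 0)
  if (l == 0 || L == 0) {
    return(list(statistic = 0, p.value = 1))
  }
  score <- numeric(length(x))
  score[resid > 0] <- sqrt(L / l)
  score[resid < 0] <- -sqrt(l / L)
  proj <- if (is.finite(slope) && slope != 0) x + y / slope else x
  cs <- cumsum(score[order(proj, x)])
  H <- max(abs(cs)) / sqrt(l + L)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * H^2))
  list(statistic = H, p.value = min(max(p, 0), 1))
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat(sprintf(
    "Passing-Bablok regression (n = %d)\n  slope     %.4f  [%.4f, %.4f]\n  intercept %.4f  [%.4f, %.4f]\n  linearity cusum p = %.3f\n",
    x$n, x$slope, x$ci_slope[1], x$ci_slope[2],
    x$intercept, x$ci_intercept[1], x$ci_intercept[2],
    x$linearity$p.value
  ))
  invisible(x)
}

#' @method tidy passing_bablok
#' @export
tidy.passing_bablok <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(x$ci_intercept[1], x$ci_slope[1]),
    conf.high = c(x$ci_intercept[2], x$ci_slope[2])
  )
}

#' @method glance passing_bablok
#' @export
glance.passing_bablok <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    linearity.statistic = x$linearity$statistic,
    linearity.p.value = x$linearity$p.value,
    conf.level = x$conf.level
  )
}

#' Intraclass correlation for absolute agreement of two methods
#'
#' Single-measure, two-way random-effects, absolute-agreement ICC — ICC(A,1)
#' in the McGraw & Wong taxonomy, the standard form for method comparison —
#' computed from the two-way ANOVA mean squares, with the F-distribution
#' confidence interval.
#'
#' @param x,y Paired measurements of the same subjects by the two methods.
#' @param conf.level Confidence level (default 0.95).
#' @return One-row tibble: `icc`, `conf.low`, `conf.high`, `n` (subjects),
#'   `k` (raters = 2), and the mean squares `ms_rows`, `ms_cols`,
#'   `ms_error`.
#' @examples
#' x <- c(100, 150, 210, 260, 300, 330)
#' icc_agreement(x, x + c(-8, 5, 3, -4, 9, -2))
#' @export
icc_agreement <- function(x, y, conf.level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  m <- cbind(x[ok], y[ok])
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0) stop("zero between-subject variance: ICC undefined", call. = FALSE)

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  if (mse == 0 && msc == 0) {
    lo <- hi <- 1 # perfect agreement: degenerate interval
  } else {
    alpha <- 1 - conf.level
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) * (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_u * mse) / (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_l * msr - mse) / (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  }
  tibble::tibble(
    icc = icc, conf.low = lo, conf.high = hi,
    n = n, k = k, ms_rows = msr, ms_cols = msc, ms_error = mse
  )
}

#' Paired-samples t-test with degenerate-input guards
#'
#' Thin wrapper around [stats::t.test()] for pre/post comparisons: identical
#' vectors return `t = 0, p = 1` by convention, and a constant nonzero
#' difference (zero spread, infinite t) raises an error rather than returning
#' a misleading statistic.
#'
#' @param pre,post Paired numeric vectors (length >= 2).
#' @return One-row tibble: `estimate` (mean of `post - pre`), `statistic`,
#'   `p.value`, `conf.low`, `conf.high`, `n`.
#' @export
paired_t_test <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  if (length(pre) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(
        estimate = 0, statistic = 0, p.value = 1,
        conf.low = 0, conf.high = 0, n = length(d)
      ))
    }
    stop("constant nonzero difference: t statistic degenerate", call. = FALSE)
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  tibble::tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    p.value = tt$p.value,
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2],
    n = length(d)
  )
}

#' Agreement between measured and model-estimated performance
#'
#' Pools measured/estimated pairs (typically subject x visit) and computes the
#' full method-comparison panel: Passing-Bablok slope and intercept with
#' confidence bounds and linearity test, ICC(A,1) with confidence interval,
#' and a paired t-test for systematic difference.
#'
#' @param data Data frame of paired values.
#' @param measured,estimated Columns of `data` holding the measured and
#'   model-estimated values (tidy evaluation).
#' @param conf.level Confidence level (default 0.95).
#' @return One-row tibble: `pb_slope`, `pb_slope_low`, `pb_slope_high`,
#'   `pb_intercept`, `pb_intercept_low`, `pb_intercept_high`,
#'   `linearity_pvalue`, `icc`, `icc_low`, `icc_high`, `t_statistic`,
#'   `t_pvalue`, `n`.
#' @export
agreement_stats <- function(data, measured, estimated, conf.level = 0.95) {
  x <- dplyr::pull(data, {{ measured }})
  y <- dplyr::pull(data, {{ estimated }})
  pb <- passing_bablok(x, y, conf.level = conf.level)
  ic <- icc_agreement(x, y, conf.level = conf.level)
  tt <- paired_t_test(x, y)
  tibble::tibble(
    pb_slope = pb$slope,
    pb_slope_low = pb$ci_slope[1], pb_slope_high = pb$ci_slope[2],
    pb_intercept = pb$intercept,
    pb_intercept_low = pb$ci_intercept[1], pb_intercept_high = pb$ci_intercept[2],
    linearity_pvalue = pb$linearity$p.value,
    icc = ic$icc, icc_low = ic$conf.low, icc_high = ic$conf.high,
    t_statistic = tt$statistic, t_pvalue = tt$p.value,
    n = length(x)
  )
}
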