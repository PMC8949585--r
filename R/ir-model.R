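#' Banister impulse-response parameters
#'
#' Bundles the five parameters of the two-component fitness-fatigue model:
#' baseline performance `p0` (m), the fitness and fatigue magnitude factors
#' `k1`, `k2` (a.u., performance gained/lost per unit TRIMP) and the decay
#' time constants `tau1`, `tau2` (days; the time for each component to fall to
#' 37\% — e^-1 — of its value).
#'
#' @param p0 Baseline performance, metres (>= 0).
#' @param k1,k2 Nonnegative magnitude factors for fitness and fatigue.
#' @param tau1,tau2 Positive decay time constants, days.
#' @return A `banister_params` object (named list).
#' @examples
#' banister_params(p0 = 114, k1 = 0.03, k2 = 0.03, tau1 = 45, tau2 = 25)
#' @export
banister_params <- function(p0, k1, k2, tau1, tau2) {
  stopifnot(
    is.numeric(p0), p0 >= 0,
    is.numeric(k1), k1 >= 0, is.numeric(k2), k2 >= 0,
    is.numeric(tau1), tau1 > 0, is.numeric(tau2), tau2 > 0
  )
  structure(
    list(p0 = p0, k1 = k1, k2 = k2, tau1 = tau1, tau2 = tau2),
    class = "banister_params"
  )
}

#' @export
print.banister_params <- function(x, ...) {
  cat(sprintf(
    "Banister IR parameters: p0 = %.1f m, k1 = %.4f, k2 = %.4f, tau1 = %.1f d, tau2 = %.1f d\n",
    x$p0, x$k1, x$k2, x$tau1, x$tau2
  ))
  invisible(x)
}

as_banister_params <- function(x) {
  if (inherits(x, "banister_params")) return(x)
  x <- as.list(x)
  banister_params(x$p0, x$k1, x$k2, x$tau1, x$tau2)
}

#' First-order exponential impulse response
#'
#' The response `t` days after a unit stimulus is `k * exp(-t / tau)`: at
#' `t = tau` it has decayed to `k * exp(-1)`, i.e. 37\% of its initial value.
#'
#' @param k Magnitude factor (a.u.).
#' @param tau Decay time constant, days (> 0).
#' @param t Days since the stimulus (>= 0), vectorised.
#' @return Response in the units of `k`.
#' @examples
#' impulse_response(1, tau = 45, t = 45) # exp(-1) ~ 0.37
#' @export
impulse_response <- function(k, tau, t) {
  if (any(tau <= 0)) stop("`tau` must be positive", call. = FALSE)
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  k * exp(-t / tau)
}

# Convolution of the daily TRIMP signal with exp(-t/tau), evaluated at all
# integer days 0..horizon. A day's training first affects the following day
# (sum over i < t), so the recursion is f(t) = e^{-1/tau} (f(t-1) + w(t-1)).
convolve_trimp <- function(w, tau, horizon) {
  decay <- exp(-1 / tau)
  out <- numeric(horizon + 1)
  acc <- 0
  n <- length(w)
  for (t in seq_len(horizon)) {
    w_prev <- if (t <= n) w[t] else 0 # w[t] holds day t-1 (0-based day index)
    acc <- decay * (acc + w_prev)
    out[t + 1] <- acc
  }
  out
}

#' Predict performance from a daily TRIMP series
#'
#' Discrete Banister convolution: predicted performance on day `t` is
#' `p(t) = p0 + k1 * sum_{i<t} w(i) exp(-(t-i)/tau1)
#'            - k2 * sum_{i<t} w(i) exp(-(t-i)/tau2)`,
#' the baseline plus the fitness component minus the fatigue component. The
#' sum runs over training days strictly before `t`: a session does not affect
#' performance measured the same day. Days past the end of the series take
#' `w = 0`, so extending `horizon` beyond the programme simulates detraining.
#'
#' @param params A [banister_params()] object (or coercible list / one-row
#'   data frame with fields `p0`, `k1`, `k2`, `tau1`, `tau2`).
#' @param trimp Daily TRIMP series: a data frame with columns `day` (0-based
#'   consecutive integers) and `trimp`, as produced by [trimp_series()], or a
#'   bare numeric vector taken as days 0, 1, 2, ...
#' @param horizon Last day to predict (>= last day of the series); defaults to
#'   the series length.
#' @return A `banister_trajectory` tibble with columns `day`, `trimp`,
#'   `fitness`, `fatigue` and `predicted` (= `p0 + fitness - fatigue`), one
#'   row per day 0..horizon.
#' @examples
#' par <- banister_params(114, 0.03, 0.03, 45, 25)
#' w <- rep(300, 30) # 30 days of constant load
#' traj <- predict_performance(par, w, horizon = 60)
#' tail(traj)
#' @export
predict_performance <- function(params, trimp, horizon = NULL) {
  params <- as_banister_params(params)
  w <- trimp_values(trimp)
  n_days <- length(w)
  if (is.null(horizon)) horizon <- n_days
  if (horizon < n_days) {
    stop("`horizon` must cover the TRIMP series (", n_days, " days)", call. = FALSE)
  }
  fitness <- params$k1 * convolve_trimp(w, params$tau1, horizon)
  fatigue <- params$k2 * convolve_trimp(w, params$tau2, horizon)
  tibble::new_tibble(
    tibble::tibble(
      day = 0:horizon,
      trimp = c(w, rep(0, horizon - n_days + 1)),
      fitness = fitness,
      fatigue = fatigue,
      predicted = params$p0 + fitness - fatigue
    ),
    class = "banister_trajectory"
  )
}

trimp_values <- function(trimp) {
  if (is.data.frame(trimp)) {
    if (!all(c("day", "trimp") %in% names(trimp))) {
      stop("`trimp` data frame needs `day` and `trimp` columns", call. = FALSE)
    }
    trimp <- trimp[order(trimp$day), ]
    if (nrow(trimp) > 0 && !identical(as.integer(trimp$day), seq_len(nrow(trimp)) - 1L)) {
      stop("`trimp$day` must be consecutive integers starting at 0", call. = FALSE)
    }
    trimp <- trimp$trimp
  }
  if (any(trimp < 0)) stop("TRIMP values must be nonnegative", call. = FALSE)
  as.numeric(trimp)
}

#' Weeks for the training-induced gain to decay back to baseline
#'
#' Simulates detraining (`w = 0` after the last training day) and reports when
#' the residual modelled gain `p(t) - p0` first falls below
#' `threshold_fraction` of its post-training peak. Because both components
#' decay exponentially the gain never reaches zero exactly; the 5\% default
#' operationalises "return to baseline".
#'
#' @inheritParams predict_performance
#' @param threshold_fraction Fraction of the peak post-training gain below
#'   which performance counts as back to baseline (default 0.05).
#' @param max_weeks Simulation cap, weeks after training ends (default 200).
#' @return One-row tibble: `peak_gain` (m), `peak_day` (day index of the
#'   post-training peak), `decay_days` and `decay_weeks` (time from the peak
#'   to the threshold crossing).
#' @examples
#' par <- banister_params(100, k1 = 0.03, k2 = 0, tau1 = 45, tau2 = 25)
#' decay_to_baseline(par, c(500)) # single impulse: ~3 * tau1 days at 5%
#' @export
decay_to_baseline <- function(params, trimp, threshold_fraction = 0.05,
                              max_weeks = 200) {
  params <- as_banister_params(params)
  w <- trimp_values(trimp)
  horizon <- length(w) + max_weeks * 7L
  traj <- predict_performance(params, w, horizon = horizon)
  gain <- traj$predicted - params$p0
  post <- traj$day >= length(w) # days at/after cessation (first untrained day)
  peak_idx <- which(post)[which.max(gain[post])]
  peak_gain <- gain[peak_idx]
  if (peak_gain <= 0) {
    stop("no positive training-induced gain at cessation; decay undefined", call. = FALSE)
  }
  below <- which(traj$day >= traj$day[peak_idx] & gain <= threshold_fraction * peak_gain)
  if (length(below) == 0) {
    stop("gain did not decay below threshold within `max_weeks`; increase the cap", call. = FALSE)
  }
  decay_days <- traj$day[below[1]] - traj$day[peak_idx]
  tibble::tibble(
    peak_gain = peak_gain,
    peak_day = traj$day[peak_idx],
    decay_days = decay_days,
    decay_weeks = decay_days / 7
  )
}
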