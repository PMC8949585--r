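# Independent oracles and shared fixtures for the suite.

# Canonical worked-example session: habitual cadence 100 steps/min, ten 1-min
# walks at 60 steps/min separated by 1-min rests.
canonical_session <- function() {
  list(cadence = 60, habitual = 100, walk_min = 1, rest_min = 1, reps = 10)
}

# Deterministic TiTo-like daily TRIMP series without using the generator:
# cadence ramps 60% -> 90% of habitual over the weeks, two sessions a day.
tito_trimp_vector <- function(weeks = 27, habitual = 100, cap = 0.90) {
  days <- 0:(weeks * 7 - 1)
  frac <- pmin(0.60 + 0.03 * (days %/% 7), cap)
  cadence <- round(habitual * frac)
  2 * (cadence / habitual) * (10 / 19) * (cadence * 10)
}

# Brute-force O(T^2) Banister convolution: the oracle for the recursive
# implementation. Day t response sums over training days strictly before t.
brute_force_predict <- function(p0, k1, k2, tau1, tau2, w, horizon) {
  sapply(0:horizon, function(t) {
    i <- seq_len(min(t, length(w))) - 1
    if (length(i) == 0) return(p0)
    p0 + k1 * sum(w[i + 1] * exp(-(t - i) / tau1)) -
      k2 * sum(w[i + 1] * exp(-(t - i) / tau2))
  })
}

# All-pairs-median Passing-Bablok oracle, valid when every pairwise slope
# exceeds -1 (then the offset K is 0 and the estimate is the plain median).
brute_force_pb <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      slopes <- c(slopes, if (dx == 0) sign(dy) * Inf else dy / dx)
    }
  }
  stopifnot(all(slopes > -1)) # oracle precondition
  b <- stats::median(slopes)
  list(slope = b, intercept = stats::median(y - b * x), slopes = slopes)
}

# Two-way ANOVA mean squares via stats::aov, the independent route to the
# ICC decomposition.
aov_mean_squares <- function(x, y) {
  n <- length(x)
  df <- data.frame(
    v = c(x, y),
    subj = factor(rep(seq_len(n), 2)),
    rater = factor(rep(c("a", "b"), each = n))
  )
  tab <- summary(stats::aov(v ~ subj + rater, data = df))[[1]]
  list(
    msr = tab["subj", "Mean Sq"],
    msc = tab["rater", "Mean Sq"],
    mse = tab["Residuals", "Mean Sq"]
  )
}

# Draw a method-comparison fixture whose pairwise slopes all exceed -1, so
# the plain all-pairs median is a valid oracle (offset K = 0).
gen_pb_fixture <- function(n, slope = 1.05, intercept = -8, noise_sd = 20) {
  repeat {
    x <- round(runif(n, 80, 350), 1)
    y <- round(slope * x + intercept + rnorm(n, 0, noise_sd), 1)
    ij <- utils::combn(n, 2)
    dx <- x[ij[2, ]] - x[ij[1, ]]; dy <- y[ij[2, ]] - y[ij[1, ]]
    s <- dy[dx != 0] / dx[dx != 0]
    if (all(dx != 0) && all(s > -1)) return(list(x = x, y = y))
  }
}

# Five-visit schedule (weeks 0, 5, 12, 20, 28) in days, unjittered.
visit_days_default <- function() c(0, 5, 12, 20, 28) * 7

make_visits <- function(days, values) {
  tibble::tibble(
    visit_label = paste0("T", seq_along(days) - 1),
    day_index = days,
    pfwd_m = values,
    six_mwd_m = values
  )
}
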