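#' Control settings for Banister model calibration
#'
#' The fit profiles the two decay constants on a deterministic grid, solving
#' the two magnitude factors by nonnegative linear least squares at each grid
#' point (the model is linear in `k1`, `k2` given `tau1`, `tau2`), then
#' polishes the best grid point with a bounded quasi-Newton refinement.
#'
#' @param tau1_bounds,tau2_bounds Search bounds in days. Defaults
#'   `c(10, 80)` and `c(5, 60)` cover the parameter ranges typically reported
#'   for walking rehabilitation (population means +/- 2 SD).
#' @param tau_step Grid step, days (default 1).
#' @param refine Logical: run the local refinement after the grid (default
#'   TRUE).
#' @param df_model Effective model degrees of freedom charged in the ANOVA on
#'   the residual sum of squares (default 2: the two magnitude factors, the
#'   profiled decay constants are not charged).
#' @param r2_threshold Acceptability rule on the coefficient of determination
#'   (default: a fit is acceptable when R^2 > 0.30).
#' @return A `banister_control` list.
#' @export
banister_control <- function(tau1_bounds = c(10, 80), tau2_bounds = c(5, 60),
                             tau_step = 1, refine = TRUE, df_model = 2,
                             r2_threshold = 0.30) {
  stopifnot(
    length(tau1_bounds) == 2, tau1_bounds[1] > 0, diff(tau1_bounds) > 0,
    length(tau2_bounds) == 2, tau2_bounds[1] > 0, diff(tau2_bounds) > 0,
    tau_step > 0
  )
  structure(
    list(
      tau1_bounds = tau1_bounds, tau2_bounds = tau2_bounds,
      tau_step = tau_step, refine = isTRUE(refine),
      df_model = df_model, r2_threshold = r2_threshold
    ),
    class = "banister_control"
  )
}

# Fitness/fatigue basis at the visit days: B[j, v] = sum_{i < t_v} w_i
# exp(-(t_v - i)/tau_j). Rows follow `taus`, columns follow `visit_days`.
basis_at_days <- function(w, visit_days, taus) {
  n <- length(w)
  out <- matrix(0, nrow = length(taus), ncol = length(visit_days))
  for (v in seq_along(visit_days)) {
    t_v <- visit_days[v]
    i <- seq_len(min(t_v, n)) - 1 # training days strictly before t_v
    if (length(i) == 0) next
    out[, v] <- exp(-outer(1 / taus, t_v - i)) %*% w[i + 1]
  }
  out
}

# Nonnegative least squares for y ~ k1*B1 - k2*B2, k1, k2 >= 0. With two
# variables the optimum is one of four candidates: the unconstrained normal-
# equation solution (when feasible), each single-k fit, or zero.
nnls2 <- function(B1, B2, y) {
  s11 <- sum(B1^2); s22 <- sum(B2^2); s12 <- sum(B1 * B2)
  b1 <- sum(B1 * y); b2 <- sum(B2 * y); syy <- sum(y^2)
  cand_k1 <- c(0); cand_k2 <- c(0); cand_rss <- c(syy)
  det <- s11 * s22 - s12^2
  if (det > 1e-12 * s11 * s22) {
    k1 <- (b1 * s22 - s12 * b2) / det
    k2 <- (s12 * b1 - s11 * b2) / det
    if (k1 >= 0 && k2 >= 0) {
      cand_k1 <- c(cand_k1, k1); cand_k2 <- c(cand_k2, k2)
      cand_rss <- c(cand_rss, syy - (k1 * b1 - k2 * b2))
    }
  }
  if (s11 > 0 && b1 > 0) {
    cand_k1 <- c(cand_k1, b1 / s11); cand_k2 <- c(cand_k2, 0)
    cand_rss <- c(cand_rss, syy - b1^2 / s11)
  }
  if (s22 > 0 && b2 < 0) {
    cand_k1 <- c(cand_k1, 0); cand_k2 <- c(cand_k2, -b2 / s22)
    cand_rss <- c(cand_rss, syy - b2^2 / s22)
  }
  best <- which.min(cand_rss)
  list(k1 = cand_k1[best], k2 = cand_k2[best], rss = max(cand_rss[best], 0))
}

# Vectorised profiled grid search over (tau1, tau2). Returns the best grid
# point under the deterministic tie-break (smallest RSS, then smallest tau2,
# then smallest tau1) plus the full RSS surface.
grid_search_tau <- function(w, visit_days, y, tau1_grid, tau2_grid) {
  B1 <- basis_at_days(w, visit_days, tau1_grid) # n1 x V
  B2 <- basis_at_days(w, visit_days, tau2_grid) # n2 x V
  s11 <- rowSums(B1^2); s22 <- rowSums(B2^2)
  b1 <- drop(B1 %*% y); b2 <- drop(B2 %*% y)
  s12 <- B1 %*% t(B2) # n1 x n2
  syy <- sum(y^2)
  n1 <- length(tau1_grid); n2 <- length(tau2_grid)

  det <- outer(s11, s22) - s12^2
  k1f <- (outer(b1, s22) - s12 * rep(b2, each = n1)) / det
  k2f <- (s12 * rep(b1, times = n2) - outer(s11, b2)) / det
  rss_full <- syy - (k1f * rep(b1, times = n2) - k2f * rep(b2, each = n1))
  ok <- det > 1e-12 * outer(s11, s22) # collinear bases (e.g. tau1 == tau2) excluded
  rss_full[!ok] <- Inf
  k1f[!ok] <- -1; k2f[!ok] <- -1
  rss_full[k1f < 0 | k2f < 0] <- Inf

  rss_k1 <- ifelse(s11 > 0 & b1 > 0, syy - b1^2 / s11, syy) # tau1 only
  rss_k2 <- ifelse(s22 > 0 & b2 < 0, syy - b2^2 / s22, syy) # tau2 only
  rss_axis <- pmin(
    matrix(rss_k1, n1, n2),
    matrix(rss_k2, n1, n2, byrow = TRUE)
  )
  rss <- pmin(rss_full, rss_axis)

  best_rss <- min(rss)
  ties <- which(rss <= best_rss + 1e-9 * (1 + abs(best_rss)), arr.ind = TRUE)
  ord <- order(tau2_grid[ties[, 2]], tau1_grid[ties[, 1]])
  a <- ties[ord[1], 1]; b <- ties[ord[1], 2]
  sol <- nnls2(B1[a, ], B2[b, ], y)
  list(
    tau1 = tau1_grid[a], tau2 = tau2_grid[b],
    k1 = sol$k1, k2 = sol$k2, rss = sol$rss, rss_surface = rss
  )
}

profiled_rss <- function(tau, w, visit_days, y) {
  B1 <- drop(basis_at_days(w, visit_days, tau[1]))
  B2 <- drop(basis_at_days(w, visit_days, tau[2]))
  nnls2(B1, B2, y)$rss
}

#' Fit the Banister model to one subject's visit measurements
#'
#' Calibrates `(k1, k2, tau1, tau2)` against sparse clinic-visit measurements
#' by minimising the residual sum of squares between the predicted trajectory
#' and the measured performance at the visit days. The baseline `p0` is fixed
#' at the measured value of the day-0 visit rather than fitted: with only a
#' handful of follow-up visits this saves a degree of freedom, and the model
#' then explains the *changes* from baseline. The magnitude factors are
#' constrained nonnegative.
#'
#' @param trimp Daily TRIMP series ([trimp_series()] output or numeric
#'   vector).
#' @param visits Data frame of visit measurements with columns `day_index`
#'   (days since programme start; the baseline visit has `day_index` 0) and
#'   the outcome column (`pfwd_m` or `six_mwd_m`).
#' @param outcome `"pfwd"` (pain-free walking distance) or `"6mwd"` (total
#'   6-min walking distance).
#' @param p0 Baseline performance in metres; defaults to the measurement at
#'   `day_index == 0`.
#' @param control A [banister_control()] list.
#' @return A `banister_fit` object with elements `params`
#'   ([banister_params()]), `rss`, `r_squared`, `f_statistic`, `f_pvalue`,
#'   `acceptable` (R^2 above the control threshold), `n_obs` (number of
#'   post-baseline visits fitted) and `fitted` (tibble of day, measured,
#'   predicted, residual). Supports [generics::tidy()], [generics::glance()]
#'   and [generics::augment()].
#' @export
fit_banister <- function(trimp, visits, outcome = c("pfwd", "6mwd"),
                         p0 = NULL, control = banister_control()) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "6mwd") "six_mwd_m" else "pfwd_m"
  visits <- tibble::as_tibble(visits)
  if (!col %in% names(visits)) {
    stop("`visits` has no column `", col, "`", call. = FALSE)
  }
  w <- trimp_values(trimp)
  if (all(w == 0)) {
    stop("all TRIMP values are zero: the model is unidentifiable", call. = FALSE)
  }
  if (is.null(p0)) {
    at0 <- visits$day_index == 0
    if (!any(at0)) stop("no baseline visit (day_index == 0) and no `p0` given", call. = FALSE)
    p0 <- visits[[col]][which(at0)[1]]
  }
  fitv <- visits[visits$day_index > 0 & !is.na(visits[[col]]), ]
  if (nrow(fitv) < 3) {
    stop("need at least 3 post-baseline visits to calibrate", call. = FALSE)
  }
  fitv <- fitv[order(fitv$day_index), ]
  days <- as.integer(fitv$day_index)
  y <- fitv[[col]] - p0

  tau1_grid <- seq(control$tau1_bounds[1], control$tau1_bounds[2], by = control$tau_step)
  tau2_grid <- seq(control$tau2_bounds[1], control$tau2_bounds[2], by = control$tau_step)
  grid <- grid_search_tau(w, days, y, tau1_grid, tau2_grid)

  tau <- c(grid$tau1, grid$tau2); rss <- grid$rss
  if (control$refine) {
    ref <- tryCatch(
      stats::optim(
        tau, profiled_rss,
        w = w, visit_days = days, y = y,
        method = "L-BFGS-B",
        lower = c(control$tau1_bounds[1], control$tau2_bounds[1]),
        upper = c(control$tau1_bounds[2], control$tau2_bounds[2])
      ),
      error = function(e) NULL
    )
    if (!is.null(ref) && ref$value < rss) {
      tau <- ref$par
      rss <- ref$value
    }
  }
  B1 <- drop(basis_at_days(w, days, tau[1]))
  B2 <- drop(basis_at_days(w, days, tau[2]))
  sol <- nnls2(B1, B2, y)
  params <- banister_params(p0 = p0, k1 = sol$k1, k2 = sol$k2,
                            tau1 = tau[1], tau2 = tau[2])
  predicted <- p0 + sol$k1 * B1 - sol$k2 * B2
  gof <- goodness_of_fit(fitv[[col]], predicted, df_model = control$df_model)

  structure(
    list(
      params = params,
      outcome = outcome,
      rss = sol$rss,
      r_squared = gof$r_squared,
      f_statistic = gof$f_statistic,
      f_pvalue = gof$f_pvalue,
      acceptable = !is.na(gof$r_squared) && gof$r_squared > control$r2_threshold,
      n_obs = nrow(fitv),
      fitted = tibble::tibble(
        day = days,
        measured = fitv[[col]],
        predicted = predicted,
        residual = fitv[[col]] - predicted
      ),
      control = control,
      trimp = w
    ),
    class = "banister_fit"
  )
}

#' Goodness of fit between predicted and measured performance
#'
#' Computes the coefficient of determination `R^2 = 1 - RSS/TSS` (total sum of
#' squares about the mean of the measured values) and an F test on the
#' residual sum of squares: `F = ((TSS - RSS)/df_model) / (RSS/df_resid)`.
#'
#' @param measured,predicted Paired numeric vectors (>= 3 points).
#' @param df_model Model degrees of freedom (default 2, the two magnitude
#'   factors of the impulse-response fit).
#' @param df_resid Residual degrees of freedom; defaults to
#'   `length(measured) - df_model`.
#' @return One-row tibble: `r_squared`, `rss`, `tss`, `f_statistic`,
#'   `f_pvalue`, `df_model`, `df_resid`.
#' @export
goodness_of_fit <- function(measured, predicted, df_model = 2,
                            df_resid = length(measured) - df_model) {
  stopifnot(length(measured) == length(predicted))
  if (length(measured) < 3) stop("need at least 3 paired points", call. = FALSE)
  rss <- sum((measured - predicted)^2)
  tss <- sum((measured - mean(measured))^2)
  if (tss == 0) stop("zero total sum of squares: R^2 undefined", call. = FALSE)
  r2 <- 1 - rss / tss
  f_stat <- if (df_resid > 0 && rss > 0) {
    ((tss - rss) / df_model) / (rss / df_resid)
  } else {
    NA_real_
  }
  pval <- if (is.finite(f_stat)) {
    stats::pf(f_stat, df_model, df_resid, lower.tail = FALSE)
  } else {
    NA_real_
  }
  tibble::tibble(
    r_squared = r2, rss = rss, tss = tss,
    f_statistic = f_stat, f_pvalue = pval,
    df_model = df_model, df_resid = df_resid
  )
}

#' @export
print.banister_fit <- function(x, ...) {
  cat(sprintf("Banister fit (%s), %d post-baseline visits\n", x$outcome, x$n_obs))
  print(x$params)
  cat(sprintf(
    "  RSS = %.2f m^2, R^2 = %.3f (%sacceptable at R^2 > %.2f)\n",
    x$rss, x$r_squared, if (x$acceptable) "" else "not ", x$control$r2_threshold
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @method tidy banister_fit
#' @export
tidy.banister_fit <- function(x, ...) {
  tibble::tibble(
    term = c("p0", "k1", "k2", "tau1", "tau2"),
    estimate = unlist(x$params, use.names = FALSE)
  )
}

#' @method glance banister_fit
#' @export
glance.banister_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    rss = x$rss,
    statistic = x$f_statistic,
    p.value = x$f_pvalue,
    df = x$control$df_model,
    df.residual = x$n_obs - x$control$df_model,
    acceptable = x$acceptable,
    nobs = x$n_obs
  )
}

#' @method augment banister_fit
#' @export
augment.banister_fit <- function(x, ...) {
  x$fitted
}

#' Summarise fitted parameters across a cohort
#'
#' @param params_df Tibble with one row per fitted subject (and outcome)
#'   holding columns `p0`, `k1`, `k2`, `tau1`, `tau2`, `r_squared` and
#'   `acceptable`, e.g. the `fits` table from [run_pipeline()].
#' @param by Optional character vector of grouping columns (e.g. `"sex"`,
#'   `"outcome"`).
#' @return Long tibble with (per group) `parameter`, `mean`, `sd`, `n` and
#'   `n_acceptable` (count of fits with R^2 above the acceptability
#'   threshold).
#' @export
cohort_summary <- function(params_df, by = NULL) {
  params_df <- tibble::as_tibble(params_df)
  if (nrow(params_df) == 0) stop("no fits to summarise", call. = FALSE)
  pars <- intersect(c("p0", "k1", "k2", "tau1", "tau2", "r_squared"), names(params_df))
  grouped <- dplyr::group_by(params_df, dplyr::across(dplyr::all_of(by)))
  long <- grouped |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(pars),
        list(mean = ~ mean(.x), sd = ~ stats::sd(.x)),
        .names = "{.col}@{.fn}"
      ),
      n = dplyr::n(),
      n_acceptable = if ("acceptable" %in% names(params_df)) {
        sum(.data$acceptable)
      } else {
        NA_integer_
      },
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(
      cols = dplyr::contains("@"),
      names_to = c("parameter", ".value"),
      names_sep = "@"
    )
  # single fit: sd() returns NA; report 0 spread
  long$sd[is.na(long$sd) & long$n == 1] <- 0
  dplyr::relocate(long, "parameter", "mean", "sd", .before = "n")
}
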