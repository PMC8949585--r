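test_that("goodness of fit matches hand-computed RSS/TSS arithmetic", {
  measured <- c(120, 150, 180, 170)
  predicted <- c(125, 140, 185, 165)
  # by hand: RSS = 25 + 100 + 25 + 25 = 175; mean = 155; TSS = 1225+25+625+225
  gof <- goodness_of_fit(measured, predicted, df_model = 2)
  expect_equal(gof$rss, 175)
  expect_equal(gof$tss, 2100)
  expect_equal(gof$r_squared, 1 - 175 / 2100)
  f_hand <- ((2100 - 175) / 2) / (175 / 2)
  expect_equal(gof$f_statistic, f_hand)
  expect_equal(gof$f_pvalue, pf(f_hand, 2, 2, lower.tail = FALSE))
  # perfect fit and mean-only fit
  expect_equal(goodness_of_fit(measured, measured)$r_squared, 1)
  expect_equal(goodness_of_fit(measured, rep(mean(measured), 4))$r_squared, 0)
  expect_error(goodness_of_fit(c(1, 1, 1), c(1, 2, 3)), "undefined")
})

test_that("noiseless subjects are recovered at prediction level (5 visits)", {
  w <- tito_trimp_vector()
  vdays <- visit_days_default()
  cases <- list(
    c(114, 0.03, 0.03, 45, 25),
    c(287, 0.02, 0.03, 37, 26),
    c(200, 0.05, 0.01, 60, 10),
    c(90, 0.004, 0.008, 20, 40) # fatigue-dominated, dips below baseline
  )
  for (cs in cases) {
    par <- banister_params(cs[1], cs[2], cs[3], cs[4], cs[5])
    traj <- predict_performance(par, w, horizon = max(vdays))
    meas <- traj$predicted[match(vdays, traj$day)]
    fit <- fit_banister(w, make_visits(vdays, meas), outcome = "pfwd")
    expect_lt(max(abs(fit$fitted$predicted - meas[-1])), 0.1)
  }
})

test_that("parameters themselves are recovered from richer visit schedules", {
  w <- tito_trimp_vector()
  vdays <- c(0, 3, 6, 9, 13, 17, 21, 25) * 7 # 7 post-baseline points
  for (cs in list(c(114, 0.03, 0.03, 45, 25), c(287, 0.02, 0.035, 37, 20))) {
    par <- banister_params(cs[1], cs[2], cs[3], cs[4], cs[5])
    traj <- predict_performance(par, w, horizon = max(max(vdays), length(w)))
    meas <- traj$predicted[match(vdays, traj$day)]
    fit <- fit_banister(w, make_visits(vdays, meas), outcome = "pfwd")
    expect_lte(abs(fit$params$tau1 - cs[4]), 2)
    expect_lte(abs(fit$params$tau2 - cs[5]), 2)
    expect_equal(fit$params$k1, cs[2], tolerance = 0.02)
    expect_equal(fit$params$k2, cs[3], tolerance = 0.02)
  }
})

test_that("the refined optimum is at least as good as every grid point", {
  set.seed(21)
  w <- tito_trimp_vector(weeks = 20)
  vdays <- c(0, 5, 9, 14, 20) * 7
  par <- banister_params(150, 0.02, 0.025, 42, 18)
  traj <- predict_performance(par, w, horizon = max(vdays))
  meas <- traj$predicted[match(vdays, traj$day)] + rnorm(5, 0, 12)
  fit <- fit_banister(w, make_visits(vdays, meas), outcome = "pfwd", p0 = meas[1])
  y <- meas[-1] - meas[1]
  for (t1 in seq(10, 80, by = 7)) {
    for (t2 in seq(5, 60, by = 7)) {
      expect_lte(
        fit$rss,
        fitfatigue:::profiled_rss(c(t1, t2), w, vdays[-1], y) + 1e-8
      )
    }
  }
})

test_that("closed-form nonnegative least squares agrees with pracma::lsqnonneg", {
  skip_if_not_installed("pracma")
  set.seed(33)
  for (i in 1:40) {
    B1 <- runif(6, 0, 100); B2 <- runif(6, 0, 100)
    y <- rnorm(6, 0, 50)
    mine <- fitfatigue:::nnls2(B1, B2, y)
    ref <- pracma::lsqnonneg(cbind(B1, -B2), y)
    expect_equal(c(mine$k1, mine$k2), unname(ref$x), tolerance = 1e-8)
    expect_equal(mine$rss, sum(ref$resid.norm), tolerance = 1e-8)
  }
})

test_that("measurement noise inflates fitted RSS in proportion to its variance", {
  set.seed(55)
  w <- tito_trimp_vector()
  vdays <- seq(0, 27, by = 3) * 7 # 9 post-baseline points
  par <- banister_params(150, 0.02, 0.02, 45, 25)
  traj <- predict_performance(par, w, horizon = max(vdays))
  truth <- traj$predicted[match(vdays, traj$day)]
  mean_rss <- function(sigma, reps = 25) {
    mean(replicate(reps, {
      meas <- truth + rnorm(length(truth), 0, sigma)
      fit_banister(w, make_visits(vdays, meas), outcome = "pfwd")$rss
    }))
  }
  r5 <- mean_rss(5); r15 <- mean_rss(15)
  expect_gt(r15, r5)
  # with ~4 effective parameters, E[RSS] ~ (n_fit - 4) * sigma^2
  n_fit <- length(vdays) - 1
  expect_gt(r15 / 15^2, 0.4 * (n_fit - 4))
  expect_lt(r15 / 15^2, 1.8 * (n_fit - 4))
})

test_that("degenerate calibration inputs raise informative errors", {
  w <- tito_trimp_vector(weeks = 10)
  vd <- c(0, 35, 70) # only 2 post-baseline visits
  expect_error(
    fit_banister(w, make_visits(vd, c(100, 120, 130)), outcome = "pfwd"),
    "at least 3"
  )
  vd5 <- visit_days_default()
  expect_error(
    fit_banister(rep(0, 200), make_visits(vd5, rep(100, 5)), outcome = "pfwd"),
    "unidentifiable"
  )
  expect_error(
    fit_banister(w, make_visits(vd5[-1] , c(100, 110, 120, 125)), outcome = "pfwd"),
    "baseline"
  )
})

test_that("null response data yields a near-zero-RSS flat fit", {
  w <- tito_trimp_vector(weeks = 27)
  vdays <- visit_days_default()
  expect_error( # constant measurements: TSS = 0, R^2 undefined
    fit_banister(w, make_visits(vdays, rep(150, 5)), outcome = "pfwd"),
    "undefined"
  )
  # nearly constant: RSS stays at the noise floor
  meas <- c(150, 150.2, 149.9, 150.1, 150.0)
  fit <- fit_banister(w, make_visits(vdays, meas), outcome = "pfwd")
  expect_lte(fit$rss, sum((meas[-1] - 150)^2) + 1e-8)
})

test_that("tidy/glance/augment expose the fit in broom style", {
  w <- tito_trimp_vector()
  vdays <- visit_days_default()
  par <- banister_params(114, 0.03, 0.03, 45, 25)
  meas <- predict_performance(par, w, horizon = max(vdays))$predicted[vdays + 1]
  fit <- fit_banister(w, make_visits(vdays, meas), outcome = "pfwd")
  td <- tidy(fit)
  expect_equal(td$term, c("p0", "k1", "k2", "tau1", "tau2"))
  expect_equal(td$estimate[1], 114)
  gl <- glance(fit)
  expect_true(gl$acceptable)
  expect_equal(gl$nobs, 4)
  expect_equal(nrow(augment(fit)), 4)
})

test_that("cohort summaries collapse to the fit itself for n = 1 and respect symmetry", {
  one <- tibble::tibble(
    p0 = 114, k1 = 0.03, k2 = 0.02, tau1 = 45, tau2 = 25,
    r_squared = 0.9, acceptable = TRUE
  )
  s <- cohort_summary(one)
  expect_equal(s$mean[s$parameter == "tau1"], 45)
  expect_true(all(s$sd == 0))
  expect_equal(unique(s$n_acceptable), 1L)
  # two identical subgroups summarise identically
  two <- dplyr::bind_rows(
    dplyr::mutate(one, sex = "M"), dplyr::mutate(one, sex = "F")
  )
  by_sex <- cohort_summary(two, by = "sex")
  a <- by_sex[by_sex$sex == "M", setdiff(names(by_sex), "sex")]
  b <- by_sex[by_sex$sex == "F", setdiff(names(by_sex), "sex")]
  expect_equal(as.data.frame(a), as.data.frame(b))
})
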