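test_that("exact affine data is recovered exactly by Passing-Bablok", {
  x <- c(51, 60, 75, 89, 104, 120, 133)
  pb1 <- passing_bablok(x, x)
  expect_equal(pb1$slope, 1)
  expect_equal(pb1$intercept, 0)
  pb2 <- passing_bablok(x, 2 * x + 3)
  expect_equal(pb2$slope, 2)
  expect_equal(pb2$intercept, 3)
  expect_equal(pb2$linearity$p.value, 1) # no residual scatter, no deviation
})

test_that("Passing-Bablok equals the all-pairs-median brute force on noisy sets", {
  set.seed(9)
  for (n in c(5, 8, 10, 12, 15)) {
    fx <- gen_pb_fixture(n, slope = 0.9, intercept = 12, noise_sd = 18)
    x <- fx$x; y <- fx$y
    pb <- passing_bablok(x, y)
    oracle <- brute_force_pb(x, y)
    expect_equal(pb$slope, oracle$slope)
    expect_equal(pb$intercept, oracle$intercept)
    expect_equal(pb$n_slopes, length(oracle$slopes))
    # CI brackets the estimate
    expect_lte(pb$ci_slope[1], pb$slope)
    expect_gte(pb$ci_slope[2], pb$slope)
  }
})

test_that("Passing-Bablok is scale- and shift-equivariant", {
  set.seed(10)
  x <- runif(12, 100, 300)
  y <- 1.1 * x + rnorm(12, 0, 15)
  pb <- passing_bablok(x, y)
  for (a in c(0.5, 3)) {
    pbs <- passing_bablok(a * x, a * y)
    expect_equal(pbs$slope, pb$slope, tolerance = 1e-12)
    expect_equal(pbs$intercept, a * pb$intercept, tolerance = 1e-9)
  }
  b <- 40
  pbb <- passing_bablok(x + b, y + b)
  expect_equal(pbb$slope, pb$slope, tolerance = 1e-12)
  expect_equal(pbb$intercept, pb$intercept + b * (1 - pb$slope), tolerance = 1e-9)
})

test_that("Passing-Bablok is invariant to swapping the methods", {
  # the -1 exclusion and the K offset exist precisely so that regressing
  # x on y inverts the slope; steep noisy data exercises K > 0
  set.seed(19)
  for (i in 1:8) {
    x <- runif(10, 50, 120)
    y <- 3 * x - 40 + rnorm(10, 0, 60)
    fwd <- passing_bablok(x, y)
    rev <- passing_bablok(y, x)
    expect_equal(rev$slope, 1 / fwd$slope, tolerance = 1e-12)
  }
})

test_that("degenerate Passing-Bablok inputs error", {
  expect_error(passing_bablok(c(1, 2), c(1, 2)), "at least 3")
  expect_error(passing_bablok(rep(5, 6), c(1, 2, 3, 4, 5, 6)), "degenerate")
})

test_that("ICC is exactly 1 on duplicated data and shift-invariant", {
  x <- c(100, 150, 210, 260, 300, 330)
  r <- icc_agreement(x, x)
  expect_equal(r$icc, 1)
  expect_equal(c(r$conf.low, r$conf.high), c(1, 1))
  y <- x + c(-8, 5, 3, -4, 9, -2)
  r1 <- icc_agreement(x, y)
  r2 <- icc_agreement(x + 75, y + 75)
  expect_equal(r1$icc, r2$icc)
  expect_equal(r1$conf.low, r2$conf.low)
})

test_that("ICC matches the ANOVA mean-squares decomposition on a 6x2 table", {
  x <- c(120, 180, 150, 260, 310, 95)
  y <- c(135, 170, 166, 240, 330, 102)
  ms <- aov_mean_squares(x, y) # independent route to the mean squares
  n <- 6; k <- 2
  icc_hand <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  r <- icc_agreement(x, y)
  expect_equal(r$icc, icc_hand, tolerance = 1e-10)
  expect_equal(r$ms_rows, ms$msr, tolerance = 1e-10)
  expect_equal(r$ms_cols, ms$msc, tolerance = 1e-10)
  expect_equal(r$ms_error, ms$mse, tolerance = 1e-10)
  expect_lte(r$conf.low, r$icc)
  expect_gte(r$conf.high, r$icc)
})

test_that("ICC on unrelated data is near zero and degenerate input errors", {
  set.seed(12)
  x <- rnorm(400, 200, 50)
  y <- rnorm(400, 200, 50) # independent: population ICC 0
  r <- icc_agreement(x, y)
  expect_lt(abs(r$icc), 0.12)
  expect_error(icc_agreement(rep(3, 5), rep(3, 5)), "undefined")
})

test_that("paired t-test matches hand arithmetic and guards degeneracy", {
  pre <- c(100, 120, 140, 160, 180)
  post <- c(112, 118, 155, 171, 189)
  d <- post - pre
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  r <- paired_t_test(pre, post)
  expect_equal(r$statistic, t_hand)
  expect_equal(r$p.value, 2 * pt(-abs(t_hand), df = 4))
  # identical vectors: t = 0, p = 1 by convention
  r0 <- paired_t_test(pre, pre)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  # constant nonzero difference: infinite t guarded
  expect_error(paired_t_test(pre, pre + 5), "degenerate")
})

test_that("the pooled agreement panel is internally consistent", {
  set.seed(14)
  df <- tibble::tibble(
    measured = runif(40, 100, 400),
    estimated = NA_real_
  )
  df$estimated <- df$measured + rnorm(40, 0, 12)
  res <- agreement_stats(df, measured, estimated)
  expect_equal(res$n, 40)
  expect_gt(res$icc, 0.9)
  expect_lte(res$icc_low, res$icc)
  expect_gte(res$icc_high, res$icc)
  expect_lt(abs(res$pb_slope - 1), 0.1)
  pb <- passing_bablok(df$measured, df$estimated)
  expect_equal(res$pb_slope, pb$slope)
})
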