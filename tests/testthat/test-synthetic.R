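test_that("prescriptions follow the progressive cadence schedule", {
  cfg <- cohort_config(n_subjects = 1)
  d <- generate_prescriptions(100, cfg, cap = 0.90)
  expect_equal(nrow(d), 27 * 7 * 2) # two sessions every day
  # week 1 at 60% of habitual
  expect_true(all(d$cadence_spm[d$week == 1] == 60))
  # +3% per week until the cap
  expect_true(all(d$cadence_spm[d$week == 2] == 63))
  expect_true(all(d$cadence_spm[d$week >= 11] == 90)) # capped
  # monotone non-decreasing week over week
  weekly <- tapply(d$cadence_spm, d$week, unique)
  expect_true(all(diff(unlist(weekly)) >= 0))
  expect_true(all(d$walk_min == 1 & d$rest_min == 1 & d$repetitions == 10))
})

test_that("cohorts are byte-identical under a fixed seed", {
  cfg <- cohort_config(n_subjects = 4, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$diary, c2$diary)
  expect_identical(c1$visits, c2$visits)
  expect_identical(c1$true_params, c2$true_params)
  # a different seed gives different draws
  c3 <- generate_cohort(cohort_config(n_subjects = 4, seed = 100))
  expect_false(identical(c1$visits, c3$visits))
})

test_that("generated cohorts respect their structural invariants", {
  cfg <- cohort_config(n_subjects = 12, seed = 17)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$subjects), 12)
  expect_equal(sum(co$subjects$sex == "M"), 9) # 75% male
  expect_true(all(co$subjects$pfwd_m <= co$subjects$six_mwd_m))
  expect_true(all(co$visits$pfwd_m <= co$visits$six_mwd_m))
  expect_true(all(co$visits$pfwd_m >= 0))
  # every subject has a baseline visit at day 0 and jittered later visits
  base <- co$visits[co$visits$visit_label == "T0", ]
  expect_true(all(base$day_index == 0))
  # parameter draws stay in the admissible space
  expect_true(all(co$true_params$k1 >= 0 & co$true_params$k2 >= 0))
  expect_true(all(co$true_params$tau1 >= 10 & co$true_params$tau1 <= 80))
  expect_true(all(co$true_params$tau2 >= 5 & co$true_params$tau2 <= 60))
  # adherence: skipped sessions carry performed_fraction 0, roughly 8%
  skip_rate <- mean(co$diary$performed_fraction == 0)
  expect_gt(skip_rate, 0.02)
  expect_lt(skip_rate, 0.16)
})

test_that("truncated-normal draws converge to the analytic truncated mean", {
  set.seed(123)
  n <- 2000
  cases <- list(
    c(mean = 0.03, sd = 0.06, lower = 0, upper = Inf),
    c(mean = 45, sd = 13, lower = 10, upper = 80),
    c(mean = 26, sd = 9, lower = 5, upper = 60)
  )
  for (cs in cases) {
    draws <- fitfatigue:::rtrunc_norm(n, cs["mean"], cs["sd"], cs["lower"], cs["upper"])
    expect_true(all(draws >= cs["lower"] & draws <= cs["upper"]))
    m_true <- fitfatigue:::trunc_norm_mean(cs["mean"], cs["sd"], cs["lower"], cs["upper"])
    se <- sd(draws) / sqrt(n)
    expect_lt(abs(mean(draws) - m_true), 3 * se + 1e-9)
  }
})

test_that("modelled end-of-follow-up gains centre on the configured change distribution", {
  cfg <- cohort_config(n_subjects = 150, seed = 31, noise_sd = 0, adherence = 1)
  co <- generate_cohort(cfg)
  gains <- co$visits |>
    tidyr::pivot_longer(c("pfwd_m", "six_mwd_m"),
                        names_to = "outcome", values_to = "v") |>
    dplyr::group_by(.data$subject_id, .data$outcome) |>
    dplyr::summarise(gain = .data$v[which.max(.data$day_index)] - .data$v[.data$day_index == 0],
                     .groups = "drop")
  g6 <- gains$gain[gains$outcome == "six_mwd_m"]
  gp <- gains$gain[gains$outcome == "pfwd_m"]
  # 6MWD gains are unconstrained by the ordering and track the target closely
  expect_lt(abs(mean(g6) - cfg$gain_6mwd[1]), 4 * cfg$gain_6mwd[2] / sqrt(length(g6)) + 5)
  # PFWD gains are additionally conditioned on PFWD <= 6MWD, which trims the
  # upper tail: the mean sits at or somewhat below the configured target
  expect_lt(mean(gp), cfg$gain_pfwd[1] + 15)
  expect_gt(mean(gp), cfg$gain_pfwd[1] - 60)
})

test_that("first-day TRIMP matches the session arithmetic at 60% cadence", {
  cfg <- cohort_config(n_subjects = 60, seed = 77)
  co <- generate_cohort(cfg)
  first <- co$diary |>
    dplyr::filter(.data$day == 0) |>
    dplyr::left_join(co$subjects, by = "subject_id")
  # expected daily value: two sessions of intensity * density * volume with
  # cadence = round(0.60 * habitual), ignoring the ~8% skip probability
  expected <- with(
    first,
    (cadence_spm / habitual_speed_spm) * (10 / 19) * (cadence_spm * 10) * performed_fraction
  )
  w_first <- co$diary |>
    dplyr::filter(.data$day == 0) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  expect_true(all(w_first$n == 2))
  observed <- sapply(seq_len(nrow(co$subjects)), function(i) {
    s <- co$subjects$subject_id[i]
    sd_ <- co$diary[co$diary$subject_id == s & co$diary$day == 0, ]
    sum(compute_trimp(sd_, co$subjects$habitual_speed_spm[i])$trimp)
  })
  expect_equal(mean(observed), mean(tapply(expected, first$subject_id, sum)),
               tolerance = 1e-9)
  expect_true(all(first$cadence_spm == round(0.60 * first$habitual_speed_spm)))
})

test_that("a noiseless cohort round-trips through calibration at every visit", {
  cfg <- cohort_config(n_subjects = 6, seed = 404, noise_sd = 0, adherence = 1)
  co <- generate_cohort(cfg)
  for (i in seq_len(nrow(co$subjects))) {
    s <- co$subjects[i, ]
    w <- trimp_series(co$diary[co$diary$subject_id == s$subject_id, ],
                      habitual_speed = s$habitual_speed_spm)
    v <- co$visits[co$visits$subject_id == s$subject_id, ]
    for (oc in c("pfwd", "6mwd")) {
      fit <- fit_banister(w, v, outcome = oc)
      col <- if (oc == "6mwd") "six_mwd_m" else "pfwd_m"
      expect_lt(max(abs(fit$fitted$predicted - v[[col]][v$day_index > 0])), 0.1)
    }
  }
})

test_that("cohort configs round-trip through JSON and YAML files", {
  dir <- withr::local_tempdir()
  p_json <- file.path(dir, "cfg.json")
  jsonlite::write_json(
    list(n_subjects = 7, seed = 3, noise_sd = 10,
         params_pfwd = list(k1 = c(0.03, 0.06), k2 = c(0.03, 0.06),
                            tau1 = c(45, 13), tau2 = c(25, 10))),
    p_json, auto_unbox = TRUE, digits = NA
  )
  cfg <- read_cohort_config(p_json)
  expect_s3_class(cfg, "cohort_config")
  expect_equal(cfg$n_subjects, 7)
  expect_equal(cfg$noise_sd, 10)
  expect_equal(cfg$adherence, 0.92) # untouched default
  expect_identical(generate_cohort(cfg)$visits,
                   generate_cohort(cfg)$visits)
  skip_if_not_installed("yaml")
  p_yaml <- file.path(dir, "cfg.yaml")
  writeLines(c("n_subjects: 7", "seed: 3", "noise_sd: 10"), p_yaml)
  cfg_y <- read_cohort_config(p_yaml)
  expect_equal(cfg_y$n_subjects, cfg$n_subjects)
  expect_equal(cfg_y$noise_sd, cfg$noise_sd)
  expect_error(read_cohort_config(file.path(dir, "cfg.txt")), "unsupported")
  jsonlite::write_json(list(bogus = 1), p_json, auto_unbox = TRUE)
  expect_error(read_cohort_config(p_json), "unknown config")
})

test_that("cohorts export and re-import through the CSV dialects unchanged", {
  cfg <- cohort_config(n_subjects = 3, seed = 8)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  base <- read_baseline(paths[1])
  diary <- read_diary(paths[2])
  visits <- read_visits(paths[3])
  expect_equal(nrow(base), 3)
  expect_equal(nrow(diary), nrow(co$diary))
  expect_equal(visits$pfwd_m, co$visits$pfwd_m)
  expect_equal(diary$performed_fraction, co$diary$performed_fraction)
})
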