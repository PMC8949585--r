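#' Configuration of a synthetic TiTo rehabilitation cohort
#'
#' Describes the study conditions the generator emulates: a 6-month (27-week)
#' home-based test-in train-out (TiTo) walking programme of two daily 10-min
#' sessions of intermittent walking (ten 1-min bouts at a metronome-paced
#' cadence separated by 1-min rests), with the prescribed cadence starting
#' near 60\% of the subject's habitual cadence and rising 3\% per week to a
#' per-subject cap in 90-100\%; clinic visits at weeks 0, 5, 12, 20 and 28
#' (with jitter); ~92\% session adherence; and per-subject impulse-response
#' parameters and baseline walking distances drawn from truncated normal
#' distributions matching a peripheral-artery-disease rehabilitation
#' population (PFWD 114 +/- 61 m, 6MWD 287 +/- 85 m; PFWD parameters
#' k1 0.03 +/- 0.06, k2 0.03 +/- 0.06, tau1 45 +/- 13 d, tau2 25 +/- 10 d;
#' 6MWD parameters k1 0.02 +/- 0.03, k2 0.03 +/- 0.03, tau1 37 +/- 11 d,
#' tau2 26 +/- 9 d).
#'
#' Only marginal means and SDs are available for the impulse-response
#' parameters, but drawing them independently produces subjects whose
#' modelled trajectories are physiologically impossible: pain-free distance
#' overtaking total distance, or performance collapsing to zero. The
#' generator therefore separates shape from magnitude. The decay constants
#' and the k1:k2 ratio are drawn from the configured truncated normals; the
#' common magnitude of `(k1, k2)` is then rescaled so the subject's modelled
#' end-of-follow-up gain equals a draw from the observed change distribution
#' (`gain_pfwd`, `gain_6mwd`), and the whole set is redrawn by rejection
#' until the trajectory over the study window (i) stays above `floor_frac`
#' of baseline and (ii) keeps PFWD at or below 6MWD on every day. This
#' conditions the joint parameter distribution on what the study actually
#' observed — performance changes of tens to ~120 metres — which marginal
#' parameter summaries alone cannot pin down.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; required for reproducible cohorts.
#' @param prop_male Proportion of male subjects (default 0.75).
#' @param six_mwd_mean,six_mwd_sd Baseline 6MWD distribution, metres.
#' @param pfwd_frac_mean,pfwd_frac_sd Baseline PFWD drawn as this fraction of
#'   6MWD (truncated to \[0.05, 0.95\]), which keeps PFWD <= 6MWD by
#'   construction.
#' @param habitual_speed_mean,habitual_speed_sd,habitual_speed_min Habitual
#'   cadence distribution, steps/min (normal truncated below at
#'   `habitual_speed_min`).
#' @param params_pfwd,params_6mwd Named lists of `c(mean, sd)` for `k1`,
#'   `k2`, `tau1`, `tau2`; draws are truncated normals (k >= 0, tau inside
#'   `tau1_range`/`tau2_range`), redrawn until the subject's trajectories
#'   satisfy the physiological constraints (see Details).
#' @param tau1_range,tau2_range Admissible decay-constant ranges, days; the
#'   same parameter space the calibration searches.
#' @param floor_frac Trajectories must stay above this fraction of the
#'   subject's baseline (default 0.10): walking performance may deteriorate
#'   under fatigue but does not collapse to zero in a cohort that completes
#'   the programme.
#' @param gain_pfwd,gain_6mwd `c(mean, sd)` of the modelled end-of-follow-up
#'   gain, metres. Defaults +121 +/- 70 m (PFWD) and +33 +/- 50 m (6MWD):
#'   the cohort mean changes reported for the TiTo programme, with
#'   change-score SDs consistent with the printed visit SDs under a typical
#'   test-retest correlation. Each subject's magnitude factors are rescaled
#'   by a common factor so the modelled gain hits a draw from this
#'   distribution (see Details).
#' @param max_redraws Cap on rejection-sampling redraws per parameter set.
#' @param noise_sd Gaussian measurement noise SD at visits, metres.
#' @param adherence Probability that a scheduled session is performed.
#' @param program_weeks Training programme length, weeks.
#' @param visit_weeks,visit_jitter_weeks Scheduled visit weeks and the
#'   half-width (weeks) of the uniform jitter on each; the baseline visit is
#'   never jittered.
#' @param speed_start_frac,speed_incr_frac Starting fraction of habitual
#'   cadence and its weekly increment.
#' @param speed_cap_range Range of the per-subject cadence cap (fraction of
#'   habitual cadence).
#' @param walk_min,rest_min,repetitions,sessions_per_day Session structure.
#' @param start_date Calendar date of day 0.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 100,
                          seed = NULL,
                          prop_male = 0.75,
                          six_mwd_mean = 287, six_mwd_sd = 85,
                          pfwd_frac_mean = 0.40, pfwd_frac_sd = 0.15,
                          habitual_speed_mean = 95, habitual_speed_sd = 15,
                          habitual_speed_min = 40,
                          params_pfwd = list(
                            k1 = c(0.03, 0.06), k2 = c(0.03, 0.06),
                            tau1 = c(45, 13), tau2 = c(25, 10)
                          ),
                          params_6mwd = list(
                            k1 = c(0.02, 0.03), k2 = c(0.03, 0.03),
                            tau1 = c(37, 11), tau2 = c(26, 9)
                          ),
                          tau1_range = c(10, 80),
                          tau2_range = c(5, 60),
                          floor_frac = 0.10,
                          gain_pfwd = c(121, 70),
                          gain_6mwd = c(33, 50),
                          max_redraws = 5000,
                          noise_sd = 15,
                          adherence = 0.92,
                          program_weeks = 27,
                          visit_weeks = c(0, 5, 12, 20, 28),
                          visit_jitter_weeks = c(0, 1, 2, 2, 3),
                          speed_start_frac = 0.60,
                          speed_incr_frac = 0.03,
                          speed_cap_range = c(0.90, 1.00),
                          walk_min = 1, rest_min = 1, repetitions = 10,
                          sessions_per_day = 2,
                          start_date = as.Date("2018-01-01")) {
  stopifnot(
    n_subjects >= 1,
    prop_male >= 0, prop_male <= 1,
    six_mwd_sd >= 0, pfwd_frac_sd >= 0, habitual_speed_sd >= 0,
    noise_sd >= 0,
    adherence >= 0, adherence <= 1,
    program_weeks >= 1,
    length(visit_weeks) == length(visit_jitter_weeks),
    speed_cap_range[1] <= speed_cap_range[2]
  )
  structure(
    as.list(environment()),
    class = "cohort_config"
  )
}

# Truncated-normal draws by rejection; the acceptance regions used here are
# wide, so the loop terminates quickly.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

# Mean of a normal(mean, sd) truncated to [lower, upper]; the analytic
# counterpart of rtrunc_norm, used to state what the generator converges to.
trunc_norm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(pmin(pmax(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

#' TiTo training prescriptions for one subject
#'
#' Builds the session-by-session diary of the progressive TiTo programme: two
#' daily sessions of `repetitions` walk bouts (1:1 walk:rest), with the
#' prescribed cadence in week `w` equal to
#' `habitual * min(speed_start_frac + speed_incr_frac * (w - 1), cap)`,
#' rounded to a whole steps/min value. All sessions are generated as fully
#' performed (`performed_fraction = 1`); adherence is applied by the cohort
#' generator.
#'
#' @param habitual_speed Habitual cadence, steps/min (> 0).
#' @param config A [cohort_config()].
#' @param cap Cadence cap as a fraction of habitual cadence; default the
#'   midpoint of `config$speed_cap_range`.
#' @return Diary tibble: `date`, `day` (0-based), `week` (1-based),
#'   `session` (within-day index), `cadence_spm`, `walk_min`, `rest_min`,
#'   `repetitions`, `performed_fraction`.
#' @examples
#' cfg <- cohort_config(n_subjects = 1)
#' d <- generate_prescriptions(100, cfg)
#' d$cadence_spm[1] # week 1: 60% of habitual -> 60 steps/min
#' @export
generate_prescriptions <- function(habitual_speed, config = cohort_config(),
                                   cap = mean(config$speed_cap_range)) {
  stopifnot(habitual_speed > 0)
  n_days <- config$program_weeks * 7L
  day <- rep(0:(n_days - 1), each = config$sessions_per_day)
  week <- day %/% 7L + 1L
  frac <- pmin(config$speed_start_frac + config$speed_incr_frac * (week - 1), cap)
  tibble::tibble(
    date = config$start_date + day,
    day = day,
    week = week,
    session = rep(seq_len(config$sessions_per_day), times = n_days),
    cadence_spm = round(habitual_speed * frac),
    walk_min = config$walk_min,
    rest_min = config$rest_min,
    repetitions = config$repetitions,
    performed_fraction = 1
  )
}

#' Generate a synthetic TiTo cohort
#'
#' Draws subjects (sex, habitual cadence, baseline distances, true
#' impulse-response parameters), builds each subject's TiTo diary with
#' sessions independently skipped with probability `1 - adherence`, and
#' produces noisy visit measurements by evaluating the true model on the
#' subject's own TRIMP series at jittered visit days and adding Gaussian
#' noise (clipped at 0 m; PFWD clipped to 6MWD).
#'
#' The same diary-derived TRIMP series drives both the PFWD and the 6MWD
#' model; only the parameters differ.
#'
#' @param config A [cohort_config()]; `config$seed`, when set, makes the
#'   cohort fully reproducible.
#' @return A `tito_cohort` list of tibbles: `subjects` (subject_id, sex,
#'   habitual_speed_spm, pfwd_m, six_mwd_m, speed_cap), `true_params`
#'   (subject_id, outcome, p0, k1, k2, tau1, tau2), `diary` (one row per
#'   scheduled session, `performed_fraction` 0 for skipped ones) and
#'   `visits` (subject_id, visit_label, day_index, pfwd_m, six_mwd_m),
#'   plus the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects

  n_male <- round(n * config$prop_male)
  sex <- sample(rep(c("M", "F"), times = c(n_male, n - n_male)))
  habitual <- round(rtrunc_norm(
    n, config$habitual_speed_mean, config$habitual_speed_sd,
    lower = config$habitual_speed_min
  ))
  six_mwd0 <- rtrunc_norm(n, config$six_mwd_mean, config$six_mwd_sd, lower = 30)
  pfwd_frac <- rtrunc_norm(n, config$pfwd_frac_mean, config$pfwd_frac_sd,
                           lower = 0.05, upper = 0.95)
  pfwd0 <- pfwd_frac * six_mwd0
  cap <- stats::runif(n, config$speed_cap_range[1], config$speed_cap_range[2])

  subject_id <- sprintf("S%03d", seq_len(n))
  subjects <- tibble::tibble(
    subject_id = subject_id, sex = sex,
    habitual_speed_spm = habitual,
    pfwd_m = pfwd0, six_mwd_m = six_mwd0,
    speed_cap = cap
  )

  draw_one <- function(spec) {
    list(
      k1 = rtrunc_norm(1, spec$k1[1], spec$k1[2], lower = 0),
      k2 = rtrunc_norm(1, spec$k2[1], spec$k2[2], lower = 0),
      tau1 = rtrunc_norm(1, spec$tau1[1], spec$tau1[2],
                         config$tau1_range[1], config$tau1_range[2]),
      tau2 = rtrunc_norm(1, spec$tau2[1], spec$tau2[2],
                         config$tau2_range[1], config$tau2_range[2])
    )
  }
  # Shape-then-magnitude rejection draw: take a (k1, k2, tau1, tau2) shape
  # draw, rescale (k1, k2) by a common factor so the modelled gain at
  # `end_day` equals a target-gain draw, and accept when the scaled
  # trajectory satisfies the constraints. On exhaustion keep the attempt
  # with the smallest constraint violation and warn.
  draw_constrained <- function(spec, p0, gain_dist, gain_of, end_day,
                               accept, violation) {
    best <- NULL; best_v <- Inf
    for (i in seq_len(config$max_redraws)) {
      par <- draw_one(spec)
      g <- gain_of(par) # unscaled gain curve over the study window
      g_end <- g[end_day + 1]
      target <- stats::rnorm(1, gain_dist[1], gain_dist[2])
      if (abs(g_end) < 1 || sign(g_end) != sign(target)) next
      c_scale <- target / g_end
      par$k1 <- par$k1 * c_scale
      par$k2 <- par$k2 * c_scale
      traj <- p0 + c_scale * g
      if (accept(traj)) return(list(par = par, traj = traj))
      v <- violation(traj)
      if (v < best_v) { best <- list(par = par, traj = traj); best_v <- v }
    }
    warning("constraint rejection exhausted after ", config$max_redraws,
            " draws; using least-violating parameter set", call. = FALSE)
    best
  }

  jitter_days <- function() {
    j <- round(stats::runif(
      length(config$visit_weeks),
      -config$visit_jitter_weeks * 7, config$visit_jitter_weeks * 7
    ))
    pmax(config$visit_weeks * 7 + j, 0)
  }

  diaries <- vector("list", n)
  visit_rows <- vector("list", n)
  param_rows <- vector("list", n)
  for (s in seq_len(n)) {
    diary <- generate_prescriptions(habitual[s], config, cap = cap[s])
    skipped <- stats::runif(nrow(diary)) > config$adherence
    diary$performed_fraction[skipped] <- 0
    diary$subject_id <- subject_id[s]
    diaries[[s]] <- diary

    w <- trimp_series(diary, habitual_speed = habitual[s],
                      start_date = config$start_date,
                      end_date = config$start_date + config$program_weeks * 7L - 1L)
    vdays <- jitter_days()
    vdays[config$visit_weeks == 0] <- 0 # baseline visit is never jittered
    vdays <- sort(vdays)
    while (anyDuplicated(vdays)) { # only reachable for overlapping custom schedules
      vdays[duplicated(vdays)] <- vdays[duplicated(vdays)] + 1
      vdays <- sort(vdays)
    }
    horizon <- max(vdays, config$program_weeks * 7L)
    end_day <- max(vdays)
    gain_of <- function(par) {
      par$k1 * convolve_trimp(w$trimp, par$tau1, horizon) -
        par$k2 * convolve_trimp(w$trimp, par$tau2, horizon)
    }

    floor6 <- config$floor_frac * six_mwd0[s]
    six <- draw_constrained(
      config$params_6mwd, six_mwd0[s], config$gain_6mwd, gain_of, end_day,
      accept = function(tr) min(tr) >= floor6,
      violation = function(tr) floor6 - min(tr)
    )
    floorp <- config$floor_frac * pfwd0[s]
    pfw <- draw_constrained(
      config$params_pfwd, pfwd0[s], config$gain_pfwd, gain_of, end_day,
      accept = function(tr) min(tr) >= floorp && all(tr <= six$traj),
      violation = function(tr) max(floorp - min(tr), max(tr - six$traj))
    )

    param_rows[[s]] <- dplyr::bind_rows(
      tibble::tibble(subject_id = subject_id[s], outcome = "pfwd",
                     p0 = pfwd0[s], !!!pfw$par),
      tibble::tibble(subject_id = subject_id[s], outcome = "6mwd",
                     p0 = six_mwd0[s], !!!six$par)
    )

    at_visits <- function(tr) tr[vdays + 1] # trajectory day 0 is element 1
    pfwd_meas <- pmax(at_visits(pfw$traj) + stats::rnorm(length(vdays), 0, config$noise_sd), 0)
    six_meas <- pmax(at_visits(six$traj) + stats::rnorm(length(vdays), 0, config$noise_sd), 0)
    pfwd_meas <- pmin(pfwd_meas, six_meas) # noise safeguard; inactive when noise_sd = 0
    visit_rows[[s]] <- tibble::tibble(
      subject_id = subject_id[s],
      visit_label = paste0("T", seq_along(vdays) - 1),
      day_index = vdays,
      pfwd_m = pfwd_meas,
      six_mwd_m = six_meas
    )
  }

  structure(
    list(
      subjects = subjects,
      true_params = dplyr::bind_rows(param_rows),
      diary = dplyr::bind_rows(diaries),
      visits = dplyr::bind_rows(visit_rows),
      config = config
    ),
    class = "tito_cohort"
  )
}

#' @export
print.tito_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic TiTo cohort: %d subjects, %d scheduled sessions, %d visit records\n",
    nrow(x$subjects), nrow(x$diary), nrow(x$visits)
  ))
  invisible(x)
}

#' Read a cohort configuration from a JSON or YAML file
#'
#' Fields mirror the arguments of [cohort_config()]; missing fields keep
#' their defaults. The file extension selects the parser (`.json`, or
#' `.yaml`/`.yml` when the yaml package is installed).
#'
#' @param path Path to the configuration file.
#' @return A `cohort_config` list.
#' @export
read_cohort_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fields <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(fields$start_date)) fields$start_date <- as.Date(fields$start_date)
  for (f in c("params_pfwd", "params_6mwd")) {
    if (!is.null(fields[[f]])) fields[[f]] <- lapply(fields[[f]], as.numeric)
  }
  do.call(cohort_config, fields)
}

#' Write a cohort to the CSV dialects the pipeline readers consume
#'
#' Emits `baseline.csv` (subject_id, habitual_speed_spm, pfwd_m, six_mwd_m,
#' sex), `diary.csv` (subject_id, date, cadence_spm, walk_min, rest_min,
#' repetitions, performed_fraction) and `visits.csv` (subject_id,
#' visit_label, day_index, pfwd_m, six_mwd_m), so the generator is a drop-in
#' replacement for real study exports.
#'
#' @param cohort A `tito_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tito_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("baseline.csv", "diary.csv", "visits.csv"))
  readr::write_csv(
    dplyr::select(
      cohort$subjects,
      "subject_id", "habitual_speed_spm", "pfwd_m", "six_mwd_m", "sex"
    ),
    paths[1]
  )
  readr::write_csv(
    dplyr::select(
      cohort$diary,
      "subject_id", "date", "cadence_spm", "walk_min", "rest_min",
      "repetitions", "performed_fraction"
    ),
    paths[2]
  )
  readr::write_csv(cohort$visits, paths[3])
  invisible(paths)
}
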