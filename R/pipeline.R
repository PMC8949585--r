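#' Read a training diary CSV
#'
#' Expected columns: `subject_id` (optional for single-subject files), `date`
#' (ISO 8601), `cadence_spm`, `walk_min`, `rest_min`, `repetitions`,
#' `performed_fraction`. One row per session.
#'
#' @param path CSV file path.
#' @return Validated diary tibble.
#' @export
read_diary <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("date", "cadence_spm", "walk_min", "rest_min", "repetitions")
  validate_columns(d, required, path)
  d$date <- as.Date(d$date)
  if (!"performed_fraction" %in% names(d)) d$performed_fraction <- 1
  bad <- which(is.na(d$date) | is.na(d$cadence_spm) | d$cadence_spm <= 0 |
                 d$walk_min <= 0 | d$rest_min < 0 | d$repetitions < 1 |
                 d$performed_fraction < 0 | d$performed_fraction > 1)
  if (length(bad) > 0) {
    stop("malformed diary rows in ", path, ": ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d
}

#' Read a subject baseline CSV
#'
#' Expected columns: `subject_id`, `habitual_speed_spm`, `pfwd_m`,
#' `six_mwd_m`, optionally `sex`.
#'
#' @param path CSV file path.
#' @return Validated baseline tibble.
#' @export
read_baseline <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  validate_columns(d, c("subject_id", "habitual_speed_spm", "pfwd_m", "six_mwd_m"), path)
  bad <- which(is.na(d$habitual_speed_spm) | d$habitual_speed_spm <= 0 |
                 d$pfwd_m < 0 | d$pfwd_m > d$six_mwd_m)
  if (length(bad) > 0) {
    stop("malformed baseline rows in ", path, ": ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d
}

#' Read a visit-measurement CSV
#'
#' Expected columns: `subject_id`, `visit_label` (T0, T1, ...), `day_index`
#' (days since programme start), `pfwd_m`, `six_mwd_m`.
#'
#' @param path CSV file path.
#' @return Validated visits tibble.
#' @export
read_visits <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  validate_columns(d, c("subject_id", "visit_label", "day_index", "pfwd_m", "six_mwd_m"), path)
  bad <- which(is.na(d$day_index) | d$day_index < 0 |
                 (!is.na(d$pfwd_m) & d$pfwd_m < 0) |
                 (!is.na(d$six_mwd_m) & d$six_mwd_m < 0))
  if (length(bad) > 0) {
    stop("malformed visit rows in ", path, ": ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d
}

validate_columns <- function(d, required, path) {
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(d)
}

#' Run the full diary -> TRIMP -> fit -> agreement pipeline
#'
#' Orchestrates the analysis end to end: per-subject TRIMP series from the
#' diary, Banister calibration against the visit measurements for each
#' outcome, cohort parameter summary, a visit-level actual-vs-estimated
#' table, and pooled method-agreement statistics. Subjects without a baseline
#' (day 0) visit are skipped with a warning.
#'
#' @param diary,baseline,visits Data frames or CSV paths in the dialects of
#'   [read_diary()], [read_baseline()] and [read_visits()]. Ignored when
#'   `config` is given.
#' @param config Optional [cohort_config()]: generate a synthetic cohort
#'   instead of reading files. Exactly one data source must be supplied, and
#'   a synthetic run requires `config$seed`.
#' @param outcomes Outcomes to fit: subset of `c("pfwd", "6mwd")`.
#' @param control [banister_control()] fit settings.
#' @param exclude_unacceptable Drop fits with R^2 at or below the
#'   acceptability threshold from the agreement statistics (default FALSE:
#'   all measured/estimated pairs are pooled).
#' @param output_dir Optional directory; when given, writes `fits.csv`,
#'   `cohort_summary.csv`, `visit_table.csv`, `agreement.csv`,
#'   `trajectories.csv` and a `manifest.json` (run configuration hash, seed,
#'   package version).
#' @return A `tito_pipeline` list: `fits` (per subject x outcome parameter
#'   and fit-statistic table), `estimates` (per visit measured and predicted
#'   values), `summary` ([cohort_summary()] by outcome), `visit_table`
#'   (actual vs estimated mean +/- SD per visit label), `agreement` (one row
#'   per outcome), `trajectories` (per-day predicted trajectories), and
#'   `skipped` (subject ids not fitted, with reasons).
#' @export
run_pipeline <- function(diary = NULL, baseline = NULL, visits = NULL,
                         config = NULL,
                         outcomes = c("pfwd", "6mwd"),
                         control = banister_control(),
                         exclude_unacceptable = FALSE,
                         output_dir = NULL) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  from_files <- !is.null(diary) || !is.null(baseline) || !is.null(visits)
  if (is.null(config) == !from_files) {
    stop("supply exactly one data source: diary/baseline/visits or a synthetic `config`",
         call. = FALSE)
  }
  if (!is.null(config)) {
    if (is.null(config$seed)) stop("synthetic runs require `config$seed`", call. = FALSE)
    cohort <- generate_cohort(config)
    diary <- cohort$diary
    baseline <- cohort$subjects
    visits <- cohort$visits
  } else {
    if (is.character(diary)) diary <- read_diary(diary)
    if (is.character(baseline)) baseline <- read_baseline(baseline)
    if (is.character(visits)) visits <- read_visits(visits)
    diary <- tibble::as_tibble(diary)
    baseline <- tibble::as_tibble(baseline)
    visits <- tibble::as_tibble(visits)
  }
  if (!"subject_id" %in% names(diary) && nrow(baseline) == 1) {
    diary$subject_id <- baseline$subject_id[1]
  }
  if (nrow(visits) == 0) stop("no visit records: zero subjects to process", call. = FALSE)

  fit_rows <- list(); est_rows <- list(); traj_rows <- list(); skipped <- list()
  for (sid in baseline$subject_id) {
    b <- baseline[baseline$subject_id == sid, ]
    sdiary <- diary[diary$subject_id == sid, ]
    svisits <- visits[visits$subject_id == sid, ]
    if (nrow(sdiary) == 0 || nrow(svisits) == 0) {
      skipped[[sid]] <- tibble::tibble(subject_id = sid, reason = "no diary or visits")
      next
    }
    if (!any(svisits$day_index == 0)) {
      warning("subject ", sid, " has no baseline (day 0) visit; skipped", call. = FALSE)
      skipped[[sid]] <- tibble::tibble(subject_id = sid, reason = "missing baseline visit")
      next
    }
    w <- trimp_series(sdiary, habitual_speed = b$habitual_speed_spm)
    horizon <- max(max(svisits$day_index), nrow(w))
    for (oc in outcomes) {
      fit <- tryCatch(
        fit_banister(w, svisits, outcome = oc, control = control),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        skipped[[paste(sid, oc)]] <- tibble::tibble(
          subject_id = sid, reason = paste0(oc, ": ", conditionMessage(fit))
        )
        next
      }
      fit_rows[[paste(sid, oc)]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = sid, outcome = oc),
        if ("sex" %in% names(b)) tibble::tibble(sex = b$sex) else NULL,
        tibble::as_tibble(unclass(fit$params)),
        tibble::tibble(
          rss = fit$rss, r_squared = fit$r_squared,
          f_statistic = fit$f_statistic, f_pvalue = fit$f_pvalue,
          acceptable = fit$acceptable, n_obs = fit$n_obs
        )
      )
      traj <- predict_performance(fit$params, w, horizon = horizon)
      traj_rows[[paste(sid, oc)]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = sid, outcome = oc), traj
      )
      col <- if (oc == "6mwd") "six_mwd_m" else "pfwd_m"
      est_rows[[paste(sid, oc)]] <- tibble::tibble(
        subject_id = sid, outcome = oc,
        visit_label = svisits$visit_label,
        day_index = svisits$day_index,
        measured = svisits[[col]],
        estimated = traj$predicted[match(svisits$day_index, traj$day)],
        acceptable = fit$acceptable
      )
    }
  }
  fits <- dplyr::bind_rows(fit_rows)
  if (nrow(fits) == 0) stop("no subject could be fitted", call. = FALSE)
  estimates <- dplyr::bind_rows(est_rows)

  agree_input <- estimates[estimates$day_index > 0, ]
  if (exclude_unacceptable) agree_input <- agree_input[agree_input$acceptable, ]
  agreement <- agree_input |>
    dplyr::group_by(.data$outcome) |>
    dplyr::group_modify(~ agreement_stats(.x, measured, estimated)) |>
    dplyr::ungroup()

  visit_table <- estimates |>
    tidyr::pivot_longer(c("measured", "estimated"),
                        names_to = "series", values_to = "value") |>
    dplyr::mutate(series = ifelse(.data$series == "measured", "actual", "estimated")) |>
    dplyr::filter(!(.data$series == "estimated" & .data$day_index == 0)) |>
    dplyr::group_by(.data$outcome, .data$series, visit = .data$visit_label) |>
    dplyr::summarise(
      mean_m = mean(.data$value), sd_m = stats::sd(.data$value),
      n = dplyr::n(), .groups = "drop"
    )

  res <- structure(
    list(
      fits = fits,
      estimates = estimates,
      summary = cohort_summary(fits, by = "outcome"),
      visit_table = visit_table,
      agreement = agreement,
      trajectories = dplyr::bind_rows(traj_rows),
      skipped = dplyr::bind_rows(skipped),
      control = control,
      config = config
    ),
    class = "tito_pipeline"
  )
  if (!is.null(output_dir)) write_pipeline_outputs(res, output_dir)
  res
}

write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$fits, file.path(output_dir, "fits.csv"))
  readr::write_csv(res$summary, file.path(output_dir, "cohort_summary.csv"))
  readr::write_csv(res$visit_table, file.path(output_dir, "visit_table.csv"))
  readr::write_csv(res$agreement, file.path(output_dir, "agreement.csv"))
  readr::write_csv(res$trajectories, file.path(output_dir, "trajectories.csv"))
  manifest <- list(
    package = "fitfatigue",
    version = as.character(utils::packageVersion("fitfatigue")),
    seed = if (!is.null(res$config)) res$config$seed else NULL,
    config_hash = rlang::hash(res$config),
    control = unclass(res$control),
    n_fits = nrow(res$fits)
  ) # no timestamp: reruns must be byte-identical given the same config
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.tito_pipeline <- function(x, ...) {
  cat(sprintf(
    "TiTo pipeline run: %d fits (%d subjects), %d skipped\n",
    nrow(x$fits), length(unique(x$fits$subject_id)), nrow(x$skipped)
  ))
  print(x$agreement)
  invisible(x)
}

#' Compare fitted parameters between two subgroups
#'
#' Per-parameter group means +/- SD and Welch two-sample t-tests, e.g. men
#' vs women.
#'
#' @param params_df Per-subject parameter table (e.g. `fits` from
#'   [run_pipeline()], filtered to one outcome).
#' @param group Name of the grouping column; it must have exactly two levels,
#'   each with at least 2 observations.
#' @param parameters Parameter columns to compare.
#' @return Tibble: `parameter`, `group1`, `mean1`, `sd1`, `n1`, `group2`,
#'   `mean2`, `sd2`, `n2`, `statistic`, `p.value`.
#' @export
compare_subgroups <- function(params_df, group = "sex",
                              parameters = c("k1", "k2", "tau1", "tau2")) {
  params_df <- tibble::as_tibble(params_df)
  g <- params_df[[group]]
  levels <- sort(unique(g))
  if (length(levels) != 2) {
    stop("`", group, "` must have exactly 2 levels, found ", length(levels),
         call. = FALSE)
  }
  if (any(table(g) < 2)) {
    stop("each subgroup needs at least 2 fits", call. = FALSE)
  }
  purrr::map_dfr(parameters, function(p) {
    v1 <- params_df[[p]][g == levels[1]]
    v2 <- params_df[[p]][g == levels[2]]
    tt <- stats::t.test(v1, v2) # Welch
    tibble::tibble(
      parameter = p,
      group1 = levels[1], mean1 = mean(v1), sd1 = stats::sd(v1), n1 = length(v1),
      group2 = levels[2], mean2 = mean(v2), sd2 = stats::sd(v2), n2 = length(v2),
      statistic = unname(tt$statistic), p.value = tt$p.value
    )
  })
}

#' Change in cohort mean performance between two visits
#'
#' Computes `to - from` deltas of the cohort mean walking distances from a
#' visit-level summary table (the `visit_table` of [run_pipeline()], or the
#' packaged reference table: see [reference_visit_means()]).
#'
#' @param visit_means Tibble with columns `outcome`, `series`
#'   (actual/estimated), `visit` and `mean_m`.
#' @param from,to Visit labels; `to` defaults to the last visit present.
#' @return Tibble: `outcome`, `series`, `from`, `to`, `delta_m`.
#' @examples
#' performance_deltas(reference_visit_means())
#' @export
performance_deltas <- function(visit_means, from = "T0", to = NULL) {
  visit_means <- tibble::as_tibble(visit_means)
  if (is.null(to)) to <- max(visit_means$visit)
  visit_means |>
    dplyr::group_by(.data$outcome, .data$series) |>
    dplyr::filter(all(c(from, to) %in% .data$visit)) |>
    dplyr::summarise(
      from = from, to = to,
      delta_m = .data$mean_m[.data$visit == to] - .data$mean_m[.data$visit == from],
      .groups = "drop"
    )
}

#' Published cohort mean walking performance at the five visits
#'
#' Visit-level mean +/- SD of actual and model-estimated PFWD and 6MWD
#' (metres) reported for a 100-patient PAD cohort completing the 6-month
#' TiTo programme, shipped as a reference table for report checks: the
#' actual-series T4 - T0 deltas are +121 m (PFWD) and +33 m (6MWD).
#'
#' @return Tibble: `outcome` (pfwd/six_mwd), `series` (actual/estimated),
#'   `visit` (T0-T4), `mean_m`, `sd_m`.
#' @export
reference_visit_means <- function() {
  path <- system.file("extdata", "cohort_visit_means.csv", package = "fitfatigue")
  readr::read_csv(path, show_col_types = FALSE)
}
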