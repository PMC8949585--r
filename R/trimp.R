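#' Training intensity of a walking session
#'
#' Intensity is the ratio between the prescribed training cadence and the
#' subject's habitual walking cadence, both in steps/min. A session walked at
#' 60 steps/min by a subject whose habitual cadence is 100 steps/min has
#' intensity 0.60.
#'
#' @param cadence Prescribed training cadence, steps/min. Must be positive.
#' @param habitual_speed Habitual walking cadence from the baseline 6-min walk
#'   test (steps counted over its first minute), steps/min. Must be positive.
#' @return Dimensionless intensity ratio, vectorised over its arguments.
#' @examples
#' trimp_intensity(60, 100) # 0.60
#' @export
trimp_intensity <- function(cadence, habitual_speed) {
  if (any(!is.finite(habitual_speed)) || any(habitual_speed <= 0)) {
    stop("invalid baseline: `habitual_speed` must be a positive number", call. = FALSE)
  }
  if (any(!is.finite(cadence)) || any(cadence <= 0)) {
    stop("`cadence` must be a positive number", call. = FALSE)
  }
  cadence / habitual_speed
}

#' Training density of a walking session
#'
#' Density is walking time divided by total elapsed session time. A session of
#' `repetitions` walk bouts separated by rest bouts has `repetitions - 1`
#' rests: the session ends with the last walk, so no trailing rest is counted.
#' Ten 1-min walks with 1-min rests therefore elapse 19 min and have density
#' 10/19.
#'
#' @param walk_min Minutes per walk bout (> 0).
#' @param rest_min Minutes per rest bout between walks (>= 0).
#' @param repetitions Number of walk bouts (>= 1).
#' @return Dimensionless density in (0, 1], vectorised.
#' @examples
#' trimp_density(1, 1, 10) # 10/19
#' @export
trimp_density <- function(walk_min, rest_min, repetitions) {
  check_session(walk_min, rest_min, repetitions)
  walk_total <- walk_min * repetitions
  walk_total / (walk_total + rest_min * (repetitions - 1))
}

#' Training volume of a walking session
#'
#' Volume is the total number of steps performed: steps per bout (cadence
#' times bout duration) times the number of bouts actually completed. Partial
#' adherence enters as the fraction of prescribed repetitions performed.
#'
#' @inheritParams trimp_intensity
#' @inheritParams trimp_density
#' @param performed_fraction Fraction in \[0, 1\] of prescribed repetitions
#'   actually done (1 = fully performed, 0 = skipped).
#' @return Steps performed, vectorised.
#' @examples
#' trimp_volume(60, 1, 10) # 600 steps
#' @export
trimp_volume <- function(cadence, walk_min, repetitions, performed_fraction = 1) {
  check_session(walk_min, 0, repetitions)
  if (any(performed_fraction < 0 | performed_fraction > 1)) {
    stop("`performed_fraction` must lie in [0, 1]", call. = FALSE)
  }
  cadence * walk_min * repetitions * performed_fraction
}

#' Session TRIMP: intensity x density x volume
#'
#' The training impulse (TRIMP, arbitrary units) of one session is the product
#' of its intensity, density and volume. Two arithmetic modes are provided:
#'
#' * `"full"` (default): the product at full floating precision; this is what
#'   the modelling pipeline consumes.
#' * `"printed"`: intensity and density are rounded to two decimals before
#'   multiplying and the product is rounded to the nearest unit, reproducing
#'   the worked arithmetic conventionally shown in prescriptions
#'   (0.60 x 0.53 x 600 = 191 a.u. for the canonical example session, whose
#'   full-precision value is about 189.47).
#'
#' @inheritParams trimp_volume
#' @inheritParams trimp_intensity
#' @param mode `"full"` or `"printed"` (see Details).
#' @return TRIMP in arbitrary units, vectorised.
#' @examples
#' session_trimp(60, 100, 1, 1, 10)                   # ~189.47
#' session_trimp(60, 100, 1, 1, 10, mode = "printed") # 191
#' @export
session_trimp <- function(cadence, habitual_speed, walk_min, rest_min,
                          repetitions, performed_fraction = 1,
                          mode = c("full", "printed")) {
  mode <- match.arg(mode)
  intensity <- trimp_intensity(cadence, habitual_speed)
  density <- trimp_density(walk_min, rest_min, repetitions)
  volume <- trimp_volume(cadence, walk_min, repetitions, performed_fraction)
  if (mode == "printed") {
    round(round(intensity, 2) * round(density, 2) * volume)
  } else {
    intensity * density * volume
  }
}

check_session <- function(walk_min, rest_min, repetitions) {
  if (any(walk_min <= 0)) stop("`walk_min` must be positive", call. = FALSE)
  if (any(rest_min < 0)) stop("`rest_min` must be nonnegative", call. = FALSE)
  if (any(repetitions < 1)) stop("`repetitions` must be >= 1", call. = FALSE)
  invisible(NULL)
}

#' Add TRIMP components to a session diary
#'
#' Takes a diary data frame (one row per training session) and returns it with
#' `intensity`, `density`, `volume` and `trimp` columns appended.
#'
#' @param sessions Data frame with columns `cadence_spm`, `walk_min`,
#'   `rest_min`, `repetitions` and optionally `performed_fraction`
#'   (defaulting to 1 when absent).
#' @param habitual_speed Habitual walking cadence of the subject, steps/min.
#' @param mode Arithmetic mode passed to [session_trimp()].
#' @return The input as a tibble with the four TRIMP columns appended.
#' @examples
#' diary <- tibble::tibble(
#'   date = as.Date("2018-01-01"), cadence_spm = 60,
#'   walk_min = 1, rest_min = 1, repetitions = 10
#' )
#' compute_trimp(diary, habitual_speed = 100)
#' @export
compute_trimp <- function(sessions, habitual_speed, mode = c("full", "printed")) {
  mode <- match.arg(mode)
  sessions <- tibble::as_tibble(sessions)
  if (!"performed_fraction" %in% names(sessions)) {
    sessions$performed_fraction <- 1
  }
  dplyr::mutate(
    sessions,
    intensity = trimp_intensity(.data$cadence_spm, habitual_speed),
    density = trimp_density(.data$walk_min, .data$rest_min, .data$repetitions),
    volume = trimp_volume(
      .data$cadence_spm, .data$walk_min, .data$repetitions,
      .data$performed_fraction
    ),
    trimp = session_trimp(
      .data$cadence_spm, habitual_speed, .data$walk_min, .data$rest_min,
      .data$repetitions, .data$performed_fraction,
      mode = mode
    )
  )
}

#' Daily TRIMP series w(t) from a session diary
#'
#' Aggregates per-session TRIMPs to the daily training quantity w(t) that
#' drives the impulse-response model: the value on a calendar day is the sum
#' of the TRIMPs of all sessions on that day (two sessions per day under the
#' TiTo prescription), and days without sessions contribute 0.
#'
#' @param sessions Session diary with a `date` column (class `Date`) plus the
#'   columns required by [compute_trimp()]; alternatively a diary already
#'   carrying a `trimp` column, which is then used as-is.
#' @param habitual_speed Habitual cadence, steps/min; required unless
#'   `sessions` already has a `trimp` column.
#' @param start_date,end_date Span of the series; default to the diary's date
#'   range. All session dates must fall inside the span.
#' @return Tibble with one row per calendar day: `date`, `day` (0-based index
#'   from `start_date`) and `trimp` (>= 0).
#' @export
trimp_series <- function(sessions, habitual_speed = NULL,
                         start_date = NULL, end_date = NULL) {
  sessions <- tibble::as_tibble(sessions)
  if (!inherits(sessions$date, "Date")) {
    sessions$date <- as.Date(sessions$date)
  }
  if (!"trimp" %in% names(sessions)) {
    if (is.null(habitual_speed)) {
      stop("`habitual_speed` is required to compute session TRIMPs", call. = FALSE)
    }
    sessions <- compute_trimp(sessions, habitual_speed)
  }
  if (is.null(start_date)) start_date <- min(sessions$date)
  if (is.null(end_date)) end_date <- max(sessions$date)
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (nrow(sessions) > 0 &&
      (min(sessions$date) < start_date || max(sessions$date) > end_date)) {
    stop("session dates fall outside [start_date, end_date]", call. = FALSE)
  }
  days <- tibble::tibble(date = seq(start_date, end_date, by = "day"))
  daily <- sessions |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(trimp = sum(.data$trimp), .groups = "drop")
  days |>
    dplyr::left_join(daily, by = "date") |>
    dplyr::mutate(
      trimp = dplyr::coalesce(.data$trimp, 0),
      day = as.integer(.data$date - start_date),
      .before = 1
    ) |>
    dplyr::select("date", "day", "trimp")
}
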