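#' Build a table of tic observation sessions
#'
#' A session is one fixed-duration observation window for one subject, visit,
#' condition and rater, carrying the onset times (seconds) of every tic the
#' rater annotated. Sessions are stored one per row, with onset times in the
#' `events` list-column, so the table pipes directly into
#' [estimate_df_sessions()] and the group-level statistics.
#'
#' @param subject_id character, subject identifiers.
#' @param visit character, `"screening"` or `"twelve_month"`.
#' @param condition character, one of `"baseline"`, `"verbal"`, `"DRO"`,
#'   `"NCR"`.
#' @param rater_id character, rater identifiers.
#' @param duration_s positive numeric, session length in seconds (default 300,
#'   the 5-minute video session).
#' @param events list of numeric vectors, tic onset times in seconds. Each
#'   time must satisfy `0 <= t < duration_s` (half-open window); times are
#'   sorted on construction.
#'
#' @return A tibble with one row per session and columns `subject_id`,
#'   `visit`, `condition`, `rater_id`, `duration_s`, `n_tics`, `events`.
#' @export
#' @examples
#' tic_sessions("s1", "screening", "baseline", "r1", 300, list(c(4.2, 1.0)))
tic_sessions <- function(subject_id, visit, condition, rater_id,
                         duration_s = 300, events = list(numeric(0))) {
  tbl <- tibble(
    subject_id = as.character(subject_id),
    visit = as.character(visit),
    condition = as.character(condition),
    rater_id = as.character(rater_id),
    duration_s = as.numeric(duration_s),
    events = lapply(events, function(e) sort(as.numeric(e)))
  )
  validate_sessions(tbl)
  tbl$n_tics <- vapply(tbl$events, length, integer(1))
  tbl[, c("subject_id", "visit", "condition", "rater_id", "duration_s",
          "n_tics", "events")]
}

validate_sessions <- function(tbl) {
  bad_visit <- !tbl$visit %in% VISIT_LEVELS
  if (any(bad_visit)) {
    abort(sprintf("unknown visit label(s): %s",
                  paste(unique(tbl$visit[bad_visit]), collapse = ", ")))
  }
  bad_cond <- !tbl$condition %in% CONDITION_LEVELS
  if (any(bad_cond)) {
    abort(sprintf("unknown condition label(s): %s",
                  paste(unique(tbl$condition[bad_cond]), collapse = ", ")))
  }
  if (any(!is.finite(tbl$duration_s)) || any(tbl$duration_s <= 0)) {
    abort("duration_s must be positive and finite")
  }
  for (i in seq_len(nrow(tbl))) {
    ev <- tbl$events[[i]]
    if (length(ev) && (any(!is.finite(ev)) || any(ev < 0) ||
                       any(ev >= tbl$duration_s[i]))) {
      abort(sprintf(
        "session %d (%s/%s/%s/%s): event times must lie in [0, %g) seconds",
        i, tbl$subject_id[i], tbl$visit[i], tbl$condition[i], tbl$rater_id[i],
        tbl$duration_s[i]))
    }
  }
  invisible(tbl)
}

#' Read tic sessions from a long-format CSV
#'
#' Expects one row per tic with columns `subject_id`, `visit`, `condition`,
#' `rater_id`, `duration_s`, `tic_time_s`. A session with no tics appears as
#' a single row with `tic_time_s` empty. Rows are grouped into sessions by
#' the four identifier columns plus duration, and onset times are sorted.
#'
#' @param path path to a CSV file.
#' @return A sessions tibble, as from [tic_sessions()].
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # a missing column raises our own format error below, not a parser warning
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    visit = readr::col_character(),
    condition = readr::col_character(),
    rater_id = readr::col_character(),
    duration_s = readr::col_double(),
    tic_time_s = readr::col_double()
  )))
  required <- c("subject_id", "visit", "condition", "rater_id",
                "duration_s", "tic_time_s")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  raw$.row <- seq_len(nrow(raw))
  bad <- !is.na(raw$tic_time_s) &
    (raw$tic_time_s < 0 | raw$tic_time_s >= raw$duration_s)
  if (any(bad)) {
    abort(sprintf(
      "event time outside [0, duration) at data row(s): %s",
      paste(raw$.row[bad], collapse = ", ")))
  }
  grouped <- raw |>
    dplyr::group_by(.data$subject_id, .data$visit, .data$condition,
                    .data$rater_id, .data$duration_s) |>
    dplyr::summarise(
      events = list(sort(.data$tic_time_s[!is.na(.data$tic_time_s)])),
      .groups = "drop"
    )
  tic_sessions(grouped$subject_id, grouped$visit, grouped$condition,
               grouped$rater_id, grouped$duration_s, grouped$events)
}

#' Write tic sessions to the long CSV dialect
#'
#' Inverse of [read_sessions()]: one row per tic, `tic_time_s` empty for
#' sessions without tics.
#'
#' @param sessions a sessions tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  long <- sessions |>
    dplyr::mutate(events = lapply(.data$events, function(e) {
      if (length(e)) e else NA_real_
    })) |>
    tidyr::unnest_longer(col = "events", values_to = "tic_time_s") |>
    dplyr::select("subject_id", "visit", "condition", "rater_id",
                  "duration_s", "tic_time_s")
  readr::write_csv(long, path, na = "")
  invisible(path)
}

#' Discretize tic onset times onto the walk time grid
#'
#' Splits the half-open observation window `[0, duration_s)` into
#' `N = round(duration_s / dt_s)` bins of width `dt_s`; bin `j` (0-based)
#' is flagged when at least one tic onset falls in `[j dt, (j+1) dt)`,
#' i.e. `floor(t / dt) = j`. The flags are boolean: several tics landing in
#' one bin trigger a single velocity reversal downstream.
#'
#' @param events numeric, tic onset times in seconds, within `[0, duration_s)`.
#' @param duration_s session length in seconds.
#' @param dt_s bin width in seconds (default 0.1, the walker time step).
#'   Must divide `duration_s` to within 1e-9 relative.
#' @return A logical vector of length `N`.
#' @export
#' @examples
#' which(bin_events(c(10.0), 300, 0.1)) # bin index 101 (1-based)
bin_events <- function(events, duration_s, dt_s = 0.1) {
  if (!is.numeric(dt_s) || length(dt_s) != 1 || !is.finite(dt_s) || dt_s <= 0) {
    abort("dt_s must be a single positive number")
  }
  n <- round(duration_s / dt_s)
  if (n < 1 || abs(n * dt_s - duration_s) > 1e-9 * duration_s) {
    abort(sprintf("dt_s = %g does not divide duration_s = %g", dt_s, duration_s))
  }
  events <- as.numeric(events)
  if (length(events) && (any(events < 0) || any(events >= duration_s))) {
    abort("event times must lie in [0, duration_s)")
  }
  flags <- logical(n)
  if (length(events)) {
    idx <- pmin(floor(events / dt_s), n - 1) + 1L
    flags[idx] <- TRUE
  }
  flags
}

#' Write / read per-session fractal-dimension results
#'
#' The results table is the flat output of [estimate_df_sessions()]:
#' one row per session per rater with the tic count, fitted `D_f`, the fit's
#' coefficient of determination and the frequency window used. Round-trips
#' losslessly at full double precision.
#'
#' @param table a results tibble.
#' @param path output (or input) CSV path.
#' @return For `write_results`, `path` invisibly; for `read_results`, the
#'   tibble.
#' @export
write_results <- function(table, path) {
  cols <- c("subject_id", "visit", "condition", "rater_id",
            "n_tics", "D_f", "fit_r2", "f_lo", "f_hi")
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    abort(sprintf("results table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  readr::write_csv(dplyr::select(table, dplyr::all_of(cols)), path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    visit = readr::col_character(),
    condition = readr::col_character(),
    rater_id = readr::col_character(),
    n_tics = readr::col_integer(),
    D_f = readr::col_double(),
    fit_r2 = readr::col_double(),
    f_lo = readr::col_double(),
    f_hi = readr::col_double()
  ))
}
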