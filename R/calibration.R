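#' Calibrate the slope-to-dimension convention
#'
#' The fractal dimension is anchored to two printed reference values:
#' ballistic motion (turn probability 0, the no-tic limit) must score
#' `D_f ~ 2` and Brownian motion (turn probability 0.5, the maximally
#' chaotic limit) must score `D_f ~ 1`. Because the mapping from the
#' log-log spectral slope to a dimension depends on conventions that the
#' scattering literature leaves to its derivations, the package does not
#' hard-code it. Instead this routine:
#'
#' 1. simulates the deterministic ballistic walk and selects the fit window
#'    -- the widest log-frequency interval on which the ballistic curve is a
#'    clean power law (OLS `r^2 >= 0.98`, at least 8 points);
#' 2. simulates a seeded ensemble of Brownian walks and measures their mean
#'    slope in the same window;
#' 3. fixes an affine map `D_f = a * slope + b`. A sign-plus-offset map
#'    (`a` in `{-1, +1}`) is preferred when it places both anchors within
#'    `tolerance`; otherwise the general affine map through the two anchor
#'    points is used, provided the two slopes are well separated.
#'
#' The resulting record pins the convention and fit window package-wide;
#' every downstream `D_f` is computed under one fixed affine map, so the
#' ballistic and Brownian anchors constrain each other (a map cannot be bent
#' to one anchor without moving the other).
#'
#' @param settings a [df_settings()] record.
#' @param n_steps walk length in steps (default 3000, a 300 s session).
#' @param n_brownian Brownian ensemble size `M` (at least 100 recommended).
#' @param seed integer; Brownian walker `k` uses `seed + k`.
#' @param r2_min minimum `r^2` for the ballistic power-law window.
#' @param tolerance maximum allowed anchor deviation (default 0.2).
#' @return A `df_calibration` object.
#' @export
calibrate_convention <- function(settings = df_settings(), n_steps = 3000,
                                 n_brownian = 100, seed = 20220223L,
                                 r2_min = 0.98, tolerance = 0.2) {
  stopifnot(inherits(settings, "df_settings"))
  ballistic <- simulate_walk(n_steps, dt_s = settings$dt_s, v = settings$v,
                             p_turn = 0)
  curve_b <- spectral_density(ballistic, n_theta = settings$n_theta,
                              n_freqs = settings$n_freqs,
                              decades = settings$decades)
  win <- select_power_law_window(curve_b, r2_min = r2_min)
  if (is.null(win)) {
    abort(sprintf(
      "calibration failed: no >= 8-point window with r^2 >= %.3f on the ballistic curve",
      r2_min))
  }
  window <- c(win$f_lo, win$f_hi)
  slope_ballistic <- fit_fractal_dimension(curve_b, window = window)$slope

  # the ensemble slope only needs the window frequencies
  window_freqs <- curve_b$freq[curve_b$freq >= window[1] &
                                 curve_b$freq <= window[2]]
  brownian_slopes <- vapply(seq_len(n_brownian), function(k) {
    w <- simulate_walk(n_steps, dt_s = settings$dt_s, v = settings$v,
                       p_turn = 0.5, seed = seed + k)
    cv <- spectral_density(w, n_theta = settings$n_theta,
                           freqs = window_freqs)
    fit_fractal_dimension(cv, window = window)$slope
  }, numeric(1))
  slope_brownian <- mean(brownian_slopes)

  map <- choose_affine_map(slope_ballistic, slope_brownian, tolerance)
  if (is.null(map)) {
    abort(sprintf(
      paste0("calibration failed: no affine slope->D_f map places both ",
             "anchors within %.2f (ballistic slope %.4f, Brownian mean ",
             "slope %.4f)"),
      tolerance, slope_ballistic, slope_brownian))
  }
  anchors <- c(ballistic = map$a * slope_ballistic + map$b,
               brownian = map$a * slope_brownian + map$b)
  structure(list(
    a = map$a, b = map$b, map_kind = map$kind,
    slope_ballistic = slope_ballistic,
    slope_brownian_mean = slope_brownian,
    slope_brownian_sd = sd(brownian_slopes),
    f_lo = window[1], f_hi = window[2],
    window_r2 = win$r2, window_n = win$n,
    anchor_ballistic = unname(anchors["ballistic"]),
    anchor_brownian = unname(anchors["brownian"]),
    n_steps = n_steps, n_brownian = n_brownian, seed = seed,
    settings = settings
  ), class = "df_calibration")
}

# Widest contiguous log-frequency window (>= 8 points) on which the curve is
# power-law to r2_min. O(n_freqs^2) OLS scans; n_freqs is small.
select_power_law_window <- function(curve, r2_min = 0.98, min_points = 8) {
  lf <- log(curve$freq)
  ls <- log(pmax(curve$S_f, .Machine$double.xmin))
  n <- length(lf)
  best <- NULL
  for (i in seq_len(n - min_points + 1)) {
    for (j in seq(i + min_points - 1, n)) {
      fit <- stats::lm.fit(cbind(1, lf[i:j]), ls[i:j])
      sst <- sum((ls[i:j] - mean(ls[i:j]))^2)
      r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 0
      if (r2 >= r2_min) {
        width <- lf[j] - lf[i]
        if (is.null(best) || width > best$width) {
          best <- list(f_lo = curve$freq[i], f_hi = curve$freq[j],
                       width = width, r2 = r2, n = j - i + 1L)
        }
      }
    }
  }
  best
}

choose_affine_map <- function(slope_ballistic, slope_brownian, tolerance) {
  # Preferred: unit-magnitude slope coefficient, offset only.
  for (a in c(-1, 1)) {
    b <- mean(c(2 - a * slope_ballistic, 1 - a * slope_brownian))
    if (abs(a * slope_ballistic + b - 2) <= tolerance &&
        abs(a * slope_brownian + b - 1) <= tolerance) {
      return(list(a = a, b = b, kind = "sign_offset"))
    }
  }
  # General affine map through both anchor points; requires the two
  # reference slopes to be distinguishable.
  if (abs(slope_ballistic - slope_brownian) < 0.2) return(NULL)
  a <- (2 - 1) / (slope_ballistic - slope_brownian)
  b <- 2 - a * slope_ballistic
  list(a = a, b = b, kind = "affine")
}

#' @export
print.df_calibration <- function(x, ...) {
  cat("<df_calibration>\n")
  cat(sprintf("  D_f = %.4f * slope + %.4f  (%s)\n", x$a, x$b, x$map_kind))
  cat(sprintf("  window [%.4g, %.4g] (%d freqs, ballistic r^2 %.4f)\n",
              x$f_lo, x$f_hi, x$window_n, x$window_r2))
  cat(sprintf("  anchors: ballistic %.3f (target 2), Brownian %.3f (target 1, M = %d)\n",
              x$anchor_ballistic, x$anchor_brownian, x$n_brownian))
  invisible(x)
}

#' @export
glance.df_calibration <- function(x, ...) {
  tibble(a = x$a, b = x$b, map_kind = x$map_kind,
         slope_ballistic = x$slope_ballistic,
         slope_brownian_mean = x$slope_brownian_mean,
         anchor_ballistic = x$anchor_ballistic,
         anchor_brownian = x$anchor_brownian,
         f_lo = x$f_lo, f_hi = x$f_hi,
         n_brownian = x$n_brownian, seed = x$seed)
}

#' Persist / restore a calibration record as JSON
#'
#' @param calibration a `df_calibration`.
#' @param path JSON file path.
#' @return For `write_calibration`, `path` invisibly; for
#'   `read_calibration`, the `df_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "df_calibration"))
  payload <- unclass(calibration)
  payload$settings <- unclass(payload$settings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(sprintf("calibration record not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  settings <- do.call(df_settings, payload$settings)
  payload$settings <- settings
  structure(payload, class = "df_calibration")
}

#' Fractal dimension of one tic event series
#'
#' End-to-end composition: bin the tic onsets onto the walker grid, run the
#' tic-modulated walk (deterministic given the events), compute the
#' orientation-averaged spectral density and fit `D_f` under the supplied
#' calibration. A walker that never escapes a single step from the origin
#' (e.g. a tic in every bin, which makes it oscillate in place) is flagged
#' `degenerate`; its fit is reported but should be excluded from group
#' statistics.
#'
#' @param events numeric tic onset times, seconds in `[0, duration_s)`.
#' @param duration_s session length, seconds.
#' @param calibration a `df_calibration` (required: fixes the window and
#'   slope convention).
#' @param settings optional [df_settings()] override; defaults to the
#'   calibration's settings.
#' @return A `df_estimate` with an added `n_tics` field.
#' @export
estimate_df <- function(events, duration_s = 300, calibration,
                        settings = NULL) {
  if (missing(calibration) || !inherits(calibration, "df_calibration")) {
    abort(paste("a df_calibration is required; run calibrate_convention()",
                "(or read_calibration()) first"))
  }
  if (is.null(settings)) settings <- calibration$settings
  flags <- bin_events(events, duration_s, settings$dt_s)
  traj <- simulate_walk(length(flags), dt_s = settings$dt_s, v = settings$v,
                        indicator = flags)
  curve <- spectral_density(traj, n_theta = settings$n_theta,
                            n_freqs = settings$n_freqs,
                            decades = settings$decades)
  est <- fit_fractal_dimension(curve, convention = calibration)
  # confined walker: position span never exceeds one step from the origin
  if (max(abs(traj$position)) <= settings$v * settings$dt_s * (1 + 1e-9)) {
    est$degenerate <- TRUE
  }
  est$n_tics <- length(events)
  est
}

#' Fractal dimension for every session in a table
#'
#' Maps [estimate_df()] over a sessions tibble and returns the table with
#' per-session results appended -- the flat form consumed by the group-level
#' statistics and by [write_results()].
#'
#' @param sessions a sessions tibble (see [tic_sessions()]).
#' @param calibration a `df_calibration`.
#' @param settings optional [df_settings()] override.
#' @return The input tibble (minus the `events` list-column) with columns
#'   `D_f`, `fit_r2`, `f_lo`, `f_hi`, `degenerate` appended.
#' @export
estimate_df_sessions <- function(sessions, calibration, settings = NULL) {
  ests <- purrr::map2(sessions$events, sessions$duration_s, function(ev, dur) {
    estimate_df(ev, dur, calibration, settings)
  })
  out <- dplyr::select(sessions, -dplyr::any_of("events"))
  out$D_f <- vapply(ests, `[[`, numeric(1), "D_f")
  out$fit_r2 <- vapply(ests, `[[`, numeric(1), "fit_r2")
  out$f_lo <- vapply(ests, `[[`, numeric(1), "f_lo")
  out$f_hi <- vapply(ests, `[[`, numeric(1), "f_hi")
  out$degenerate <- vapply(ests, `[[`, logical(1), "degenerate")
  out
}
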