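#' Spectral-analysis settings
#'
#' Bundles the tunable parameters of the fractal-dimension pipeline. The
#' defaults are the package's reference configuration: 0.1 s time steps
#' (3000 steps per 300 s session), 180 rotation angles, and 64 log-spaced
#' frequencies spanning 2.5 decades above the fundamental `2*pi /` (the
#' normalized trajectory span, which is 1).
#'
#' @param dt_s walker time step, seconds.
#' @param v walker speed, position units per second.
#' @param n_theta number of rotation angles, evenly spaced in `[0, 2*pi)`.
#' @param n_freqs number of frequencies on the log-spaced grid.
#' @param decades number of decades the grid spans above the fundamental.
#' @return A `df_settings` list.
#' @export
df_settings <- function(dt_s = 0.1, v = 1, n_theta = 180,
                        n_freqs = 64, decades = 2.5) {
  stopifnot(dt_s > 0, v > 0, n_theta >= 1, n_freqs >= 8, decades > 0)
  structure(list(dt_s = dt_s, v = v, n_theta = as.integer(n_theta),
                 n_freqs = as.integer(n_freqs), decades = decades),
            class = "df_settings")
}

#' Log-spaced frequency grid above the fundamental
#'
#' @param n_freqs number of frequencies.
#' @param decades decades spanned above `f0`.
#' @param f0 fundamental frequency (default `2*pi` for a unit-span
#'   trajectory).
#' @return Numeric vector of increasing frequencies.
#' @export
frequency_grid <- function(n_freqs = 64, decades = 2.5, f0 = 2 * pi) {
  exp(seq(log(f0), log(f0 * 10^decades), length.out = n_freqs))
}

#' Orientation-averaged spectral density of a planar point set
#'
#' The raw primitive behind [spectral_density()]: for points
#' `(t[j], x[j])` and each of `n_theta` rotation angles evenly spaced in
#' `[0, 2*pi)`, computes the squared modulus of the mean phasor
#' `S(f, theta) = |(1/N) sum_j exp(i f (cos(theta) t_j + sin(theta) x_j))|^2`
#' and averages over angles. No coordinate normalization is applied here.
#'
#' `S` is bounded in `[0, 1]`, tends to 1 as `f -> 0`, and is invariant to
#' translating the point set (the modulus removes the global phase).
#'
#' @param t,x numeric coordinate vectors of equal length.
#' @param freqs positive frequencies at which to evaluate.
#' @param n_theta number of rotation angles.
#' @return Numeric vector of `S` values, one per frequency.
#' @export
structure_factor <- function(t, x, freqs, n_theta = 180) {
  if (length(t) != length(x)) abort("t and x must have equal length")
  if (any(freqs <= 0)) abort("frequencies must be positive")
  .sf_kernel(as.numeric(t), as.numeric(x), as.numeric(freqs),
             as.integer(n_theta))
}

#' Spectral density of a walk trajectory
#'
#' Normalizes the trajectory so that both axes are commensurate -- time by
#' its span and position by the walker's maximum absolute displacement, each
#' mapping to unit span -- then computes the orientation-averaged spectral
#' density via [structure_factor()] on a log-spaced frequency grid. The
#' normalization is recorded in the result's `scaling` attribute; rotation of
#' anisotropically scaled axes would otherwise make the fitted dimension
#' depend on arbitrary units.
#'
#' A degenerate trajectory (all points identical) yields `S == 1` at every
#' frequency and sets the `degenerate` flag in the scaling record.
#'
#' @param trajectory a `walk_trajectory` from [simulate_walk()], or any
#'   data frame with `time_s` and `position` columns.
#' @param n_theta number of rotation angles (default 180).
#' @param n_freqs,decades frequency-grid shape (see [df_settings()]).
#' @param freqs optional explicit frequency vector overriding the grid.
#' @return A `spectral_curve` tibble with columns `freq` and `S_f` and
#'   attributes `n_theta` and `scaling`.
#' @export
spectral_density <- function(trajectory, n_theta = 180,
                             n_freqs = 64, decades = 2.5, freqs = NULL) {
  t <- trajectory$time_s
  x <- trajectory$position
  if (length(t) < 2) abort("trajectory must have at least 2 points")
  if (is.null(freqs)) freqs <- frequency_grid(n_freqs, decades)
  t_span <- max(t) - min(t)
  x_max <- max(abs(x))
  degenerate <- t_span == 0 && max(x) - min(x) == 0
  tt <- if (t_span > 0) (t - min(t)) / t_span else rep(0, length(t))
  xx <- if (x_max > 0) x / x_max else rep(0, length(x))
  values <- if (degenerate) rep(1, length(freqs)) else {
    structure_factor(tt, xx, freqs, n_theta)
  }
  out <- new_tibble(list(freq = freqs, S_f = values),
                    nrow = length(freqs), class = "spectral_curve")
  attr(out, "n_theta") <- as.integer(n_theta)
  attr(out, "scaling") <- list(t_span = t_span, x_max_abs = x_max,
                               degenerate = degenerate)
  out
}

#' Fit the fractal dimension from a spectral curve
#'
#' Ordinary least squares of `log(S_f)` on `log(freq)` over a frequency
#' window, with the slope mapped to a fractal dimension through the affine
#' convention fixed by [calibrate_convention()]. Frequencies where `S_f` is
#' exactly zero are dropped with a warning; at least 8 usable points are
#' required.
#'
#' @param curve a `spectral_curve`.
#' @param window `c(f_lo, f_hi)` fit bounds; defaults to the calibration's
#'   window if a calibration is supplied, else the full grid.
#' @param convention either a `df_calibration` object or a bare
#'   `list(a =, b =)` giving `D_f = a * slope + b`. If `NULL`, the slope and
#'   fit are returned with `D_f = NA`.
#' @return A `df_estimate` list: `D_f`, `slope`, `intercept`, `f_lo`,
#'   `f_hi`, `fit_r2`, `n_points`, `degenerate`.
#' @export
fit_fractal_dimension <- function(curve, window = NULL, convention = NULL) {
  if (inherits(convention, "df_calibration") && is.null(window)) {
    window <- c(convention$f_lo, convention$f_hi)
  }
  if (is.null(window)) window <- range(curve$freq)
  keep <- curve$freq >= window[1] & curve$freq <= window[2]
  if (!any(keep)) abort("fit window excludes all frequencies")
  f <- curve$freq[keep]
  s <- curve$S_f[keep]
  zero <- s <= 0
  if (any(zero)) {
    warn(sprintf("dropping %d frequencies with S_f = 0", sum(zero)))
    f <- f[!zero]
    s <- s[!zero]
  }
  if (length(f) < 8) abort("fewer than 8 usable frequencies in the fit window")
  fit <- lm(log(s) ~ log(f))
  slope <- unname(coef(fit)[2])
  # perfect fits (exact synthetic power laws) are fine; no need for
  # summary.lm's reliability warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  scaling <- attr(curve, "scaling")
  structure(list(
    D_f = apply_convention(slope, convention),
    slope = slope,
    intercept = unname(coef(fit)[1]),
    f_lo = window[1],
    f_hi = window[2],
    fit_r2 = r2,
    n_points = length(f),
    degenerate = isTRUE(scaling$degenerate)
  ), class = "df_estimate")
}

apply_convention <- function(slope, convention) {
  if (is.null(convention)) return(NA_real_)
  if (inherits(convention, "df_calibration")) {
    return(convention$a * slope + convention$b)
  }
  if (is.list(convention) && all(c("a", "b") %in% names(convention))) {
    return(convention$a * slope + convention$b)
  }
  abort("convention must be a df_calibration or list(a =, b =)")
}

#' @export
print.df_estimate <- function(x, ...) {
  cat(sprintf(
    "<df_estimate>  D_f = %s  (slope %.4f, r^2 %.4f, %d freqs in [%.3g, %.3g])%s\n",
    ifelse(is.na(x$D_f), "NA", sprintf("%.4f", x$D_f)),
    x$slope, x$fit_r2, x$n_points, x$f_lo, x$f_hi,
    if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

#' @export
tidy.df_estimate <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @export
glance.df_estimate <- function(x, ...) {
  tibble(D_f = x$D_f, slope = x$slope, fit_r2 = x$fit_r2,
         f_lo = x$f_lo, f_hi = x$f_hi, n_points = x$n_points,
         degenerate = x$degenerate)
}

#' @export
autoplot.spectral_curve <- function(object, estimate = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$freq, y = .data$S_f)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (1 / normalized span)",
                  y = expression(S[f])) +
    ggplot2::theme_minimal()
  if (!is.null(estimate)) {
    fl <- tibble(freq = c(estimate$f_lo, estimate$f_hi))
    fl$S_f <- exp(estimate$intercept + estimate$slope * log(fl$freq))
    p <- p + ggplot2::geom_line(data = fl, colour = "red")
  }
  p
}
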