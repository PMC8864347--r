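#' Simulate a velocity-reversal random walk
#'
#' The walker starts at position 0 with velocity `+v` (one position unit per
#' second by default) and advances in steps of `dt_s` seconds. At each step
#' the velocity either reverses sign or is kept, according to the turn
#' policy:
#'
#' * *tic-modulated*: supply `indicator`, the boolean bin flags from
#'   [bin_events()]. A flagged bin reverses the velocity used for that step
#'   (reversal applies before the step), so the walk is a deterministic
#'   function of the tic train.
#' * *constant probability*: supply `p_turn` in `[0, 1]` and a `seed`.
#'   `p_turn = 0` is ballistic (straight line, the no-tic limit);
#'   `p_turn = 0.5` is the Brownian reference (maximally chaotic ticcing).
#'
#' Every increment has magnitude exactly `v * dt_s`.
#'
#' @param n_steps integer, number of steps `N` (3000 for a 300 s session at
#'   `dt_s = 0.1`).
#' @param dt_s time step in seconds.
#' @param v speed, position units per second.
#' @param indicator logical vector of length `n_steps` (tic-modulated walks).
#' @param p_turn turn probability in `[0, 1]` (constant-probability walks).
#' @param seed integer seed; required when `p_turn > 0`.
#' @return A `walk_trajectory` tibble with columns `step` (0..N), `time_s`
#'   and `position`, and attributes `dt_s` and `v`.
#' @export
#' @examples
#' w <- simulate_walk(3000, indicator = bin_events(numeric(0), 300))
#' tail(w, 1)$position # 300: ballistic limit
simulate_walk <- function(n_steps, dt_s = 0.1, v = 1,
                          indicator = NULL, p_turn = NULL, seed = NULL) {
  if (!is.numeric(n_steps) || length(n_steps) != 1 || n_steps < 1) {
    abort("n_steps must be a positive integer")
  }
  n_steps <- as.integer(n_steps)
  if (is.null(indicator) == is.null(p_turn)) {
    abort("supply exactly one of `indicator` (tic-modulated) or `p_turn`")
  }
  if (!is.null(indicator)) {
    if (length(indicator) != n_steps) {
      abort(sprintf("indicator has length %d but n_steps is %d",
                    length(indicator), n_steps))
    }
    turns <- as.logical(indicator)
  } else {
    if (p_turn < 0 || p_turn > 1) abort("p_turn must lie in [0, 1]")
    if (p_turn == 0) {
      turns <- rep(FALSE, n_steps)
    } else {
      if (is.null(seed)) abort("a seed is required for stochastic walks")
      turns <- withr::with_seed(seed, runif(n_steps) < p_turn)
    }
  }
  # d_j = direction of step j; initial direction +1, a turn at step j flips
  # the direction used for that step.
  d <- cumprod(ifelse(turns, -1, 1))
  position <- c(0, cumsum(d * v * dt_s))
  out <- new_tibble(
    list(step = 0:n_steps,
         time_s = (0:n_steps) * dt_s,
         position = position),
    nrow = n_steps + 1L,
    class = "walk_trajectory"
  )
  attr(out, "dt_s") <- dt_s
  attr(out, "v") <- v
  out
}

#' Number of velocity reversals in a trajectory
#'
#' Counts steps whose direction differs from the previous step's (the first
#' step counts as a reversal if it moves against the initial `+v` velocity).
#' For a tic-modulated walk this equals the number of flagged bins.
#'
#' @param trajectory a `walk_trajectory`.
#' @return integer count.
#' @export
turn_count <- function(trajectory) {
  d <- sign(diff(trajectory$position))
  if (any(d == 0)) abort("degenerate trajectory: zero-length step")
  sum(d != c(1, d[-length(d)]))
}

#' @export
autoplot.walk_trajectory <- function(object, normalize = TRUE, ...) {
  df <- as_tibble(object)
  ylab <- "position (units)"
  if (normalize) {
    m <- max(abs(df$position))
    if (m > 0) df$position <- df$position / m
    ylab <- "position / max |position|"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$position)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = ylab) +
    ggplot2::theme_minimal()
}
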