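#' Parameters of the bursty tic-train generator
#'
#' Tics cluster at (at least) two timescales within a session: bouts of
#' several tics separated by sub-second-to-second gaps, and bouts recurring
#' in episodes separated by much longer tic-free intervals. The generator is
#' a three-level renewal cascade: episode onsets form a Poisson process;
#' each episode contains a geometric number of bouts spaced by exponential
#' gaps; each bout contains a geometric number of tics spaced by shorter
#' exponential gaps. Geometric counts and exponential gaps keep the expected
#' event count in closed form:
#' `episode_rate * duration_s * mean_bouts_per_episode * mean_tics_per_bout`
#' (up to end-of-window truncation).
#'
#' Defaults describe a moderately ticcing child in a 5-minute baseline
#' session: about 6 episodes, 2 bouts per episode and 3 tics per bout
#' (roughly 36 tics, 7 per minute), bout gaps of 0.5 s within a bout and
#' 15 s between bouts.
#'
#' @param episode_rate episodes per second (Poisson rate).
#' @param mean_bouts_per_episode mean bout count per episode (>= 1).
#' @param mean_tics_per_bout mean tic count per bout (>= 1).
#' @param within_bout_gap_s mean gap between tics inside a bout, seconds.
#' @param within_episode_gap_s mean gap between bouts inside an episode,
#'   seconds; must exceed `within_bout_gap_s` (timescale separation).
#' @param duration_s session length, seconds.
#' @return A `tic_train_params` list.
#' @export
tic_train_params <- function(episode_rate = 0.02,
                             mean_bouts_per_episode = 2,
                             mean_tics_per_bout = 3,
                             within_bout_gap_s = 0.5,
                             within_episode_gap_s = 15,
                             duration_s = 300) {
  if (episode_rate < 0) abort("episode_rate must be >= 0")
  if (mean_bouts_per_episode < 1) abort("mean_bouts_per_episode must be >= 1")
  if (mean_tics_per_bout < 1) abort("mean_tics_per_bout must be >= 1")
  if (within_bout_gap_s <= 0 || within_episode_gap_s <= 0) {
    abort("gap means must be positive")
  }
  if (within_bout_gap_s >= within_episode_gap_s) {
    abort("within_bout_gap_s must be smaller than within_episode_gap_s")
  }
  if (duration_s <= 0) abort("duration_s must be positive")
  structure(list(episode_rate = episode_rate,
                 mean_bouts_per_episode = mean_bouts_per_episode,
                 mean_tics_per_bout = mean_tics_per_bout,
                 within_bout_gap_s = within_bout_gap_s,
                 within_episode_gap_s = within_episode_gap_s,
                 duration_s = duration_s),
            class = "tic_train_params")
}

# geometric count with support {1, 2, ...} and the given mean
rcount <- function(n, mean) 1L + rgeom(n, prob = 1 / mean)

#' Generate one synthetic tic train
#'
#' @param params a [tic_train_params()] record.
#' @param seed integer seed; the train is a deterministic function of
#'   `(params, seed)`.
#' @return Sorted numeric vector of tic onset times in
#'   `[0, params$duration_s)`.
#' @export
#' @examples
#' generate_tic_train(tic_train_params(), seed = 1)
generate_tic_train <- function(params, seed) {
  stopifnot(inherits(params, "tic_train_params"))
  if (missing(seed)) abort("a seed is required")
  withr::with_seed(seed, {
    dur <- params$duration_s
    n_ep <- rpois(1, params$episode_rate * dur)
    if (n_ep == 0) return(numeric(0))
    episode_onsets <- sort(runif(n_ep, 0, dur))
    events <- unlist(lapply(episode_onsets, function(ep0) {
      n_bouts <- rcount(1, params$mean_bouts_per_episode)
      bout_onsets <- ep0 + c(0, cumsum(rexp(n_bouts - 1,
                                            rate = 1 / params$within_episode_gap_s)))
      unlist(lapply(bout_onsets, function(b0) {
        n_tics <- rcount(1, params$mean_tics_per_bout)
        b0 + c(0, cumsum(rexp(n_tics - 1,
                              rate = 1 / params$within_bout_gap_s)))
      }))
    }))
    sort(events[events < dur])
  })
}

#' Map latent severity to tic-train parameters
#'
#' Severity is an abstract per-subject score on a 0-50 scale (a stand-in for
#' a clinician-rated total tic score; it carries no clinical meaning). The
#' map is strictly monotone and exponential in the episode rate,
#' `rate = rate_floor * 10^(severity / decade_span) * rate_factor`:
#' a point of severity multiplies the tic rate by a constant factor, so the
#' score spans quasi-silent (a few tics per 5-minute session at severity 0)
#' to quasi-continuous ticcing (about 2 per second at severity 50) -- the
#' range over which the walker's dimension traverses its Brownian-to-
#' ballistic domain. A multiplicative `rate_factor` (< 1 for suppression
#' conditions) scales the episode rate without touching the within-episode
#' structure.
#'
#' @param severity numeric score in `[0, 50]`.
#' @param rate_factor multiplicative condition factor applied to the episode
#'   rate.
#' @param base a [tic_train_params()] record supplying the non-rate fields.
#' @param rate_floor episode rate at severity 0, episodes per second.
#' @param decade_span severity points per tenfold rate increase.
#' @return A `tic_train_params` record.
#' @export
severity_to_params <- function(severity, rate_factor = 1,
                               base = tic_train_params(),
                               rate_floor = 0.004, decade_span = 25) {
  if (severity < 0 || severity > 50) abort("severity must lie in [0, 50]")
  rate <- rate_floor * 10^(severity / decade_span) * rate_factor
  tic_train_params(episode_rate = rate,
                   mean_bouts_per_episode = base$mean_bouts_per_episode,
                   mean_tics_per_bout = base$mean_tics_per_bout,
                   within_bout_gap_s = base$within_bout_gap_s,
                   within_episode_gap_s = base$within_episode_gap_s,
                   duration_s = base$duration_s)
}

#' Specification of a synthetic cohort
#'
#' Describes a longitudinal study: `n_subjects` children observed at a
#' screening visit and again twelve months later, each visit comprising one
#' session per suppression condition. Each subject carries a latent severity
#' drawn from a normal distribution (truncated to the 0-50 score range) and
#' a normally distributed twelve-month severity change. Condition factors
#' multiply the episode rate; factors below 1 emulate effective suppression.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param severity_mean,severity_sd screening-severity distribution.
#' @param change_mean,change_sd twelve-month severity-change distribution.
#' @param condition_factors named numeric, episode-rate multipliers for
#'   `baseline`, `verbal`, `DRO`, `NCR`; suppression factors must be <= 1.
#' @param base_params a [tic_train_params()] record for the non-rate fields.
#' @param duration_s session length, seconds.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 40,
                        severity_mean = 30, severity_sd = 8,
                        change_mean = -4, change_sd = 8,
                        condition_factors = c(baseline = 1, verbal = 0.5,
                                              DRO = 0.25, NCR = 0.9),
                        base_params = tic_train_params(),
                        duration_s = 300) {
  if (n_subjects < 2) abort("n_subjects must be >= 2")
  missing_conditions <- setdiff(CONDITION_LEVELS, names(condition_factors))
  if (length(missing_conditions)) {
    abort(sprintf("condition_factors lacks: %s",
                  paste(missing_conditions, collapse = ", ")))
  }
  if (any(condition_factors <= 0)) abort("condition factors must be positive")
  if (any(condition_factors > 1)) {
    abort("condition factors must be <= 1 (baseline is the reference rate)")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 severity_mean = severity_mean, severity_sd = severity_sd,
                 change_mean = change_mean, change_sd = change_sd,
                 condition_factors = condition_factors[CONDITION_LEVELS],
                 base_params = base_params,
                 duration_s = duration_s),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of tic sessions
#'
#' Draws per-subject severities, builds one session per visit and condition
#' with episode rates set by [severity_to_params()] times the condition
#' factor, and returns the sessions together with the latent severity of the
#' subject at that visit (the quantity the group statistics try to recover).
#' All sessions are attributed to rater `"r1"`; apply
#' [apply_rater_sessions()] for a second-rater replica.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the cohort is a deterministic function of
#'   `(spec, seed)`.
#' @param visits which visits to generate (default both).
#' @return A sessions tibble with an extra `severity` column.
#' @export
generate_cohort <- function(spec, seed, visits = VISIT_LEVELS) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed)) abort("a seed is required")
  visits <- match.arg(visits, VISIT_LEVELS, several.ok = TRUE)
  draws <- withr::with_seed(seed, {
    sev0 <- pmin(pmax(rnorm(spec$n_subjects, spec$severity_mean,
                            spec$severity_sd), 0), 50)
    delta <- rnorm(spec$n_subjects, spec$change_mean, spec$change_sd)
    sev12 <- pmin(pmax(sev0 + delta, 0), 50)
    list(sev0 = sev0, sev12 = sev12,
         session_seeds = sample.int(.Machine$integer.max - 1,
                                    spec$n_subjects * 2 * 4))
  })
  grid <- tidyr::expand_grid(
    subject = seq_len(spec$n_subjects),
    visit = VISIT_LEVELS,
    condition = CONDITION_LEVELS
  )
  grid$severity <- ifelse(grid$visit == "screening",
                          draws$sev0[grid$subject], draws$sev12[grid$subject])
  grid$session_seed <- draws$session_seeds
  # filtering after seed assignment keeps retained sessions identical
  # whichever visit subset is requested
  grid <- grid[grid$visit %in% visits, ]
  base <- spec$base_params
  base$duration_s <- spec$duration_s
  events <- purrr::pmap(
    list(grid$severity, grid$condition, grid$session_seed),
    function(sev, cond, s_seed) {
      params <- severity_to_params(sev, spec$condition_factors[[cond]],
                                   base = base)
      params$duration_s <- spec$duration_s
      generate_tic_train(params, seed = s_seed)
    })
  out <- tic_sessions(sprintf("s%03d", grid$subject), grid$visit,
                      grid$condition, "r1", spec$duration_s, events)
  out$severity <- grid$severity
  out
}

#' Rater observation-noise model
#'
#' Emulates an independent human rater re-annotating the same session:
#' each true tic is missed with probability `miss_prob`, surviving onsets
#' are jittered by centred Gaussian noise (clipped to the observation
#' window), and spurious annotations arrive as a Poisson process at
#' `false_alarm_rate` per second. With all parameters zero the model is the
#' identity.
#'
#' @param miss_prob probability in `[0, 1]` of dropping a true tic.
#' @param false_alarm_rate spurious annotations per second (>= 0).
#' @param jitter_sd_s standard deviation of onset-time jitter, seconds.
#' @return A `rater_model` list.
#' @export
rater_model <- function(miss_prob = 0, false_alarm_rate = 0,
                        jitter_sd_s = 0) {
  if (miss_prob < 0 || miss_prob > 1) abort("miss_prob must lie in [0, 1]")
  if (false_alarm_rate < 0) abort("false_alarm_rate must be >= 0")
  if (jitter_sd_s < 0) abort("jitter_sd_s must be >= 0")
  structure(list(miss_prob = miss_prob, false_alarm_rate = false_alarm_rate,
                 jitter_sd_s = jitter_sd_s), class = "rater_model")
}

#' Apply rater noise to one event series
#'
#' @param events numeric tic onset times, seconds.
#' @param duration_s observation window, seconds.
#' @param model a [rater_model()].
#' @param seed integer seed.
#' @return Sorted numeric vector of observed onset times in
#'   `[0, duration_s)`.
#' @export
apply_rater <- function(events, duration_s, model, seed) {
  stopifnot(inherits(model, "rater_model"))
  if (model$miss_prob == 0 && model$false_alarm_rate == 0 &&
      model$jitter_sd_s == 0) {
    return(sort(as.numeric(events)))
  }
  if (missing(seed)) abort("a seed is required for a noisy rater")
  withr::with_seed(seed, {
    kept <- events[runif(length(events)) >= model$miss_prob]
    if (model$jitter_sd_s > 0 && length(kept)) {
      kept <- kept + rnorm(length(kept), 0, model$jitter_sd_s)
      kept <- pmin(pmax(kept, 0), duration_s - 1e-9)
    }
    n_fa <- rpois(1, model$false_alarm_rate * duration_s)
    sort(c(kept, runif(n_fa, 0, duration_s)))
  })
}

#' Apply rater noise to every session in a table
#'
#' @param sessions a sessions tibble.
#' @param model a [rater_model()].
#' @param rater_id label for the replica rater.
#' @param seed integer seed; session `i` uses `seed + i`.
#' @return A sessions tibble with the same session keys but `rater_id`
#'   replaced and events re-observed.
#' @export
apply_rater_sessions <- function(sessions, model, rater_id = "r2", seed) {
  events <- purrr::imap(sessions$events, function(ev, i) {
    apply_rater(ev, sessions$duration_s[i], model, seed = seed + i)
  })
  out <- tic_sessions(sessions$subject_id, sessions$visit, sessions$condition,
                      rater_id, sessions$duration_s, events)
  if ("severity" %in% names(sessions)) out$severity <- sessions$severity
  out
}
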