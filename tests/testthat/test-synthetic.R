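test_that("parameter validation enforces the timescale separation", {
  expect_error(tic_train_params(within_bout_gap_s = 20,
                                within_episode_gap_s = 10), "smaller")
  expect_error(tic_train_params(mean_tics_per_bout = 0.5), ">= 1")
  expect_error(tic_train_params(episode_rate = -1), ">= 0")
  expect_silent(tic_train_params())
})

test_that("a zero episode rate yields an empty train", {
  p <- tic_train_params(episode_rate = 0)
  expect_length(generate_tic_train(p, seed = 1), 0)
})

test_that("trains are seed-deterministic and seed-sensitive", {
  p <- tic_train_params()
  t1 <- generate_tic_train(p, seed = 8)
  expect_identical(t1, generate_tic_train(p, seed = 8))
  expect_false(identical(t1, generate_tic_train(p, seed = 9)))
  expect_true(all(diff(t1) >= 0))
  expect_true(all(t1 >= 0 & t1 < 300))
})

test_that("the mean event count matches the cascade's closed form", {
  # low-truncation setting: short cascades well inside the window
  p <- tic_train_params(episode_rate = 0.01, mean_bouts_per_episode = 1.5,
                        mean_tics_per_bout = 2, within_bout_gap_s = 0.2,
                        within_episode_gap_s = 2)
  expected <- 0.01 * 300 * 1.5 * 2
  counts <- vapply(1:2000, function(k) {
    length(generate_tic_train(p, seed = 10000 + k))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.05 * expected)
})

test_that("inter-event intervals are bimodal across the two timescales", {
  p <- tic_train_params(episode_rate = 0.02, within_bout_gap_s = 0.5,
                        within_episode_gap_s = 20)
  gaps <- unlist(lapply(1:60, function(k) {
    diff(generate_tic_train(p, seed = 500 + k))
  }))
  gaps <- gaps[gaps > 0]
  split <- sqrt(0.5 * 20) # geometric midpoint of the two gap scales
  short <- gaps[gaps < split]
  long <- gaps[gaps >= split]
  expect_gt(length(short), 50)
  expect_gt(length(long), 50)
  # modes separated by more than a decade
  expect_gt(mean(log10(long)) - mean(log10(short)), 1)
})

test_that("generated trains cluster (Fano factor above Poisson)", {
  p <- tic_train_params()
  counts <- unlist(lapply(1:50, function(k) {
    ev <- generate_tic_train(p, seed = 900 + k)
    tabulate(floor(ev / 10) + 1, nbins = 30)
  }))
  expect_gt(var(counts) / mean(counts), 1)
})

test_that("expected tic count increases strictly with latent severity", {
  mean_count <- function(sev) {
    mean(vapply(1:200, function(k) {
      length(generate_tic_train(severity_to_params(sev), seed = 7000 + k))
    }, numeric(1)))
  }
  counts <- vapply(c(10, 25, 40), mean_count, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("cohorts reproduce bit-identically from their seed", {
  spec <- cohort_spec(n_subjects = 4)
  c1 <- generate_cohort(spec, seed = 3)
  c2 <- generate_cohort(spec, seed = 3)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$severity, c2$severity)
  expect_equal(nrow(c1), 4 * 2 * 4) # subjects x visits x conditions
  scr <- generate_cohort(spec, seed = 3, visits = "screening")
  expect_identical(scr$events,
                   c1$events[c1$visit == "screening"])
})

test_that("suppression factors scale tic counts as specified", {
  spec <- cohort_spec(n_subjects = 30,
                      condition_factors = c(baseline = 1, verbal = 0.6,
                                            DRO = 0.4, NCR = 0.9))
  coh <- generate_cohort(spec, seed = 21, visits = "screening")
  n_base <- coh$n_tics[coh$condition == "baseline"]
  n_dro <- coh$n_tics[coh$condition == "DRO"]
  d <- n_dro - n_base
  expect_lt(mean(d), -3 * sd(d) / sqrt(length(d)))
})

test_that("zero severity change makes the visits exchangeable", {
  spec <- cohort_spec(n_subjects = 25, change_mean = 0, change_sd = 0,
                      condition_factors = c(baseline = 1, verbal = 1,
                                            DRO = 1, NCR = 1))
  coh <- generate_cohort(spec, seed = 13)
  n0 <- coh$n_tics[coh$visit == "screening"]
  n12 <- coh$n_tics[coh$visit == "twelve_month"]
  se <- sqrt(var(n0) / length(n0) + var(n12) / length(n12))
  expect_lt(abs(mean(n0) - mean(n12)), 3 * se)
})

test_that("the rater model is the identity at zero noise", {
  ev <- c(1, 5.5, 200)
  expect_identical(apply_rater(ev, 300, rater_model()), ev)
})

test_that("a rater that misses everything returns an empty series", {
  ev <- generate_tic_train(tic_train_params(), seed = 2)
  got <- apply_rater(ev, 300, rater_model(miss_prob = 1), seed = 4)
  expect_length(got, 0)
})

test_that("jitter preserves the event count inside the window", {
  ev <- generate_tic_train(tic_train_params(), seed = 6)
  got <- apply_rater(ev, 300, rater_model(jitter_sd_s = 0.05), seed = 4)
  expect_length(got, length(ev))
  expect_true(all(got >= 0 & got < 300))
  expect_true(all(diff(got) >= 0))
})

test_that("false alarms arrive at the requested rate", {
  model <- rater_model(false_alarm_rate = 0.1)
  n_fa <- vapply(1:200, function(k) {
    length(apply_rater(numeric(0), 300, model, seed = k))
  }, numeric(1))
  se <- sd(n_fa) / sqrt(length(n_fa))
  expect_lt(abs(mean(n_fa) - 30), 3 * se)
})
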