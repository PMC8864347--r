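make_results <- function(subject_id, visit, condition, D_f, severity = 0,
                         rater_id = "r1") {
  tibble::tibble(subject_id = subject_id, visit = visit,
                 condition = condition, rater_id = rater_id,
                 D_f = D_f, severity = severity)
}

test_that("a perfectly anti-proportional change gives r = -1", {
  n <- 6
  dsev <- c(-5, -3, -1, 2, 4, 6)
  tbl <- dplyr::bind_rows(
    make_results(paste0("s", 1:n), "screening", "baseline", 1.5, 20),
    make_results(paste0("s", 1:n), "twelve_month", "baseline",
                 1.5 - 0.02 * dsev, 20 + dsev)
  )
  da <- delta_analysis(tbl)
  expect_equal(da$r, -1, tolerance = 1e-12)
  expect_equal(da$n, n)
  expect_equal(tidy(da)$delta_severity, dsev)
})

test_that("a constant severity change leaves r undefined and flagged", {
  tbl <- dplyr::bind_rows(
    make_results(paste0("s", 1:4), "screening", "baseline", c(1.2, 1.4, 1.6, 1.8), 20),
    make_results(paste0("s", 1:4), "twelve_month", "baseline", c(1.3, 1.2, 1.9, 1.4), 25)
  )
  da <- delta_analysis(tbl)
  expect_true(is.na(da$r))
  expect_match(da$flag, "zero variance")
})

test_that("too few complete subjects is an error", {
  tbl <- dplyr::bind_rows(
    make_results(c("a", "b"), "screening", "baseline", c(1.2, 1.4), 20),
    make_results(c("a", "b"), "twelve_month", "baseline", c(1.3, 1.2), 25)
  )
  expect_error(delta_analysis(tbl), ">= 3 subjects")
})

test_that("condition summaries collapse to closed forms", {
  # identical values: zero-width interval
  tbl <- make_results(paste0("s", 1:3), "screening", "baseline", rep(1.5, 3))
  summ <- condition_summary(tbl)
  expect_equal(summ$mean_D_f, 1.5)
  expect_equal(summ$ci_lo, 1.5)
  expect_equal(summ$ci_hi, 1.5)
  # two values: mean and t(1) interval
  a <- 1.2
  b <- 1.8
  tbl2 <- make_results(c("s1", "s2"), "screening", "DRO", c(a, b))
  summ2 <- condition_summary(tbl2)
  half <- qt(0.975, 1) * sd(c(a, b)) / sqrt(2)
  expect_equal(summ2$mean_D_f, (a + b) / 2)
  expect_equal(summ2$ci_hi - summ2$mean_D_f, half, tolerance = 1e-12)
  # singleton cell flagged with undefined interval
  tbl3 <- make_results("s1", "screening", "NCR", 1.4)
  expect_warning(summ3 <- condition_summary(tbl3), "singleton")
  expect_true(is.na(summ3$ci_lo))
})

test_that("equal per-subject condition means give F = 0", {
  tbl <- make_results(rep(paste0("s", 1:3), each = 2),
                      "screening",
                      rep(c("baseline", "DRO"), 3),
                      rep(c(1.2, 1.5, 1.8), each = 2))
  an <- rm_anova(tbl)
  expect_equal(an$statistic, 0)
  expect_equal(c(an$df1, an$df2), c(1, 2))
})

test_that("the F statistic matches aov's within-subject stratum", {
  withr::with_seed(19, {
    tbl <- make_results(
      rep(paste0("s", 1:7), each = 4), "screening",
      rep(c("baseline", "verbal", "DRO", "NCR"), 7),
      round(runif(28, 1, 2), 3))
    an <- rm_anova(tbl)
    fit <- stats::aov(D_f ~ condition + Error(factor(subject_id)),
                      data = tbl)
    ref <- summary(fit)[["Error: Within"]][[1]]
    expect_equal(an$statistic, ref["condition", "F value"], tolerance = 1e-10)
    expect_equal(an$p, ref["condition", "Pr(>F)"], tolerance = 1e-10)
    expect_equal(unname(an$ss["error"]), ref["Residuals", "Sum Sq"],
                 tolerance = 1e-10)
  })
})

test_that("a hand-computed 3 x 2 block matches the sums of squares", {
  tbl <- make_results(rep(c("a", "b", "c"), each = 2), "screening",
                      rep(c("baseline", "DRO"), 3),
                      c(1.0, 1.4, 1.2, 1.4, 1.1, 1.7))
  an <- rm_anova(tbl)
  # direct arithmetic: condition means 1.1 and 1.5, grand mean 1.3
  expect_equal(unname(an$ss["condition"]), 3 * (0.2^2 + 0.2^2))
  y <- c(1.0, 1.4, 1.2, 1.4, 1.1, 1.7)
  ss_total <- sum((y - 1.3)^2)
  subj <- c(1.2, 1.3, 1.4)
  ss_subj <- 2 * sum((subj - 1.3)^2)
  expect_equal(unname(an$ss["subjects"]), ss_subj, tolerance = 1e-12)
  expect_equal(sum(an$ss), ss_total, tolerance = 1e-12)
})

test_that("F is invariant to adding per-subject constants", {
  withr::with_seed(23, {
    tbl <- make_results(rep(paste0("s", 1:6), each = 3), "screening",
                        rep(c("baseline", "verbal", "DRO"), 6),
                        runif(18, 1, 2))
    an1 <- rm_anova(tbl)
    shift <- rep(rnorm(6, sd = 5), each = 3)
    tbl2 <- tbl
    tbl2$D_f <- tbl2$D_f + shift
    an2 <- rm_anova(tbl2)
    expect_equal(an2$statistic, an1$statistic, tolerance = 1e-9)
  })
})

test_that("the parametric p matches a within-subject permutation oracle", {
  withr::with_seed(29, {
    n <- 9
    k <- 4
    tbl <- make_results(rep(paste0("s", 1:n), each = k), "screening",
                        rep(c("baseline", "verbal", "DRO", "NCR"), n),
                        rnorm(n * k, mean = 1.5, sd = 0.2) +
                          rep(c(0, 0.05, 0.12, 0.02), n))
    an <- rm_anova(tbl)
    perm_f <- vapply(1:1500, function(i) {
      tbl$D_f <- unlist(lapply(split(tbl$D_f, tbl$subject_id), sample),
                        use.names = FALSE)
      rm_anova(tbl)$statistic
    }, numeric(1))
    p_perm <- mean(perm_f >= an$statistic)
    expect_lt(abs(p_perm - an$p), 0.06)
  })
})

test_that("incomplete blocks are dropped with a warning", {
  tbl <- make_results(c("a", "a", "b", "b", "c"), "screening",
                      c("baseline", "DRO", "baseline", "DRO", "baseline"),
                      c(1.1, 1.2, 1.4, 1.5, 1.9))
  expect_warning(an <- rm_anova(tbl), "incomplete")
  expect_equal(an$n_subjects, 2)
  expect_error(suppressWarnings(
    rm_anova(tbl[tbl$subject_id == "a", ])), ">= 2 subjects")
})

test_that("Pearson agreement behaves at its fixed points", {
  withr::with_seed(37, {
    t1 <- make_results(paste0("s", 1:50), "screening", "baseline",
                       runif(50, 1, 2))
    # identical tables agree perfectly
    expect_equal(interrater_agreement(t1, t1)$r, 1, tolerance = 1e-12)
    # an unrelated rater decorrelates
    t2 <- t1
    t2$D_f <- runif(50, 1, 2)
    expect_lt(abs(interrater_agreement(t1, t2)$r), 0.35)
    # affine rescaling of one rater leaves r unchanged
    t3 <- t1
    t3$D_f <- 3 * t1$D_f - 1
    expect_equal(interrater_agreement(t1, t3)$r, 1, tolerance = 1e-12)
    expect_error(interrater_agreement(t1[1:2, ], t1[1:2, ]), ">= 3")
  })
})

test_that("degenerate sessions are excluded from group statistics", {
  tbl <- make_results(rep(paste0("s", 1:4), each = 2), "screening",
                      rep(c("baseline", "DRO"), 4), runif(8, 1, 2))
  tbl$degenerate <- c(rep(FALSE, 7), TRUE)
  expect_warning(an <- rm_anova(tbl), "incomplete")
  expect_equal(an$n_subjects, 3)
})
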