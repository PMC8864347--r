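#' Severity-change versus dimension-change analysis
#'
#' For each subject with baseline-condition sessions at both visits, computes
#' the change in fractal dimension between screening and the twelve-month
#' visit, `delta_D_f = D_f(twelve_month) - D_f(screening)`, and the matching
#' change in severity, then the Pearson product-moment correlation between
#' the two with a two-sided t-test p-value (n - 2 degrees of freedom).
#' Effective suppression shows as a negative correlation: subjects whose
#' severity dropped gain dimension (towards the ballistic 2), subjects whose
#' severity rose lose it (towards the Brownian 1).
#'
#' Sessions flagged `degenerate` are excluded (and counted); if a subject
#' has several matching rows per visit (e.g. several raters) their `D_f`
#' and severity are averaged within visit first.
#'
#' @param table a results tibble with columns `subject_id`, `visit`,
#'   `condition`, `D_f`, `severity` (and optionally `degenerate`).
#' @param condition which condition's sessions to difference (default
#'   `"baseline"`, the free-to-tic condition).
#' @return A `df_delta` object: per-subject tibble plus `r`, `p`, `n`,
#'   `n_excluded`.
#' @export
delta_analysis <- function(table, condition = "baseline") {
  required <- c("subject_id", "visit", "condition", "D_f", "severity")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    abort(sprintf("table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  n_before <- nrow(table)
  table <- drop_degenerate(table)
  n_excluded <- n_before - nrow(table)
  cond <- condition
  wide <- table |>
    dplyr::filter(.data$condition == cond) |>
    dplyr::group_by(.data$subject_id, .data$visit) |>
    dplyr::summarise(D_f = mean(.data$D_f), severity = mean(.data$severity),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "visit",
                       values_from = c("D_f", "severity")) |>
    dplyr::filter(stats::complete.cases(
      dplyr::pick(dplyr::everything())))
  needed <- c("D_f_screening", "D_f_twelve_month",
              "severity_screening", "severity_twelve_month")
  if (!all(needed %in% names(wide)) || nrow(wide) < 3) {
    abort("need >= 3 subjects with both visits under the chosen condition")
  }
  per_subject <- tibble(
    subject_id = wide$subject_id,
    delta_D_f = wide$D_f_twelve_month - wide$D_f_screening,
    delta_severity = wide$severity_twelve_month - wide$severity_screening
  )
  if (var(per_subject$delta_severity) == 0 || var(per_subject$delta_D_f) == 0) {
    r <- NA_real_
    p <- NA_real_
    flag <- "zero variance in one of the change scores; r undefined"
  } else {
    ct <- cor.test(per_subject$delta_D_f, per_subject$delta_severity)
    r <- unname(ct$estimate)
    p <- ct$p.value
    flag <- NULL
  }
  structure(list(per_subject = per_subject, r = r, p = p,
                 n = nrow(per_subject), n_excluded = n_excluded,
                 condition = condition, flag = flag),
            class = "df_delta")
}

drop_degenerate <- function(table) {
  if ("degenerate" %in% names(table)) {
    table <- dplyr::filter(table, !.data$degenerate)
  }
  dplyr::filter(table, is.finite(.data$D_f))
}

#' @export
print.df_delta <- function(x, ...) {
  cat(sprintf(
    "<df_delta>  r = %s, p = %s  (n = %d subjects, %s condition%s)\n",
    ifelse(is.na(x$r), "NA", sprintf("%.3f", x$r)),
    ifelse(is.na(x$p), "NA", format.pval(x$p, digits = 3)),
    x$n, x$condition,
    if (x$n_excluded) sprintf(", %d degenerate sessions excluded", x$n_excluded)
    else ""))
  if (!is.null(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' @export
tidy.df_delta <- function(x, ...) x$per_subject

#' @export
glance.df_delta <- function(x, ...) {
  tibble(r = x$r, p = x$p, n = x$n, n_excluded = x$n_excluded)
}

#' Per-condition summary of the fractal dimension
#'
#' Mean `D_f` with a t-based 95% confidence interval for every
#' visit-condition cell. Singleton cells are kept with an `NA` interval and
#' flagged.
#'
#' @param table a results tibble with `visit`, `condition`, `D_f` (and
#'   optionally `degenerate`).
#' @param conf_level confidence level (default 0.95).
#' @return A tibble with `visit`, `condition`, `n`, `mean_D_f`, `ci_lo`,
#'   `ci_hi`, `singleton`.
#' @export
condition_summary <- function(table, conf_level = 0.95) {
  table <- drop_degenerate(table)
  out <- table |>
    dplyr::group_by(.data$visit, .data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean_D_f = mean(.data$D_f),
                     sd_D_f = sd(.data$D_f), .groups = "drop")
  half <- ifelse(out$n >= 2,
                 qt(1 - (1 - conf_level) / 2, out$n - 1) *
                   out$sd_D_f / sqrt(out$n),
                 NA_real_)
  out$ci_lo <- out$mean_D_f - half
  out$ci_hi <- out$mean_D_f + half
  out$singleton <- out$n < 2
  if (any(out$singleton)) {
    warn("singleton visit/condition cell(s): confidence interval undefined")
  }
  dplyr::select(out, -"sd_D_f")
}

#' Plot the per-condition summary
#'
#' @param table a results tibble, passed to [condition_summary()].
#' @param ... passed on to [condition_summary()].
#' @return A ggplot: mean `D_f` per condition with 95% CI error bars,
#'   faceted by visit.
#' @export
plot_condition_summary <- function(table, ...) {
  summ <- condition_summary(table, ...)
  summ$condition <- factor(summ$condition, levels = CONDITION_LEVELS)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$condition,
                                     y = .data$mean_D_f)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::facet_wrap(~visit) +
    ggplot2::labs(x = NULL, y = expression(bar(D)[f])) +
    ggplot2::theme_minimal()
}

#' One-way within-subjects (repeated measures) ANOVA on the dimension
#'
#' Tests whether mean `D_f` differs across suppression conditions while
#' removing the per-subject level. Computed from sums of squares:
#' `SS_condition` (between conditions), `SS_subjects` (between subjects),
#' and `SS_error = SS_within_subjects - SS_condition`, with
#' `F = MS_condition / MS_error` on `(k - 1, (n - 1)(k - 1))` degrees of
#' freedom for `n` subjects and `k` conditions. Subjects lacking any
#' condition are dropped with a warning (complete blocks only); several
#' rows per subject-condition cell (e.g. visits or raters) are averaged.
#'
#' @param table a results tibble with `subject_id`, `condition`, `D_f`.
#' @param value name of the response column (default `"D_f"`).
#' @return An `rm_anova` object with the F statistic, degrees of freedom,
#'   p-value and the sums-of-squares decomposition.
#' @export
rm_anova <- function(table, value = "D_f") {
  table <- drop_degenerate(table)
  cells <- table |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(y = mean(.data[[value]]), .groups = "drop")
  k_all <- length(unique(cells$condition))
  complete <- cells |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == k_all)
  dropped <- setdiff(unique(cells$subject_id), complete$subject_id)
  if (length(dropped)) {
    warn(sprintf("dropping %d subject(s) with incomplete condition blocks",
                 length(dropped)))
    cells <- dplyr::filter(cells, .data$subject_id %in% complete$subject_id)
  }
  n <- length(unique(cells$subject_id))
  k <- length(unique(cells$condition))
  if (k < 2 || n < 2) abort("need >= 2 subjects and >= 2 conditions")
  grand <- mean(cells$y)
  cond_means <- tapply(cells$y, cells$condition, mean)
  subj_means <- tapply(cells$y, cells$subject_id, mean)
  ss_condition <- n * sum((cond_means - grand)^2)
  ss_subjects <- k * sum((subj_means - grand)^2)
  ss_total <- sum((cells$y - grand)^2)
  ss_error <- ss_total - ss_condition - ss_subjects
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_condition <- ss_condition / df1
  ms_error <- ss_error / df2
  f_stat <- if (ms_error > 0) ms_condition / ms_error else
    ifelse(ms_condition > 0, Inf, 0)
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  structure(list(statistic = f_stat, df1 = df1, df2 = df2, p = p,
                 ss = c(condition = ss_condition, subjects = ss_subjects,
                        error = ss_error),
                 n_subjects = n, n_conditions = k,
                 n_dropped = length(dropped)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "<rm_anova>  F(%d, %d) = %.3f, p = %s  (%d subjects x %d conditions%s)\n",
    x$df1, x$df2, x$statistic, format.pval(x$p, digits = 3),
    x$n_subjects, x$n_conditions,
    if (x$n_dropped) sprintf("; %d incomplete dropped", x$n_dropped) else ""))
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(term = c("condition", "subjects", "error"),
         df = c(x$df1, x$n_subjects - 1, x$df2),
         sumsq = unname(x$ss),
         statistic = c(x$statistic, NA, NA),
         p.value = c(x$p, NA, NA))
}

#' @export
glance.rm_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2, p.value = x$p,
         n_subjects = x$n_subjects, n_conditions = x$n_conditions)
}

#' Inter-rater agreement on the fractal dimension
#'
#' Pearson product-moment correlation of `D_f` over sessions matched on
#' subject, visit and condition between two raters' result tables. Sessions
#' degenerate for either rater are excluded.
#'
#' @param table_r1,table_r2 results tibbles (one rater each).
#' @return A list with `r`, `p`, `n` (matched sessions) and the matched
#'   pairs tibble.
#' @export
interrater_agreement <- function(table_r1, table_r2) {
  t1 <- drop_degenerate(table_r1)
  t2 <- drop_degenerate(table_r2)
  keys <- c("subject_id", "visit", "condition")
  pairs <- dplyr::inner_join(
    dplyr::select(t1, dplyr::all_of(keys), D_f_r1 = "D_f"),
    dplyr::select(t2, dplyr::all_of(keys), D_f_r2 = "D_f"),
    by = keys
  )
  if (nrow(pairs) < 3) abort("need >= 3 matched sessions")
  ct <- cor.test(pairs$D_f_r1, pairs$D_f_r2)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs),
       pairs = pairs)
}
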