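#' Midpoint ratio R
#'
#' `R = (rt_n - rt_c) / (rt_i - rt_n)`, the ratio of the neutral-congruent to
#' the incongruent-neutral mean-RT difference. Under the midpoint assumption
#' (neutral RT midway between congruent and incongruent) `R = 1`. The ratio is
#' invariant to adding a common constant to all three RTs and to multiplying
#' all three by a positive constant. Negative values (neutral faster than
#' congruent) are legal and preserved.
#'
#' @param rt_c,rt_n,rt_i Mean RT (ms) of the congruent, neutral and
#'   incongruent conditions; finite and positive. Vectors are accepted and
#'   recycled by position.
#' @return The dimensionless ratio (full precision; round for display).
#' @examples
#' compute_R(638, 646, 714)    # 0.1176...
#' compute_R(400, 450, 500)    # exactly 1
#' @export
compute_R <- function(rt_c, rt_n, rt_i) {
  stopifnot(length(rt_c) == length(rt_n), length(rt_n) == length(rt_i))
  if (!all(is.finite(rt_c), is.finite(rt_n), is.finite(rt_i)) ||
      any(rt_c <= 0) || any(rt_n <= 0) || any(rt_i <= 0)) {
    stop_mp("all RTs must be finite and positive", "invalid_argument")
  }
  denom <- rt_i - rt_n
  if (any(denom == 0)) {
    stop_mp("rt_i equals rt_n: midpoint ratio undefined (degenerate denominator)",
            "undefined_ratio")
  }
  (rt_n - rt_c) / denom
}

#' Midpoint symmetry gap
#'
#' `(rt_n - rt_c) - (rt_i - rt_n) = 2 rt_n - rt_c - rt_i`, in ms; zero exactly
#' when the midpoint assumption holds. Whenever `rt_i > rt_n`, the sign of the
#' gap equals the sign of `R - 1`.
#'
#' @inheritParams compute_R
#' @return The gap in ms (vectorised).
#' @examples
#' midpoint_gap(400, 450, 500)  # 0
#' midpoint_gap(638, 646, 714)  # -60
#' @export
midpoint_gap <- function(rt_c, rt_n, rt_i) {
  if (!all(is.finite(rt_c), is.finite(rt_n), is.finite(rt_i))) {
    stop_mp("all RTs must be finite", "invalid_argument")
  }
  2 * rt_n - rt_c - rt_i
}

#' Aggregate a study-level table of condition means
#'
#' Recomputes `R` for each study from its three condition means, excludes and
#' reports rows with a degenerate denominator (`rt_i == rt_n`), and summarises:
#' overall and per-task counts, the share of studies with `R < 1`, and the
#' per-task median `R`. If the table carries a previously stored `r_printed`
#' column, rows whose stored value disagrees with the recomputation by more
#' than `r_tol` are flagged (never silently corrected).
#'
#' @param records A data frame with columns `study_id`, `task`,
#'   `rt_congruent_ms`, `rt_neutral_ms`, `rt_incongruent_ms`, optionally
#'   `r_printed`.
#' @param r_tol Flagging tolerance against `r_printed` (default 0.001, the
#'   3-decimal convention of published tables).
#' @return An object of class `"study_table_report"`: a list with `table`
#'   (records plus recomputed `r_ratio`), `excluded` (degenerate rows),
#'   `flagged` (stored-vs-recomputed disagreements), `n`, `n_r_lt_1`,
#'   `share_r_lt_1` (percent), `task_counts` and `task_median_r`.
#' @examples
#' rep <- analyze_study_table(load_literature_table())
#' rep$share_r_lt_1  # 86.54
#' @export
analyze_study_table <- function(records, r_tol = 0.001) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_mp("`records` must be a non-empty study-level data frame", "invalid_argument")
  }
  need <- c("study_id", "task", "rt_congruent_ms", "rt_neutral_ms", "rt_incongruent_ms")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_mp(sprintf("study table missing column(s): %s", paste(miss, collapse = ", ")),
            "schema_error")
  }
  degenerate <- records$rt_incongruent_ms == records$rt_neutral_ms
  excluded <- records[degenerate, , drop = FALSE]
  tab <- records[!degenerate, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop_mp("all rows have degenerate denominators", "invalid_argument")
  }
  tab$r_ratio <- compute_R(tab$rt_congruent_ms, tab$rt_neutral_ms,
                           tab$rt_incongruent_ms)
  flagged <- tab[0, , drop = FALSE]
  if ("r_printed" %in% names(tab)) {
    flagged <- tab[abs(tab$r_ratio - tab$r_printed) > r_tol, , drop = FALSE]
  }
  counts <- table(tab$task)
  medians <- vapply(split(tab$r_ratio, tab$task), stats::median, numeric(1))
  structure(list(
    table = tab,
    excluded = excluded,
    flagged = flagged,
    n = nrow(tab),
    n_r_lt_1 = sum(tab$r_ratio < 1),
    share_r_lt_1 = 100 * mean(tab$r_ratio < 1),
    task_counts = counts,
    task_median_r = medians
  ), class = "study_table_report")
}

#' @export
print.study_table_report <- function(x, ...) {
  cat(sprintf("<study table report>  %d studies (%s)\n", x$n,
              paste(sprintf("%s %d", names(x$task_counts), x$task_counts),
                    collapse = ", ")))
  cat(sprintf("  R < 1: %d/%d = %.2f%%\n", x$n_r_lt_1, x$n, x$share_r_lt_1))
  cat("  per-task median R:",
      paste(sprintf("%s %.3f", names(x$task_median_r), x$task_median_r),
            collapse = ", "), "\n")
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded (degenerate denominator): %d row(s)\n", nrow(x$excluded)))
  }
  if (nrow(x$flagged)) {
    cat(sprintf("  flagged (stored R disagrees with recomputation): %s\n",
                paste(x$flagged$study_id, collapse = ", ")))
  }
  invisible(x)
}

#' Subject-level paired midpoint t-test
#'
#' Two-sided paired t-test of each subject's neutral mean RT against the
#' average of that subject's congruent and incongruent mean RTs, with
#' `df = n - 1`. This is the subject-level inference on the midpoint
#' assumption; a negative mean gap indicates a neutral RT closer to the
#' congruent condition.
#'
#' If every per-subject difference is exactly zero the midpoint assumption
#' holds trivially and `t = 0`, `p = 1` is returned; a zero-variance set of
#' differences with nonzero mean is a degenerate-variance error.
#'
#' @param subjects A data frame with one row per subject and columns
#'   `subject_id`, `rt_congruent_ms`, `rt_neutral_ms`, `rt_incongruent_ms`.
#' @return A list of class `"midpoint_ttest"`: `t`, `df`, `p_value`,
#'   `mean_gap` (ms, mean of `rt_n - (rt_c + rt_i)/2`), `n`.
#' @examples
#' cohort <- generate_midpoint_cohort(n_subjects = 30, seed = 5)
#' midpoint_ttest(cohort)
#' @export
midpoint_ttest <- function(subjects) {
  if (!is.data.frame(subjects)) {
    stop_mp("`subjects` must be a data frame of per-subject condition means",
            "invalid_argument")
  }
  need <- c("subject_id", "rt_congruent_ms", "rt_neutral_ms", "rt_incongruent_ms")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) {
    stop_mp(sprintf("subject summary missing column(s): %s",
                    paste(miss, collapse = ", ")), "schema_error")
  }
  n <- nrow(subjects)
  if (n < 2L) {
    stop_mp("at least 2 subjects are required for the paired t-test",
            "insufficient_data")
  }
  if (any(!stats::complete.cases(subjects[, need[-1]]))) {
    stop_mp("every subject needs all three condition means", "invalid_argument")
  }
  diffs <- subjects$rt_neutral_ms -
    (subjects$rt_congruent_ms + subjects$rt_incongruent_ms) / 2
  if (stats::sd(diffs) == 0) {
    if (all(diffs == 0)) {
      out <- list(t = 0, df = n - 1L, p_value = 1, mean_gap = 0, n = n)
      return(structure(out, class = "midpoint_ttest"))
    }
    stop_mp("zero variance of per-subject differences with nonzero mean",
            "degenerate_variance")
  }
  ht <- stats::t.test(diffs, mu = 0, alternative = "two.sided")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_gap = mean(diffs), n = n),
            class = "midpoint_ttest")
}

#' @export
print.midpoint_ttest <- function(x, ...) {
  cat(sprintf("<paired midpoint t-test>  t(%d) = %.3f, p = %.4g, mean gap = %.2f ms (n = %d)\n",
              x$df, x$t, x$p_value, x$mean_gap, x$n))
  invisible(x)
}
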