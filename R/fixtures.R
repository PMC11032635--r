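# Packaged literature table: 52 conflict-task studies (16 flanker, 17 simon,
# 19 stroop) with mean RT per condition as printed, en-dash negatives
# normalised to ASCII minus. The content hash guards the transcription.
LITERATURE_TABLE_MD5 <- "7a160d9de5fcfce44b641847600b8db7"

#' Load the packaged 52-study literature table
#'
#' A transcription of a literature survey of conflict-task studies reporting
#' congruent, neutral and incongruent mean RTs (16 flanker, 17 Simon,
#' 19 Stroop studies). The `r_printed` column carries the R ratio as printed
#' in the source table; [analyze_study_table()] recomputes R from the means
#' and flags rows where the two disagree beyond 0.001 (in five rows the
#' printed ratio was evidently computed from unrounded means and differs
#' slightly from the value implied by the printed means).
#'
#' @return A 52-row data frame with columns `study_id`, `task`,
#'   `rt_congruent_ms`, `rt_neutral_ms`, `rt_incongruent_ms`, `r_printed`.
#' @examples
#' tab <- load_literature_table()
#' table(tab$task)
#' @export
load_literature_table <- function() {
  path <- system.file("extdata", "literature_table.csv", package = "midpointr",
                      mustWork = TRUE)
  hash <- unname(tools::md5sum(path))
  if (!identical(hash, LITERATURE_TABLE_MD5)) {
    stop_mp(sprintf("literature table checksum mismatch (%s): fixture corrupted",
                    hash), "integrity_error")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 52L)
  tab
}

#' Synthetic experiment design
#'
#' Settings for [generate_experiment()]: a cohort of subjects whose trials are
#' simulated from a conflict-diffusion model with log-normal between-subject
#' variability. Each subject receives two multiplicative jitter factors, one
#' on the response threshold and one on the model's controlled-drive parameter
#' (`mu_c` for DMC, `p_target` for SSP, `mu_tar` for DSTP); the factors are
#' `exp(N(0, between_subject_sd))`, hence positive, and a given seed always
#' reproduces the same dataset.
#'
#' @param params Generating model parameters (a `conflict_params` object).
#' @param n_subjects Number of subjects (> 1).
#' @param n_trials_per_condition Trials per condition per subject (> 0).
#' @param between_subject_sd Log-scale SD of the jitter factors (>= 0).
#' @param seed Integer seed.
#' @param dt,max_time Passed to the per-subject [sim_config()].
#' @return A list of class `"synth_design"`.
#' @export
synth_design <- function(params, n_subjects = 40, n_trials_per_condition = 100,
                         between_subject_sd = 0.1, seed = 1, dt = 1,
                         max_time = 3000) {
  if (!inherits(params, "conflict_params")) {
    stop_mp("`params` is not a conflict-model parameter object", "invalid_argument")
  }
  n_subjects <- check_number(n_subjects, "n_subjects", lower = 2)
  n_trials_per_condition <- check_number(n_trials_per_condition,
                                         "n_trials_per_condition", lower = 1)
  between_subject_sd <- check_number(between_subject_sd, "between_subject_sd",
                                     lower = 0)
  structure(list(params = params, n_subjects = as.integer(n_subjects),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 between_subject_sd = between_subject_sd,
                 seed = as.integer(seed), dt = dt, max_time = max_time),
            class = "synth_design")
}

drive_field <- function(family) {
  switch(family, dmc = "mu_c", ssp = "p_target", dstp = "mu_tar")
}

#' Generate a synthetic trial-level experiment
#'
#' For each subject, the generating parameters are jittered (see
#' [synth_design()]) and [simulate_trials()] produces
#' `n_trials_per_condition` trials per condition. Censoring above 5% of all
#' trials triggers a warning.
#'
#' @param design A [synth_design()].
#' @return A trial-level data frame: `subject`, `condition`, `rt_ms`,
#'   `correct`, `censored`.
#' @examples
#' des <- synth_design(preset("dmc_flanker"), n_subjects = 4,
#'                     n_trials_per_condition = 20, seed = 3)
#' head(generate_experiment(des))
#' @export
generate_experiment <- function(design) {
  if (!inherits(design, "synth_design")) {
    stop_mp("`design` must be created with synth_design()", "invalid_argument")
  }
  set.seed(design$seed)
  sds <- design$between_subject_sd
  f_theta <- exp(stats::rnorm(design$n_subjects, 0, sds))
  f_drive <- exp(stats::rnorm(design$n_subjects, 0, sds))
  subject_seeds <- sample.int(2147483646L, design$n_subjects)
  drive <- drive_field(model_family(design$params))
  out <- vector("list", design$n_subjects)
  for (s in seq_len(design$n_subjects)) {
    over <- list(theta_resp = design$params$theta_resp * f_theta[s])
    over[[drive]] <- design$params[[drive]] * f_drive[s]
    p_s <- do.call(update_params, c(list(design$params), over))
    sim <- sim_config(n_trials = design$n_trials_per_condition,
                      seed = subject_seeds[s], dt = design$dt,
                      max_time = design$max_time)
    trials <- do.call(rbind, lapply(conflict_conditions, function(cond) {
      simulate_trials(p_s, cond, sim)
    }))
    out[[s]] <- data.frame(
      subject = sprintf("s%03d", s),
      condition = trials$condition,
      rt_ms = trials$rt_ms,
      correct = ifelse(trials$censored, NA, trials$boundary == "correct"),
      censored = trials$censored,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  cr <- mean(res$censored)
  if (cr > 0.05) {
    warning(sprintf("censoring rate %.1f%% exceeds 5%%", 100 * cr), call. = FALSE)
  }
  res
}

#' Generate a synthetic subject-level cohort with a known midpoint gap
#'
#' Draws per-subject condition means directly (no diffusion simulation):
#' congruent and incongruent means vary across subjects, and the neutral mean
#' is placed at the congruent/incongruent midpoint plus a subject-specific gap
#' `N(true_gap_ms, between_sd_ms)`. Useful for calibrating the power of
#' [midpoint_ttest()] against a known ground truth.
#'
#' @param n_subjects Cohort size (>= 2).
#' @param true_gap_ms Population mean of the midpoint gap (ms); negative means
#'   the neutral RT sits closer to the congruent RT.
#' @param between_sd_ms Between-subject SD of the gap (ms, >= 0).
#' @param base_rt_ms Mean congruent RT across subjects (ms).
#' @param effect_ms Mean congruency effect, incongruent minus congruent (ms).
#' @param subject_sd_ms Between-subject SD of the congruent mean (ms).
#' @param seed Integer seed.
#' @return A subject-summary data frame suitable for [midpoint_ttest()].
#' @export
generate_midpoint_cohort <- function(n_subjects = 50, true_gap_ms = -30,
                                     between_sd_ms = 20, base_rt_ms = 450,
                                     effect_ms = 60, subject_sd_ms = 40,
                                     seed = 1) {
  n_subjects <- as.integer(check_number(n_subjects, "n_subjects", lower = 2))
  set.seed(as.integer(seed))
  rt_c <- stats::rnorm(n_subjects, base_rt_ms, subject_sd_ms)
  rt_i <- rt_c + stats::rnorm(n_subjects, effect_ms, subject_sd_ms / 4)
  gap <- stats::rnorm(n_subjects, true_gap_ms, between_sd_ms)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n_subjects)),
    rt_congruent_ms = rt_c,
    rt_neutral_ms = (rt_c + rt_i) / 2 + gap,
    rt_incongruent_ms = rt_i,
    stringsAsFactors = FALSE
  )
}

#' Per-subject condition means from trial-level data
#'
#' Applies the RT trimming window, keeps correct uncensored trials, and
#' averages RT per subject and condition, returning the wide subject-summary
#' layout used by [midpoint_ttest()]. Subjects lacking trials in any condition
#' after filtering are dropped with a warning.
#'
#' @param trials Trial-level data frame with columns `subject`, `condition`,
#'   `rt_ms`, `correct` (and optionally `censored`).
#' @param trim_lower_ms,trim_upper_ms RT trimming bounds (ms); trials outside
#'   `[trim_lower_ms, trim_upper_ms]` are removed before averaging.
#' @return A subject-summary data frame (`subject_id` plus the three
#'   condition-mean columns).
#' @export
subject_condition_means <- function(trials, trim_lower_ms = 200,
                                    trim_upper_ms = 2000) {
  need <- c("subject", "condition", "rt_ms", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop_mp(sprintf("trial data missing column(s): %s", paste(miss, collapse = ", ")),
            "schema_error")
  }
  keep <- !is.na(trials$correct) & trials$correct &
    trials$rt_ms >= trim_lower_ms & trials$rt_ms <= trim_upper_ms
  if ("censored" %in% names(trials)) keep <- keep & !trials$censored
  d <- trials[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop_mp("no trials left after filtering", "insufficient_data")
  agg <- stats::aggregate(rt_ms ~ subject + condition, data = d, FUN = mean)
  wide <- stats::reshape(agg, idvar = "subject", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^rt_ms\\.", "", names(wide))
  miss_cond <- setdiff(conflict_conditions, names(wide))
  if (length(miss_cond)) {
    stop_mp(sprintf("no trials for condition(s): %s",
                    paste(miss_cond, collapse = ", ")), "insufficient_data")
  }
  complete <- stats::complete.cases(wide[, conflict_conditions])
  if (!all(complete)) {
    warning(sprintf("dropping %d subject(s) lacking trials in some condition",
                    sum(!complete)), call. = FALSE)
    wide <- wide[complete, , drop = FALSE]
  }
  data.frame(
    subject_id = wide$subject,
    rt_congruent_ms = wide$congruent,
    rt_neutral_ms = wide$neutral,
    rt_incongruent_ms = wide$incongruent,
    stringsAsFactors = FALSE
  )
}
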