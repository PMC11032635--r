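#' Simulation configuration
#'
#' Settings for the Euler-Maruyama first-passage sampler.
#'
#' @param n_trials Trials per condition (> 0).
#' @param seed Integer RNG seed. Each condition draws from its own substream,
#'   derived deterministically from this seed, so conditions are independently
#'   reproducible.
#' @param dt Integration step (ms, in (0, 5]).
#' @param max_time Censoring horizon (ms, >= 10 * dt). Trials still unabsorbed
#'   at the horizon are returned censored.
#' @param start_z Initial evidence (default 0, midway between the symmetric
#'   boundaries).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_trials = 1000, seed = 1, dt = 1, max_time = 3000,
                       start_z = 0) {
  n_trials <- check_number(n_trials, "n_trials", lower = 1)
  if (n_trials != round(n_trials)) {
    stop_mp("`n_trials` must be a whole number", "invalid_argument")
  }
  dt <- check_number(dt, "dt", lower = 0, upper = 5, strict_lower = TRUE)
  max_time <- check_number(max_time, "max_time", lower = 10 * dt)
  seed <- check_number(seed, "seed")
  structure(list(n_trials = as.integer(n_trials), seed = as.integer(seed),
                 dt = dt, max_time = max_time, start_z = as.numeric(start_z)),
            class = "sim_config")
}

# Vectorised Euler-Maruyama first passage through symmetric boundaries
# +/- theta for a drift that depends on time only. Drift is evaluated at step
# midpoints, which also keeps DMC away from its t = 0 singularity.
euler_fpt <- function(drift_at, n, dt, max_time, theta, sigma, start) {
  n_steps <- ceiling(max_time / dt)
  v <- drift_at((seq_len(n_steps) - 0.5) * dt)
  decision <- rep(NA_real_, n)
  boundary <- rep(NA_integer_, n)
  alive <- seq_len(n)
  x <- rep(start, n)
  sq <- sigma * sqrt(dt)
  for (k in seq_len(n_steps)) {
    m <- length(alive)
    if (m == 0L) break
    x <- x + v[k] * dt + (if (sq > 0) sq * stats::rnorm(m) else 0)
    up <- x >= theta
    lo <- x <= -theta
    hit <- up | lo
    if (any(hit)) {
      id <- alive[hit]
      decision[id] <- k * dt
      boundary[id] <- ifelse(up[hit], 1L, -1L)
      alive <- alive[!hit]
      x <- x[!hit]
    }
  }
  list(decision_ms = decision, boundary = boundary)
}

# DSTP: the response diffusion runs alongside an independent stimulus-selection
# diffusion (drift mu_ss, thresholds +/- theta_sel, same sigma). When selection
# absorbs, the response drift switches to the phase-2 rate; +theta_sel means
# the target was selected, -theta_sel a flanker. A flanker selected on a
# neutral trial yields phase-2 drift 0 and the trial is flagged.
euler_fpt_dstp <- function(params, condition, n, dt, max_time, start) {
  v1 <- dstp_drift(params, condition, phase = "rs1")
  v2_target <- dstp_drift(params, condition, phase = "rs2", selected = "target")
  v2_flanker <- dstp_drift(params, condition, phase = "rs2", selected = "flanker")
  n_steps <- ceiling(max_time / dt)
  decision <- rep(NA_real_, n)
  boundary <- rep(NA_integer_, n)
  flagged <- rep(FALSE, n)
  alive <- seq_len(n)
  x <- rep(start, n)
  s <- rep(0, n)               # selection evidence
  vresp <- rep(v1, n)
  selecting <- rep(TRUE, n)    # selection diffusion still running
  sq <- params$sigma * sqrt(dt)
  theta <- params$theta_resp
  for (k in seq_len(n_steps)) {
    m <- length(alive)
    if (m == 0L) break
    noise <- if (sq > 0) sq * stats::rnorm(m) else 0
    x <- x + vresp * dt + noise
    sel <- selecting
    if (any(sel)) {
      s[sel] <- s[sel] + params$mu_ss * dt +
        (if (sq > 0) sq * stats::rnorm(sum(sel)) else 0)
      done_t <- sel & s >= params$theta_sel
      done_f <- sel & s <= -params$theta_sel
      if (any(done_t)) {
        vresp[done_t] <- v2_target
        selecting[done_t] <- FALSE
      }
      if (any(done_f)) {
        vresp[done_f] <- v2_flanker
        selecting[done_f] <- FALSE
        if (condition == "neutral") flagged[alive[done_f]] <- TRUE
      }
    }
    up <- x >= theta
    lo <- x <= -theta
    hit <- up | lo
    if (any(hit)) {
      id <- alive[hit]
      decision[id] <- k * dt
      boundary[id] <- ifelse(up[hit], 1L, -1L)
      keep <- !hit
      alive <- alive[keep]
      x <- x[keep]
      s <- s[keep]
      vresp <- vresp[keep]
      selecting <- selecting[keep]
    }
  }
  list(decision_ms = decision, boundary = boundary, flagged = flagged)
}

#' Simulate trials of a conflict-diffusion model
#'
#' Euler-Maruyama first-passage sampling of the model's evidence accumulator:
#' `X <- X + v(t) dt + sigma sqrt(dt) Z`, absorbed at `+/- theta_resp`. The
#' correct response is the `+theta_resp` boundary by convention; on neutral
#' trials either boundary terminates the trial and `+theta_resp` is still
#' labelled correct. For DSTP the stimulus-selection diffusion runs
#' concurrently and switches the response drift to the phase-2 rate on
#' absorption. With `sigma = 0` every trial reproduces the deterministic
#' [first_crossing()] time to within one `dt`.
#'
#' @param params A conflict-model parameter object.
#' @param condition One of [conflict_conditions].
#' @param sim A [sim_config()].
#' @return A data frame with one row per trial: `condition`, `decision_ms`
#'   (first-passage time, `NA` if censored), `rt_ms` (`decision_ms + ter`),
#'   `boundary` (`"correct"`/`"error"`, `NA` if censored), `censored`, and
#'   `flagged` (DSTP neutral trials whose selection diffusion absorbed at the
#'   flanker boundary).
#' @examples
#' p <- preset("dmc_flanker")
#' trials <- simulate_trials(p, "incongruent", sim_config(n_trials = 100, seed = 7))
#' summarize_trials(trials)
#' @export
simulate_trials <- function(params, condition, sim = sim_config()) {
  if (!inherits(params, "conflict_params")) {
    stop_mp("`params` is not a conflict-model parameter object", "invalid_argument")
  }
  check_condition(condition)
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  set.seed(substream_seed(sim$seed, condition))
  family <- model_family(params)
  if (family == "dstp") {
    res <- euler_fpt_dstp(params, condition, sim$n_trials, sim$dt,
                          sim$max_time, sim$start_z)
  } else {
    drift_at <- switch(family,
      ssp = function(tt) ssp_drift(params, condition, tt),
      dmc = function(tt) dmc_drift(params, condition, tt)
    )
    res <- euler_fpt(drift_at, sim$n_trials, sim$dt, sim$max_time,
                     params$theta_resp, params$sigma, sim$start_z)
    res$flagged <- rep(FALSE, sim$n_trials)
  }
  censored <- is.na(res$decision_ms)
  data.frame(
    condition = condition,
    decision_ms = res$decision_ms,
    rt_ms = res$decision_ms + params$ter,
    boundary = ifelse(censored, NA_character_,
                      ifelse(res$boundary == 1L, "correct", "error")),
    censored = censored,
    flagged = res$flagged,
    stringsAsFactors = FALSE
  )
}

#' Per-condition summary of simulated trials
#'
#' Mean RT is computed over correct, uncensored trials (matching the standard
#' correct-RT analyses); accuracy is correct / (correct + error) among
#' uncensored trials; the censoring rate is reported separately.
#'
#' @param trials A trial data frame as returned by [simulate_trials()] or
#'   [generate_experiment()].
#' @return A data frame with one row per condition: `condition`, `n`,
#'   `n_correct`, `n_error`, `n_censored`, `accuracy`, `mean_rt_ms`,
#'   `censor_rate`.
#' @export
summarize_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    stop_mp("`trials` must be a non-empty trial data frame", "invalid_argument")
  }
  need <- c("condition", "rt_ms", "boundary", "censored")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop_mp(sprintf("trial data missing column(s): %s", paste(miss, collapse = ", ")),
            "schema_error")
  }
  out <- do.call(rbind, lapply(split(trials, trials$condition), function(d) {
    ok <- !d$censored
    correct <- ok & d$boundary == "correct"
    error <- ok & d$boundary == "error"
    if (!any(correct)) {
      stop_mp(sprintf("no uncensored correct trials for condition '%s'",
                      d$condition[1]), "insufficient_data")
    }
    data.frame(
      condition = d$condition[1],
      n = nrow(d),
      n_correct = sum(correct),
      n_error = sum(error),
      n_censored = sum(!ok),
      accuracy = sum(correct) / sum(ok),
      mean_rt_ms = mean(d$rt_ms[correct]),
      censor_rate = mean(!ok),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  present <- intersect(conflict_conditions, out$condition)
  out[match(present, out$condition), , drop = FALSE]
}

#' Monte Carlo midpoint ratio
#'
#' Simulates the three conditions, applies the midpoint ratio
#' `R = (RT_N - RT_C) / (RT_I - RT_N)` to the per-condition mean correct RTs,
#' and attaches a nonparametric bootstrap standard error (resampling trials
#' within condition).
#'
#' @param params A conflict-model parameter object.
#' @param sim A [sim_config()]; `n_trials` must be at least 10 per condition.
#' @param n_boot Bootstrap resamples for the standard error.
#' @return A list of class `"simulated_R"`: `r_ratio`, `se` (bootstrap),
#'   `n_boot`, `summary` (the per-condition summary data frame) and
#'   `n_trials`.
#' @examples
#' simulated_R(preset("dmc_flanker"), sim_config(n_trials = 500, seed = 11))
#' @export
simulated_R <- function(params, sim = sim_config(), n_boot = 200) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  if (sim$n_trials < 10L) {
    stop_mp("`n_trials` must be at least 10 per condition", "invalid_argument")
  }
  trials <- do.call(rbind, lapply(conflict_conditions, function(cond) {
    simulate_trials(params, cond, sim)
  }))
  summ <- summarize_trials(trials)
  rts <- lapply(conflict_conditions, function(cond) {
    d <- trials[trials$condition == cond & !trials$censored &
                  trials$boundary == "correct", "rt_ms"]
    d[!is.na(d)]
  })
  names(rts) <- conflict_conditions
  means <- vapply(rts, mean, numeric(1))
  denom <- means[["incongruent"]] - means[["neutral"]]
  if (denom == 0) {
    stop_mp("mean incongruent RT equals mean neutral RT: ratio undefined",
            "undefined_ratio")
  }
  r_hat <- (means[["neutral"]] - means[["congruent"]]) / denom
  set.seed(substream_seed(sim$seed + 1L, "neutral"))
  r_boot <- vapply(seq_len(n_boot), function(b) {
    m <- vapply(rts, function(v) mean(v[sample.int(length(v), replace = TRUE)]),
                numeric(1))
    (m[["neutral"]] - m[["congruent"]]) / (m[["incongruent"]] - m[["neutral"]])
  }, numeric(1))
  structure(list(r_ratio = unname(r_hat), se = stats::sd(r_boot),
                 n_boot = n_boot, summary = summ, n_trials = sim$n_trials),
            class = "simulated_R")
}

#' @export
print.simulated_R <- function(x, ...) {
  cat(sprintf("<Monte Carlo midpoint ratio>  R = %.4f  (bootstrap SE %.4f, %d trials/condition)\n",
              x$r_ratio, x$se, x$n_trials))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
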