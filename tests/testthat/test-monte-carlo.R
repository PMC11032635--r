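test_that("noise-free simulation reproduces the deterministic crossing", {
  for (p in list(dmc_toy(sigma = 0), ssp_toy(sigma = 0), dstp_toy(sigma = 0))) {
    for (cond in conflict_conditions) {
      tr <- simulate_trials(p, cond, sim_config(n_trials = 3, seed = 1, dt = 1))
      det <- first_crossing(p, cond)
      expect_true(all(abs(tr$decision_ms - det) <= 1 + 1e-9))
      expect_true(all(tr$boundary == "correct"))
      expect_false(any(tr$censored))
    }
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  p <- preset("dmc_flanker")
  sim <- sim_config(n_trials = 200, seed = 77)
  a <- simulate_trials(p, "incongruent", sim)
  b <- simulate_trials(p, "incongruent", sim)
  expect_identical(a, b)
  # per-condition substreams: another condition's draw does not disturb it
  invisible(simulate_trials(p, "congruent", sim))
  expect_identical(simulate_trials(p, "incongruent", sim), a)
})

test_that("rt is decision time plus non-decision time and censoring is flagged", {
  p <- dmc_toy(sigma = 4, ter = 300)
  tr <- simulate_trials(p, "congruent", sim_config(n_trials = 500, seed = 5))
  ok <- !tr$censored
  expect_equal(tr$rt_ms[ok], tr$decision_ms[ok] + 300)
  expect_true(all(tr$rt_ms[ok] >= 300))
  # an impossibly tight horizon censors everything
  slow <- dmc_params(amp_A = 0.01, tau = 30, mu_c = 0.001, theta_resp = 75,
                     sigma = 0.01)
  tr2 <- simulate_trials(slow, "neutral", sim_config(n_trials = 20, seed = 2,
                                                     dt = 1, max_time = 50))
  expect_true(all(tr2$censored))
  expect_true(all(is.na(tr2$boundary)))
})

test_that("summarize_trials applies the correct-trial convention", {
  toy <- data.frame(condition = "neutral", rt_ms = rep(400, 5),
                    boundary = "correct", censored = FALSE)
  s <- summarize_trials(toy)
  expect_equal(s$mean_rt_ms, 400)
  expect_equal(s$accuracy, 1)
  mixed <- data.frame(condition = "neutral",
                      rt_ms = c(400, 400, 1000, 300),
                      boundary = c("correct", "correct", "error", "error"),
                      censored = FALSE)
  s2 <- summarize_trials(mixed)
  expect_equal(s2$accuracy, 0.5)
  expect_equal(s2$mean_rt_ms, 400)  # error RTs never enter the mean
  expect_error(summarize_trials(mixed[0, ]), class = "invalid_argument")
  only_err <- data.frame(condition = "neutral", rt_ms = 300,
                         boundary = "error", censored = FALSE)
  expect_error(summarize_trials(only_err), class = "insufficient_data")
})

test_that("DMC simulation orders conditions as congruent < neutral < incongruent", {
  s <- summarize_trials(do.call(rbind, lapply(conflict_conditions, function(cc) {
    simulate_trials(preset("dmc_flanker"), cc, sim_config(n_trials = 10000, seed = 31))
  })))
  m <- s$mean_rt_ms[match(conflict_conditions, s$condition)]
  expect_lt(m[1], m[2])
  expect_lt(m[2], m[3])
  acc <- s$accuracy[match(conflict_conditions, s$condition)]
  expect_gte(acc[1], acc[3])
})

test_that("halving dt leaves mean RTs stable", {
  for (nm in c("ssp_flanker", "dmc_flanker")) {
    p <- preset(nm)
    m <- sapply(c(1, 0.5), function(dd) {
      s <- summarize_trials(do.call(rbind, lapply(conflict_conditions, function(cc) {
        simulate_trials(p, cc, sim_config(n_trials = 20000, seed = 21, dt = dd))
      })))
      s$mean_rt_ms
    })
    expect_lt(max(abs(m[, 1] - m[, 2])), 2)
  }
  # the coupled selection diffusion makes DSTP more step-size sensitive
  p <- preset("dstp_flanker")
  m <- sapply(c(1, 0.5), function(dd) {
    s <- summarize_trials(do.call(rbind, lapply(conflict_conditions, function(cc) {
      simulate_trials(p, cc, sim_config(n_trials = 20000, seed = 21, dt = dd))
    })))
    s$mean_rt_ms
  })
  expect_lt(max(abs(m[, 1] - m[, 2])), 5)
})

test_that("censoring is rare at a 3000 ms horizon for all presets", {
  for (nm in list_presets()) {
    tr <- do.call(rbind, lapply(conflict_conditions, function(cc) {
      simulate_trials(preset(nm), cc, sim_config(n_trials = 2000, seed = 3))
    }))
    expect_lt(mean(tr$censored), 0.01)
  }
})

test_that("simulated_R matches the deterministic ratio in the noise-free limit", {
  p <- dmc_toy(sigma = 0)
  sr <- simulated_R(p, sim_config(n_trials = 10, seed = 1, dt = 0.1))
  det <- predict_R(p)$r_ratio
  # dt-rounding of three crossing times bounds the discrepancy
  expect_equal(sr$r_ratio, det, tolerance = 0.1)
  expect_error(simulated_R(p, sim_config(n_trials = 5, seed = 1)),
               class = "invalid_argument")
})

test_that("simulated DMC ratio exceeds one with noise", {
  sr <- simulated_R(preset("dmc_flanker"), sim_config(n_trials = 20000, seed = 9))
  expect_gt(sr$r_ratio, 1)
  expect_true(is.finite(sr$se) && sr$se > 0)
})

test_that("DSTP neutral trials with flanker selection are flagged, not dropped", {
  p <- preset("dstp_flanker")
  tr <- simulate_trials(p, "neutral", sim_config(n_trials = 4000, seed = 13))
  expect_true(any(tr$flagged))
  expect_false(any(simulate_trials(p, "congruent",
                                   sim_config(n_trials = 500, seed = 13))$flagged))
})
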