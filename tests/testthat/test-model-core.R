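test_that("DSTP drift follows the two-phase rules", {
  p <- dstp_params(mu_tar = 0.1, mu_fl = 0.05, mu_rs2 = 0.2, mu_ss = 0.5,
                   theta_resp = 50, theta_sel = 50)
  expect_equal(dstp_drift(p, "congruent", "rs1"), 0.15)
  expect_equal(dstp_drift(p, "incongruent", "rs1"), 0.05)
  expect_equal(dstp_drift(update_params(p, mu_fl = 0), "neutral", "rs1"), 0.1)
  # neutral ignores mu_fl entirely (zero-weight flankers)
  expect_equal(dstp_drift(p, "neutral", "rs1"), 0.1)
  expect_equal(dstp_drift(p, "incongruent", "rs2", selected = "flanker"), -0.2)
  expect_equal(dstp_drift(p, "congruent", "rs2", selected = "flanker"), 0.2)
  expect_equal(dstp_drift(p, "incongruent", "rs2", selected = "target"), 0.2)
  # flanker "selected" on a neutral trial carries no response information
  expect_equal(dstp_drift(p, "neutral", "rs2", selected = "flanker"), 0)
  expect_error(dstp_drift(p, "congruent", "rs3"), class = "invalid_argument")
  expect_error(dstp_drift(p, "congruent", "rs2"), class = "invalid_argument")
  expect_error(dstp_drift(p, "sideways", "rs1"), class = "invalid_argument")
})

test_that("spotlight width shrinks linearly and is floored at zero", {
  p <- ssp_toy()
  expect_equal(ssp_attention_width(p, 0), 1.8)
  expect_equal(ssp_attention_width(p, 50), 0.9)
  expect_equal(ssp_attention_width(p, 100), 0)
  expect_equal(ssp_attention_width(p, 500), 0)
  t <- seq(0, 200, by = 5)
  expect_true(all(diff(ssp_attention_width(p, t)) <= 0))
  expect_error(ssp_attention_width(p, -1), class = "invalid_argument")
})

test_that("attention areas are the Gaussian region masses", {
  # unit width at all times: r_d = 0 keeps sd_a fixed
  p <- ssp_params(p_outer = 1, p_inner = 1, p_target = 1, sd_a = 1, r_d = 0,
                  theta_resp = 1)
  a <- ssp_areas(p, 10)
  expect_equal(unname(a["a_target"]), 2 * pnorm(0.5) - 1, tolerance = 1e-12)
  expect_equal(unname(a["a_outer"]), pnorm(-1.5), tolerance = 1e-12)
  expect_equal(unname(a["a_inner"]), pnorm(-0.5) - pnorm(-1.5), tolerance = 1e-12)
  # collapsed spotlight sits entirely on the target
  pc <- ssp_toy()
  expect_equal(unname(ssp_areas(pc, 100)), c(0, 0, 1))
})

test_that("areas plus their mirror images integrate to one", {
  for (w in c(3, 1.8, 0.9, 0.31, 0.05, 0.004)) {
    p <- ssp_params(p_outer = 1, p_inner = 1, p_target = 1, sd_a = w, r_d = 0,
                    theta_resp = 1)
    a <- ssp_areas(p, 0)
    expect_equal(unname(2 * a["a_outer"] + 2 * a["a_inner"] + a["a_target"]), 1,
                 tolerance = 1e-10)
  }
})

test_that("SSP drift weights the flanker term by condition sign", {
  p <- ssp_toy()
  # t <= 75: beyond that the flanker mass underflows against the target term
  t <- c(0, 25, 50, 75)
  a <- ssp_areas(p, t)
  expect_equal(ssp_drift(p, "neutral", t), p$p_target * a[, "a_target"],
               ignore_attr = TRUE)
  # collapsed spotlight: only the target survives
  expect_equal(ssp_drift(p, "congruent", 150), p$p_target)
  expect_equal(ssp_drift(p, "incongruent", 150), p$p_target)
  # biased neutral exceeds the zero-influence neutral wherever flankers have mass
  pb <- ssp_toy(bias_b = 0.5)
  expect_true(all(ssp_drift(pb, "neutral", t) > ssp_drift(p, "neutral", t)))
  # congruent drift is non-decreasing; incongruent recovers towards p_target
  tt <- seq(0, 200, by = 1)
  expect_true(all(diff(ssp_drift(p, "congruent", tt)) >= -1e-15))
  vi <- ssp_drift(p, "incongruent", tt)
  expect_lt(vi[1], 0)
  expect_equal(vi[length(vi)], p$p_target, tolerance = 1e-12)
})

test_that("DMC drift superimposes pulse derivative and controlled process", {
  p <- dmc_toy()
  # at t = (a-1)*tau the pulse is at its maximum: derivative term vanishes
  expect_equal(dmc_drift(p, "congruent", 30), p$mu_c, tolerance = 1e-12)
  expect_equal(dmc_drift(p, "neutral", c(1, 50, 400)), rep(p$mu_c, 3))
  t <- c(5, 20, 80, 200)
  expect_equal(dmc_drift(p, "congruent", t) - dmc_drift(p, "incongruent", t),
               2 * (dmc_drift(p, "congruent", t) - p$mu_c), tolerance = 1e-12)
  expect_error(dmc_drift(p, "congruent", 0), class = "invalid_argument")
  expect_error(dmc_drift(p, "congruent", -5), class = "invalid_argument")
  # concave controlled process decays exponentially
  pc <- dmc_toy(curvature_c = 0.01)
  expect_equal(dmc_drift(pc, "neutral", 100), 0.5 * exp(-1), tolerance = 1e-12)
})

test_that("expected accumulation matches quadrature of the drift", {
  t <- c(0, 1, 12.5, 60, 101, 137, 250, 400, 800, 1000)
  for (p in list(dmc_toy(), dmc_toy(curvature_c = 0.004, shape_a = 3),
                 ssp_toy(), ssp_toy(bias_b = 0.4), dstp_toy())) {
    for (cond in conflict_conditions) {
      got <- expected_accumulation(p, cond, t)
      want <- quad_accum(p, cond, t)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("DMC pulse component peaks at amplitude A at t = (a-1)*tau", {
  grid <- seq(1, 1200, by = 0.5)
  for (tau in c(20, 75, 150)) {
    for (a in c(1.5, 2, 3)) {
      p <- dmc_params(amp_A = 25, tau = tau, shape_a = a, mu_c = 0.5,
                      theta_resp = 75)
      pulse_at <- function(t) {
        expected_accumulation(p, "congruent", t) -
          expected_accumulation(p, "neutral", t)
      }
      expect_equal(pulse_at((a - 1) * tau), 25, tolerance = 1e-9)
      pulse <- pulse_at(grid)
      expect_true(all(pulse <= 25 + 1e-9))
      expect_equal(grid[which.max(pulse)], (a - 1) * tau, tolerance = 0.5)
    }
  }
})

test_that("concave controlled accumulation is concave and bounded by mu_c / c", {
  p <- dmc_toy(curvature_c = 0.005)
  t <- seq(0, 3000, by = 10)
  e <- expected_accumulation(p, "neutral", t)
  expect_true(all(diff(diff(e)) < 0))
  expect_true(all(e < p$mu_c / p$curvature_c))
  # c -> 0 recovers the linear controlled process
  p_tiny <- dmc_toy(curvature_c = 1e-12)
  p_zero <- dmc_toy(curvature_c = 0)
  expect_equal(expected_accumulation(p_tiny, "neutral", 500),
               expected_accumulation(p_zero, "neutral", 500),
               tolerance = 1e-9)
})

test_that("accumulation starts at zero and parameter validation bites", {
  for (p in list(dmc_toy(), ssp_toy(), dstp_toy())) {
    expect_equal(expected_accumulation(p, "congruent", 0), 0)
  }
  expect_error(dmc_params(amp_A = 20, tau = 30, shape_a = 1, mu_c = 0.5,
                          theta_resp = 75), class = "invalid_argument")
  expect_error(ssp_params(p_outer = 1, p_inner = 1, p_target = 1, sd_a = 1.8,
                          r_d = 0.018, bias_b = 1, theta_resp = 0.05),
               class = "invalid_argument")
  expect_error(dstp_params(mu_tar = 0.1, mu_fl = -0.1, mu_rs2 = 0.2,
                           mu_ss = 0.5, theta_resp = 50, theta_sel = 50),
               class = "invalid_argument")
  expect_error(update_params(dmc_toy(), nonsense = 1), class = "invalid_argument")
})

test_that("presets load, list and override", {
  expect_true(all(c("dstp_flanker", "ssp_flanker", "dmc_flanker") %in% list_presets()))
  p <- preset("dmc_flanker")
  expect_s3_class(p, "dmc_params")
  expect_identical(model_family(p), "dmc")
  p2 <- preset("dmc_flanker", curvature_c = 0.002)
  expect_equal(p2$curvature_c, 0.002)
  expect_error(preset("no_such_preset"), class = "config_error")
  expect_error(preset("no_such_preset"), "available presets")
})
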