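# Shared fixtures and independent oracles for the test suite.

# Small parameter sets with convenient round-number crossings.
dstp_toy <- function(...) {
  update_params(dstp_params(mu_tar = 0.1, mu_fl = 0.1, mu_rs2 = 0.2,
                            mu_ss = 0.5, theta_resp = 50, theta_sel = 50), ...)
}

dmc_toy <- function(...) {
  update_params(dmc_params(amp_A = 20, tau = 30, shape_a = 2, mu_c = 0.5,
                           theta_resp = 75), ...)
}

ssp_toy <- function(...) {
  update_params(ssp_params(p_outer = 4e-4, p_inner = 4e-4, p_target = 4e-4,
                           sd_a = 1.8, r_d = 0.018, theta_resp = 0.05), ...)
}

# Independent accumulation oracle: adaptive quadrature of the drift function,
# splitting at the model's kink points (DSTP phase switch, SSP spotlight
# collapse) so the integrator only ever sees smooth pieces.
quad_accum <- function(params, condition, t) {
  fam <- model_family(params)
  drift <- switch(fam,
    dmc = function(s) dmc_drift(params, condition, s),
    ssp = function(s) ssp_drift(params, condition, s),
    dstp = {
      t_sel <- params$theta_sel / params$mu_ss
      v1 <- dstp_drift(params, condition, "rs1")
      function(s) ifelse(s <= t_sel, v1, params$mu_rs2)
    }
  )
  kinks <- switch(fam,
    dstp = params$theta_sel / params$mu_ss,
    ssp = if (params$r_d > 0) params$sd_a / params$r_d else numeric(),
    dmc = numeric()
  )
  vapply(t, function(tt) {
    if (tt == 0) return(0)
    pts <- sort(unique(c(0, kinks[kinks < tt], tt)))
    total <- 0
    for (i in seq_len(length(pts) - 1L)) {
      lo <- max(pts[i], 1e-12)  # DMC drift is singular at 0; integrand is integrable
      total <- total + stats::integrate(drift, lo, pts[i + 1L],
                                        rel.tol = 1e-10, abs.tol = 1e-13,
                                        subdivisions = 400L)$value
    }
    total
  }, numeric(1))
}

# Independent crossing oracle: dense grid scan of expected accumulation.
fine_grid_crossing <- function(params, condition, horizon = 600, dt = 0.001) {
  g <- seq(dt, horizon, by = dt)
  e <- expected_accumulation(params, condition, g)
  idx <- which(e >= params$theta_resp)[1L]
  if (is.na(idx)) NA_real_ else g[idx]
}
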