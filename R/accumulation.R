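#' Expected evidence accumulation
#'
#' The noise-free (expected) accumulated evidence at time `t` for a given
#' model and condition; the deterministic path whose threshold crossing defines
#' the model's predicted decision time.
#'
#' * **DMC**: closed form, `s * pulse(t) + controlled(t)` where `pulse(t)` is
#'   the gamma-shaped automatic activation (maximum `amp_A` at
#'   `t = (shape_a - 1) * tau`) and the controlled part is `mu_c * t`
#'   (`curvature_c = 0`) or `(mu_c / curvature_c) * (1 - exp(-curvature_c t))`.
#' * **SSP**: numerical integral of [ssp_drift()] from 0 to `t` (composite
#'   trapezoid at 0.01 ms while the spotlight is shrinking, exact linear tail
#'   with slope `p_target` after it has collapsed).
#' * **DSTP**: piecewise-linear across the two phases, with the deterministic
#'   stimulus-selection time `theta_sel / mu_ss` and target selection (the
#'   noise-free selection diffusion always absorbs at the target boundary).
#'
#' @param params A conflict-model parameter object.
#' @param condition One of [conflict_conditions].
#' @param t Time(s) since onset (ms, >= 0).
#' @return Expected evidence (same length as `t`); 0 at `t = 0`.
#' @export
expected_accumulation <- function(params, condition, t) {
  UseMethod("expected_accumulation")
}

check_time_vec <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)) || any(t < 0)) {
    stop_mp("`t` must be non-negative and finite", "invalid_argument")
  }
  as.numeric(t)
}

#' @export
expected_accumulation.dmc_params <- function(params, condition, t) {
  check_condition(condition)
  t <- check_time_vec(t)
  s <- switch(condition, congruent = 1, incongruent = -1, neutral = 0)
  cc <- params$curvature_c
  controlled <- if (cc == 0) params$mu_c * t else params$mu_c * (-expm1(-cc * t)) / cc
  s * dmc_pulse(params, t) + controlled
}

#' @export
expected_accumulation.dstp_params <- function(params, condition, t) {
  check_condition(condition)
  t <- check_time_vec(t)
  v1 <- dstp_drift(params, condition, phase = "rs1")
  t_sel <- params$theta_sel / params$mu_ss
  v1 * pmin(t, t_sel) + params$mu_rs2 * pmax(t - t_sel, 0)
}

#' @export
expected_accumulation.ssp_params <- function(params, condition, t) {
  check_condition(condition)
  t <- check_time_vec(t)
  t0 <- if (params$r_d > 0) params$sd_a / params$r_d else Inf
  tcap <- pmin(t, t0)
  tmax <- max(tcap)
  out <- numeric(length(t))
  if (tmax > 0) {
    h <- 0.01
    grid <- seq(0, tmax, by = h)
    if (grid[length(grid)] < tmax) grid <- c(grid, tmax)
    vals <- ssp_drift(params, condition, grid)
    cum <- c(0, cumsum(diff(grid) * (vals[-1L] + vals[-length(vals)]) / 2))
    out <- stats::approx(grid, cum, xout = tcap, rule = 2)$y
  }
  # after spotlight collapse the drift is exactly p_target for every condition
  out + params$p_target * pmax(t - t0, 0)
}
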