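#' DSTP drift rate
#'
#' Phase-1 response selection sums target and flanker evidence:
#' `mu_tar + mu_fl` (congruent), `mu_tar - mu_fl` (incongruent), `mu_tar`
#' (neutral, flanker weights zero). Phase-2 drift is `+mu_rs2` when the target
#' was selected, `+mu_rs2` for a flanker selected on a congruent trial, and
#' `-mu_rs2` for a flanker selected on an incongruent trial. A flanker
#' "selected" on a neutral trial carries no response information, so phase-2
#' drift is 0 (pure noise); trial-level simulation flags such trials.
#'
#' @param params A [dstp_params()] object.
#' @param condition One of [conflict_conditions].
#' @param phase `"rs1"` (response selection phase 1) or `"rs2"`.
#' @param selected For `phase = "rs2"`, the stimulus-selection outcome:
#'   `"target"` or `"flanker"`.
#' @return Drift rate in evidence/ms.
#' @export
dstp_drift <- function(params, condition, phase = c("rs1", "rs2"),
                       selected = NULL) {
  stopifnot(inherits(params, "dstp_params"))
  check_condition(condition)
  if (!is.character(phase) || !phase[1] %in% c("rs1", "rs2")) {
    stop_mp("`phase` must be \"rs1\" or \"rs2\"", "invalid_argument")
  }
  phase <- phase[1]
  if (phase == "rs1") {
    return(switch(condition,
      congruent = params$mu_tar + params$mu_fl,
      incongruent = params$mu_tar - params$mu_fl,
      neutral = params$mu_tar
    ))
  }
  if (is.null(selected) || !is.character(selected) ||
      !selected[1] %in% c("target", "flanker")) {
    stop_mp("phase \"rs2\" requires `selected` = \"target\" or \"flanker\"",
            "invalid_argument")
  }
  if (selected[1] == "target") return(params$mu_rs2)
  switch(condition,
    congruent = params$mu_rs2,
    incongruent = -params$mu_rs2,
    neutral = 0
  )
}

#' SSP spotlight width
#'
#' The spotlight standard deviation shrinks linearly and is floored at zero:
#' `max(sd_a - r_d * t, 0)`.
#'
#' @param params An [ssp_params()] object.
#' @param t Time since stimulus onset (ms, >= 0); may be a vector.
#' @return Spotlight width(s) in stimulus-position units; non-increasing in `t`.
#' @export
ssp_attention_width <- function(params, t) {
  stopifnot(inherits(params, "ssp_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_mp("`t` must be non-negative and finite", "invalid_argument")
  }
  pmax(params$sd_a - params$r_d * t, 0)
}

#' SSP attention areas
#'
#' Mass of the spotlight (a centred Gaussian with standard deviation
#' `sd_a(t)`) over the outer-flanker, inner-flanker and target regions of a
#' unit-spaced five-item display: the integrals over `(-Inf, -1.5]`,
#' `(-1.5, -0.5]` and `(-0.5, 0.5]`. As the width tends to zero the spotlight
#' sits entirely on the target: `(0, 0, 1)`.
#'
#' @inheritParams ssp_attention_width
#' @return For scalar `t`, a named numeric vector `(a_outer, a_inner,
#'   a_target)`; for vector `t`, a three-column matrix with one row per time.
#' @export
ssp_areas <- function(params, t) {
  w <- ssp_attention_width(params, t)
  a_outer <- ifelse(w > 0, stats::pnorm(-1.5, sd = pmax(w, .Machine$double.xmin)), 0)
  phi_half <- ifelse(w > 0, stats::pnorm(-0.5, sd = pmax(w, .Machine$double.xmin)), 0)
  a_inner <- phi_half - a_outer
  a_target <- 1 - 2 * phi_half
  out <- cbind(a_outer = a_outer, a_inner = a_inner, a_target = a_target)
  if (length(t) == 1L) out[1L, ] else out
}

#' SSP drift rate
#'
#' The spotlight-weighted sum of item strengths,
#' `s * (2 p_outer a_outer(t) + 2 p_inner a_inner(t)) + p_target a_target(t)`,
#' where the flanker sign `s` is +1 (congruent), -1 (incongruent) or `bias_b`
#' (neutral; `bias_b = 0` gives the classic zero-influence neutral).
#'
#' @inheritParams ssp_attention_width
#' @param condition One of [conflict_conditions].
#' @return Drift rate(s) in evidence/ms.
#' @export
ssp_drift <- function(params, condition, t) {
  check_condition(condition)
  a <- ssp_areas(params, t)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L, dimnames = list(NULL, names(a)))
  s <- switch(condition, congruent = 1, incongruent = -1, neutral = params$bias_b)
  v <- s * (2 * params$p_outer * a[, "a_outer"] + 2 * params$p_inner * a[, "a_inner"]) +
    params$p_target * a[, "a_target"]
  unname(v)
}

# Expected automatic activation of DMC: a gamma-shaped pulse rescaled so its
# maximum is amp_A, attained at t = (shape_a - 1) * tau. Vectorised in t >= 0.
dmc_pulse <- function(params, t) {
  a <- params$shape_a
  ifelse(t > 0,
         params$amp_A * exp(-t / params$tau) *
           (t * exp(1) / ((a - 1) * params$tau))^(a - 1),
         0)
}

#' DMC drift rate
#'
#' The superimposed drift of the automatic pulse and the controlled process:
#' `s * A * exp(-t/tau) * (t e / ((a-1) tau))^(a-1) * ((a-1)/t - 1/tau) +
#' mu_c(t)` with `s` = +1 (congruent), -1 (incongruent), 0 (neutral: controlled
#' process only) and `mu_c(t) = mu_c * exp(-curvature_c * t)`. Evaluation at
#' `t = 0` is forbidden because the pulse derivative divides by `t`.
#'
#' @param params A [dmc_params()] object.
#' @param condition One of [conflict_conditions].
#' @param t Time since onset (ms, strictly positive); may be a vector.
#' @return Drift rate(s) in evidence/ms.
#' @export
dmc_drift <- function(params, condition, t) {
  stopifnot(inherits(params, "dmc_params"))
  check_condition(condition)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop_mp("`t` must be strictly positive and finite (the pulse derivative is singular at t = 0)",
            "invalid_argument")
  }
  s <- switch(condition, congruent = 1, incongruent = -1, neutral = 0)
  a <- params$shape_a
  pulse_deriv <- dmc_pulse(params, t) * ((a - 1) / t - 1 / params$tau)
  mu_ct <- params$mu_c * exp(-params$curvature_c * t)
  s * pulse_deriv + mu_ct
}
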