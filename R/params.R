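#' Conflict-task conditions
#'
#' The three admissible trial types of a conflict task. Every prediction and
#' simulation call in midpointr carries exactly one of these labels.
#'
#' @format A character vector: `"congruent"`, `"neutral"`, `"incongruent"`.
#' @export
conflict_conditions <- c("congruent", "neutral", "incongruent")

check_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% conflict_conditions) {
    stop_mp(sprintf("`condition` must be one of: %s",
                    paste(conflict_conditions, collapse = ", ")),
            "invalid_argument")
  }
  condition
}

new_params <- function(fields, family) {
  structure(fields, class = c(paste0(family, "_params"), "conflict_params"),
            family = family)
}

#' Model family of a parameter set
#'
#' @param params A parameter object created by [dstp_params()], [ssp_params()]
#'   or [dmc_params()].
#' @return `"dstp"`, `"ssp"` or `"dmc"`.
#' @export
model_family <- function(params) {
  if (!inherits(params, "conflict_params")) {
    stop_mp("`params` is not a conflict-model parameter object", "invalid_argument")
  }
  attr(params, "family")
}

#' Dual-stage two-phase (DSTP) model parameters
#'
#' The DSTP describes flanker-task decisions as two response-selection phases
#' coupled to a parallel stimulus-selection diffusion. During phase 1 the
#' response accumulator drifts at `mu_tar + mu_fl` (congruent),
#' `mu_tar - mu_fl` (incongruent) or `mu_tar` (neutral: flanker weights zero).
#' When the stimulus-selection diffusion (drift `mu_ss`, thresholds
#' `+/- theta_sel`) absorbs, phase 2 begins with drift `+mu_rs2` (target or
#' congruent flanker selected) or `-mu_rs2` (incongruent flanker selected).
#'
#' Time is in milliseconds; evidence units are arbitrary and parameter-defined.
#' `sigma = 0` yields the deterministic model.
#'
#' @param mu_tar Target drift during phase 1 (evidence/ms).
#' @param mu_fl Flanker drift magnitude during phase 1 (evidence/ms, >= 0).
#' @param mu_rs2 Phase-2 drift magnitude (evidence/ms, > 0).
#' @param mu_ss Stimulus-selection drift (evidence/ms, > 0).
#' @param theta_resp Response threshold (evidence, > 0); absorption at
#'   `+/- theta_resp`.
#' @param theta_sel Stimulus-selection threshold (evidence, > 0).
#' @param sigma Diffusion coefficient (evidence per sqrt-ms, >= 0).
#' @param ter Non-decision time (ms, >= 0).
#' @return An object of class `c("dstp_params", "conflict_params")`.
#' @seealso [preset()] for published parameterisations.
#' @examples
#' p <- dstp_params(mu_tar = 0.1, mu_fl = 0.05, mu_rs2 = 0.2, mu_ss = 0.5,
#'                  theta_resp = 50, theta_sel = 50)
#' dstp_drift(p, "congruent", phase = "rs1")
#' @export
dstp_params <- function(mu_tar, mu_fl, mu_rs2, mu_ss, theta_resp, theta_sel,
                        sigma = 0, ter = 0) {
  new_params(list(
    mu_tar = check_number(mu_tar, "mu_tar"),
    mu_fl = check_number(mu_fl, "mu_fl", lower = 0),
    mu_rs2 = check_number(mu_rs2, "mu_rs2", lower = 0, strict_lower = TRUE),
    mu_ss = check_number(mu_ss, "mu_ss", lower = 0, strict_lower = TRUE),
    theta_resp = check_number(theta_resp, "theta_resp", lower = 0, strict_lower = TRUE),
    theta_sel = check_number(theta_sel, "theta_sel", lower = 0, strict_lower = TRUE),
    sigma = check_number(sigma, "sigma", lower = 0),
    ter = check_number(ter, "ter", lower = 0)
  ), "dstp")
}

#' Shrinking-spotlight (SSP) model parameters
#'
#' The SSP models flanker-task attention as a Gaussian spotlight centred on the
#' target whose standard deviation `sd_a` shrinks linearly at rate `r_d`
#' (never below zero). Item strengths `p_outer`, `p_inner`, `p_target` are
#' weighted by the spotlight mass over the outer-flanker, inner-flanker and
#' target regions of a unit-spaced display. The flanker contribution enters
#' with sign +1 (congruent), -1 (incongruent) or, for the biased-neutral
#' extension, a continuous weight `bias_b` in (-1, 1); `bias_b = 0` is the
#' classic zero-influence neutral.
#'
#' @param p_outer,p_inner,p_target Perceptual strength of outer flankers,
#'   inner flankers and target (evidence/ms).
#' @param sd_a Initial spotlight standard deviation (stimulus-position units, > 0).
#' @param r_d Spotlight shrink rate (width units/ms, >= 0).
#' @param bias_b Neutral-condition flanker weight, strictly inside (-1, 1).
#'   Only consulted for the neutral condition.
#' @param theta_resp Response threshold (evidence, > 0).
#' @param sigma Diffusion coefficient (evidence per sqrt-ms, >= 0).
#' @param ter Non-decision time (ms, >= 0).
#' @return An object of class `c("ssp_params", "conflict_params")`.
#' @examples
#' p <- ssp_params(p_outer = 4e-4, p_inner = 4e-4, p_target = 4e-4,
#'                 sd_a = 1.8, r_d = 0.018, theta_resp = 0.05)
#' ssp_attention_width(p, t = 50)
#' @export
ssp_params <- function(p_outer, p_inner, p_target, sd_a, r_d, bias_b = 0,
                       theta_resp, sigma = 0, ter = 0) {
  new_params(list(
    p_outer = check_number(p_outer, "p_outer"),
    p_inner = check_number(p_inner, "p_inner"),
    p_target = check_number(p_target, "p_target"),
    sd_a = check_number(sd_a, "sd_a", lower = 0, strict_lower = TRUE),
    r_d = check_number(r_d, "r_d", lower = 0),
    bias_b = check_number(bias_b, "bias_b", lower = -1, upper = 1,
                          strict_lower = TRUE, strict_upper = TRUE),
    theta_resp = check_number(theta_resp, "theta_resp", lower = 0, strict_lower = TRUE),
    sigma = check_number(sigma, "sigma", lower = 0),
    ter = check_number(ter, "ter", lower = 0)
  ), "ssp")
}

#' Diffusion model of conflict (DMC) parameters
#'
#' DMC superimposes a controlled process (drift `mu_c` toward the correct
#' boundary) and an automatic process whose expected activation follows a
#' rescaled gamma pulse with amplitude `amp_A`, shape `shape_a` (> 1) and
#' scale `tau`. The pulse adds to the drift on congruent trials, subtracts on
#' incongruent trials, and is absent on neutral trials (controlled process
#' only). The concave-accrual extension lets the controlled drift decay as
#' `mu_c * exp(-curvature_c * t)`, so expected controlled evidence
#' `(mu_c / curvature_c) * (1 - exp(-curvature_c * t))` saturates instead of
#' growing linearly; `curvature_c = 0` recovers the published linear model.
#'
#' @param amp_A Pulse amplitude: peak expected automatic activation (evidence).
#' @param tau Pulse scale (ms, > 0). The pulse peaks at `t = (shape_a - 1) * tau`.
#' @param shape_a Pulse shape (> 1).
#' @param mu_c Controlled drift (evidence/ms, > 0).
#' @param curvature_c Controlled-process decay rate (1/ms, >= 0).
#' @param theta_resp Response threshold (evidence, > 0).
#' @param sigma Diffusion coefficient (evidence per sqrt-ms, >= 0).
#' @param ter Non-decision time (ms, >= 0).
#' @return An object of class `c("dmc_params", "conflict_params")`.
#' @examples
#' p <- dmc_params(amp_A = 20, tau = 30, shape_a = 2, mu_c = 0.5, theta_resp = 75)
#' dmc_drift(p, "neutral", t = 100)  # controlled process only
#' @export
dmc_params <- function(amp_A, tau, shape_a = 2, mu_c, curvature_c = 0,
                       theta_resp, sigma = 0, ter = 0) {
  new_params(list(
    amp_A = check_number(amp_A, "amp_A", lower = 0),
    tau = check_number(tau, "tau", lower = 0, strict_lower = TRUE),
    shape_a = check_number(shape_a, "shape_a", lower = 1, strict_lower = TRUE),
    mu_c = check_number(mu_c, "mu_c", lower = 0, strict_lower = TRUE),
    curvature_c = check_number(curvature_c, "curvature_c", lower = 0),
    theta_resp = check_number(theta_resp, "theta_resp", lower = 0, strict_lower = TRUE),
    sigma = check_number(sigma, "sigma", lower = 0),
    ter = check_number(ter, "ter", lower = 0)
  ), "dmc")
}

#' @export
print.conflict_params <- function(x, ...) {
  cat(sprintf("<%s parameters>\n", toupper(model_family(x))))
  vals <- unlist(x)
  for (nm in names(vals)) cat(sprintf("  %-12s %g\n", nm, vals[[nm]]))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-running all
#' validity checks.
#'
#' @param params A conflict-model parameter object.
#' @param ... Named fields to override, e.g. `bias_b = 0.4`.
#' @return A parameter object of the same family.
#' @examples
#' update_params(preset("dmc_flanker"), curvature_c = 0.002)
#' @export
update_params <- function(params, ...) {
  family <- model_family(params)
  over <- list(...)
  bad <- setdiff(names(over), names(params))
  if (length(bad)) {
    stop_mp(sprintf("unknown %s parameter(s): %s", family,
                    paste(bad, collapse = ", ")), "invalid_argument")
  }
  fields <- utils::modifyList(unclass(params), over)
  do.call(paste0(family, "_params"), fields)
}

preset_file <- function() {
  system.file("presets", "presets.yaml", package = "midpointr", mustWork = TRUE)
}

#' List shipped parameter presets
#'
#' @return A character vector of preset names usable with [preset()].
#' @export
list_presets <- function() {
  names(yaml::read_yaml(preset_file()))
}

#' Load a named parameter preset
#'
#' Presets ship with the package (see `inst/presets/presets.yaml`) and carry
#' per-millisecond parameter values drawn from the model families' original
#' publications; each preset documents its source and the seconds-to-ms
#' rescaling convention in the preset file itself. Every field can be
#' overridden.
#'
#' @param name Preset name; see [list_presets()].
#' @param ... Named field overrides passed to the family constructor.
#' @return A conflict-model parameter object.
#' @examples
#' preset("dmc_flanker")
#' preset("ssp_flanker", bias_b = 0.3)
#' @export
preset <- function(name, ...) {
  all <- yaml::read_yaml(preset_file())
  if (!is.character(name) || length(name) != 1L || !name %in% names(all)) {
    stop_mp(sprintf("unknown preset '%s'; available presets: %s",
                    as.character(name)[1], paste(names(all), collapse = ", ")),
            "config_error")
  }
  block <- all[[name]]
  family <- block$family
  fields <- block[setdiff(names(block), c("family", "source", "notes"))]
  params <- do.call(paste0(family, "_params"), fields)
  if (...length() > 0L) params <- update_params(params, ...)
  params
}
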