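# Parameter presets for the conflict-diffusion model families.
#
# Time unit convention: all rates are per millisecond. The flanker-model
# literature usually reports parameters on a seconds time base with diffusion
# coefficient sigma = 0.1; the rescaling used here divides drift-like rates
# (evidence/s) by 1000 and the diffusion coefficient by sqrt(1000)
# (0.1 / sqrt(1000) = 3.1623e-3 per sqrt-ms). Thresholds and the spotlight
# geometry are time-free and carry over unchanged. Boundaries are symmetric at
# +/- theta_resp, so theta_resp is half the boundary-separation parameter of
# the single-boundary-separation convention.
#
# Values are representative fits from the model families' original
# publications (DSTP: Huebner, Steinhauser & Lebiere, 2010; SSP: White,
# Ratcliff & Starns, 2011; DMC: Ulrich, Schroeter, Leuthold & Birngruber,
# 2015), rounded; every field can be overridden via preset(name, ...).

dstp_flanker:
  family: dstp
  source: >
    Dual-stage two-phase flanker fits (Huebner et al., 2010), seconds-based
    rates divided by 1000; sigma 0.1/sqrt(s) -> 3.1623e-3/sqrt(ms).
  mu_tar: 6.6e-05      # 0.066 evidence/s
  mu_fl: 1.8e-04       # 0.180 evidence/s
  mu_ss: 3.62e-04      # 0.362 evidence/s
  mu_rs2: 1.432e-03    # 1.432 evidence/s
  theta_resp: 0.059
  theta_sel: 0.082
  sigma: 3.1623e-03
  ter: 322             # ms

ssp_flanker:
  family: ssp
  source: >
    Shrinking-spotlight flanker fits (White et al., 2011): equal perceptual
    strength p = 0.4 evidence/s for every display item -> 4e-4 evidence/ms;
    spotlight sd 1.8 position units shrinking at 0.018 units/ms; boundary
    separation 0.1 -> theta_resp 0.05; sigma 0.1/sqrt(s) -> 3.1623e-3.
  p_outer: 4.0e-04
  p_inner: 4.0e-04
  p_target: 4.0e-04
  sd_a: 1.8
  r_d: 0.018
  bias_b: 0.0          # zero-influence neutral; biased-neutral extension sets b != 0
  theta_resp: 0.05
  sigma: 3.1623e-03
  ter: 300             # ms

dmc_flanker:
  family: dmc
  source: >
    Diffusion model of conflict (Ulrich et al., 2015), flanker-task scale:
    already parameterised per millisecond in its original publication.
  amp_A: 20
  tau: 100             # ms; pulse peaks at (shape_a - 1) * tau
  shape_a: 2
  mu_c: 0.5
  curvature_c: 0.0     # 0 = published linear controlled process
  theta_resp: 75
  sigma: 4
  ter: 300             # ms

dmc_simon:
  family: dmc
  source: >
    As dmc_flanker but with the short automatic-pulse scale typical of
    Simon-task fits (Ulrich et al., 2015).
  amp_A: 20
  tau: 30
  shape_a: 2
  mu_c: 0.5
  curvature_c: 0.0
  theta_resp: 75
  sigma: 4
  ter: 300
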