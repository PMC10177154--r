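# Default configuration: population-average model constants, an assumed
# radiotherapy regimen, the tremelimumab pharmacodynamics and the
# virtual-cohort distributions.  Any key may be omitted; package defaults
# (identical to the values below) then apply.  Set `ici: false` or
# `rt: false` to remove a modality entirely.

parameters:
  a: 0.01            # tumor growth rate (1/d)
  omega1: 0.119      # lymphocyte killing efficiency (1/d)
  omega2: 0.003      # viable-tumor-driven recruitment (1/d); ICI target
  omega3: 0.009      # dying-cell-driven recruitment (1/d)
  g: 7.33e+10         # half-saturation constant (cells)
  s: 1.47e+08          # lymphocyte regeneration (cells/d)
  f: 0.033           # lymphocyte decay (1/d)
  r: 0.14            # dying-cell clearance (1/d)
  alpha_T: 0.139     # tumor LQ alpha (1/Gy)
  alphabeta_ratio_T: 14.3   # tumor alpha/beta (Gy); beta_T derived
  alpha_L: 0.737     # lymphocyte LQ alpha (1/Gy); kill linear in dose
  tumor_density: 1.0e+09      # cells per cm^3

ici:
  delta0: 37         # initial efficacy per administration (dimensionless)
  half_life: 22      # days; published tremelimumab elimination half-life (assumption)
  start_time: 0
  repeat_interval: 90  # days; quarterly dosing as in the calibrating trial (assumption)

rt:                  # assumed regimen; the calibrating trial's is unpublished
  start_time: 0
  n_fractions: 5
  dose_tumor: 8      # Gy per fraction to the tumor
  dose_lymph: 0.5    # Gy effective whole-blood dose per fraction
  interval: 1        # daily fractions

cohort:
  n_patients: 100
  tumor_diameter_mean: 5.0    # cm (assumed baseline distribution)
  tumor_diameter_sd: 1.5
  lymphocyte_mean: 4.45e+09     # cells; tumor-free equilibrium s/f
  lymphocyte_sd: 1.0e+09
  alpha_T_mean: 0.139
  alpha_T_sd: 0.0139          # 10% coefficient of variation
  delta0_mean: 37
  delta0_sd: 4
  itf: 0.5                    # irradiated tumor fraction at baseline
  seed: 1

horizon: 365         # follow-up (d), monthly RECIST assessments
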