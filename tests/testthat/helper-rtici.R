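# shared fixtures: small, fast configurations used across test files

default_p <- model_parameters()

# a mid-sized single patient: 5 cm total burden split 50/50, lymphocytes at
# the tumor-free equilibrium
mid_patient <- function(p = default_p, itf = 0.5, diameter = 5) {
  st <- burden_to_initial_state(diameter, itf, p$s / p$f, p$tumor_density)
  system_state(st$T_I, st$I, st$T_NI, st$L)
}

tiny_cfg <- function(n = 20, seed = 42, ...) {
  population_config(n_patients = n, seed = seed, ...)
}

ici_single <- function(delta0 = 37, half_life = 22) {
  ici_pharmacodynamics(delta0 = delta0, half_life = half_life,
                       repeat_interval = NULL)
}

# build a response_curve object directly from known rates (no simulation)
synthetic_curve <- function(delta, CR, PR, SD, PD) {
  out <- data.frame(delta = delta, CR = CR, PR = PR, SD = SD, PD = PD)
  class(out) <- c("response_curve", "data.frame")
  out
}

final_tumor <- function(traj) {
  last <- traj[nrow(traj), ]
  last$T_I + last$T_NI
}
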