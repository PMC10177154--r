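test_that("drug efficacy decays from each administration with the half-life", {
  pd <- ici_single(delta0 = 37, half_life = 22)
  expect_equal(delta_trem_at(0, pd), 37)
  expect_equal(delta_trem_at(22, pd), 37 / 2)
  expect_equal(delta_trem_at(44, pd), 37 / 4)
  # constant-efficacy limit
  expect_equal(delta_trem_at(c(0, 100, 1000), ici_single(half_life = Inf)),
               rep(37, 3))
  # nothing before the first administration
  late <- ici_pharmacodynamics(delta0 = 10, start_time = 50,
                               repeat_interval = NULL)
  expect_equal(delta_trem_at(c(0, 49.9), late), c(0, 0))
  expect_equal(delta_trem_at(50, late), 10)
  # re-dosing resets the decay clock
  q90 <- ici_pharmacodynamics(delta0 = 37, half_life = 22, repeat_interval = 90)
  expect_equal(delta_trem_at(90, q90), 37)
  expect_equal(delta_trem_at(112, q90), 37 / 2)
  # no drug at all
  expect_equal(delta_trem_at(c(0, 10), NULL), c(0, 0))
})

test_that("the tumor-free lymphocyte equilibrium is a fixed point", {
  p <- default_p
  st <- system_state(0, 0, 0, p$s / p$f)
  expect_equal(unname(tumor_immune_rates(st, p)), rep(0, 4), tolerance = 1e-12)
  # with Table-value rates the equilibrium sits near 4.45e9 cells
  expect_equal(p$s / p$f, 1.47e8 / 0.033)
})

test_that("without lymphocytes the tumor grows purely exponentially", {
  p <- default_p
  st <- system_state(T_I = 1e9, I = 0, T_NI = 0, L = 0)
  r <- tumor_immune_rates(st, p)
  expect_equal(r[["T_I"]], p$a * 1e9)
  # doubling time ln 2 / a
  expect_equal(log(2) / p$a, 69.3, tolerance = 1e-2)
})

test_that("the drug efficacy enters only the lymphocyte recruitment term", {
  p <- default_p
  st <- system_state(2e10, 1e9, 3e10, 5e9)
  r1 <- tumor_immune_rates(st, p, delta = 10)
  r2 <- tumor_immune_rates(st, p, delta = 20)
  expect_equal(r1[c("T_I", "I", "T_NI")], r2[c("T_I", "I", "T_NI")])
  Tt <- st$T_I + st$T_NI
  expect_equal(r2[["L"]] - r1[["L"]], p$omega2 * 10 * Tt / (p$g + Tt) * st$L)
  # sensitivity switch moves the amplification to the dying-cell term
  p3 <- model_parameters(delta_target = "omega3")
  r3a <- tumor_immune_rates(st, p3, delta = 10)
  r3b <- tumor_immune_rates(st, p3, delta = 20)
  expect_equal(r3b[["L"]] - r3a[["L"]],
               p3$omega3 * 10 * st$I / (p3$g + st$I) * st$L)
})

test_that("a radiotherapy fraction applies LQ kill and conserves cells", {
  p <- default_p
  st <- system_state(1e10, 2e9, 5e9, 4e9)
  # zero dose is the identity
  same <- apply_rt_fraction(st, 0, 0, p)
  expect_equal(unclass(same)[1:4], unclass(st)[1:4])
  # survival fraction evaluated directly from the LQ formula
  d <- 8
  sf_expected <- exp(-(0.139 * d + 0.139 / 14.3 * d^2))
  post <- apply_rt_fraction(st, d, 0.5, p)
  expect_equal(post$T_I / st$T_I, sf_expected, tolerance = 1e-12)
  expect_equal(sf_expected, 0.1766, tolerance = 1e-3)
  # exact conservation: viable loss equals dying gain
  expect_equal(st$T_I - post$T_I, post$I - st$I)
  # lymphocyte kill is linear in dose, non-irradiated compartment untouched
  expect_equal(post$L, st$L * exp(-p$alpha_L * 0.5))
  expect_equal(post$T_NI, st$T_NI)
  expect_error(apply_rt_fraction(st, -1, 0, p), "non-negative")
})

test_that("irradiated tumor fraction follows its definition", {
  expect_equal(irradiated_tumor_fraction(1e9, 1e9), 0.5)
  expect_equal(irradiated_tumor_fraction(1e9, 0), 1)
  expect_equal(irradiated_tumor_fraction(1e9, 3e9), 0.25)
  expect_equal(irradiated_tumor_fraction(system_state(2e9, 0, 6e9, 1e9)), 0.25)
  expect_error(irradiated_tumor_fraction(0, 0), "undefined")
})

test_that("a patient at the tumor-free fixed point stays there", {
  p <- default_p
  st <- system_state(0, 0, 0, p$s / p$f)
  traj <- simulate_patient(st, p, treatment_schedule(horizon = 365))
  expect_true(all(abs(traj$L - p$s / p$f) / (p$s / p$f) < 1e-8))
  expect_true(all(traj$T_I == 0) && all(traj$T_NI == 0) && all(traj$I == 0))
})

test_that("trajectory pre/post pairs at RT events match the impulse map", {
  p <- default_p
  st <- mid_patient()
  sch <- treatment_schedule(rt_fractions(start_time = 10, n_fractions = 2),
                            horizon = 60)
  traj <- simulate_patient(st, p, sch)
  ev <- attr(traj, "events")
  expect_equal(nrow(ev), 2)
  for (k in seq_len(nrow(ev))) {
    pre <- system_state(ev$T_I_pre[k], ev$I_pre[k], ev$T_NI_pre[k], ev$L_pre[k])
    post <- apply_rt_fraction(pre, 8, 0.5, p)
    expect_equal(ev$T_I_post[k], post$T_I)
    expect_equal(ev$I_post[k], post$I)
    expect_equal(ev$L_post[k], post$L)
    # conservation at relative tolerance 1e-10
    expect_lt(abs((ev$T_I_pre[k] - ev$T_I_post[k]) - (ev$I_post[k] - ev$I_pre[k])) /
                ev$T_I_pre[k], 1e-10)
  }
  # both pre and post rows are present in the emitted trajectory
  expect_true(sum(traj$time_d == 10) >= 2)
})

test_that("compartments stay non-negative across random schedules", {
  p <- default_p
  set.seed(11)
  for (i in 1:5) {
    st <- system_state(runif(1, 1e8, 5e10), 0, runif(1, 1e8, 5e10),
                       runif(1, 1e9, 8e9))
    rt <- rt_fractions(start_time = sample(0:20, 1),
                       n_fractions = sample(1:5, 1),
                       dose_tumor = runif(1, 1, 10), dose_lymph = runif(1, 0, 1))
    sch <- treatment_schedule(rt, ici_pharmacodynamics(delta0 = runif(1, 0, 60)),
                              horizon = 180)
    traj <- simulate_patient(st, p, sch)
    expect_true(all(traj[, c("T_I", "I", "T_NI", "L")] >= 0))
  }
})

test_that("the eradication floor zeroes sub-cell tumor burdens for good", {
  p <- default_p
  st <- system_state(1e4, 0, 0, p$s / p$f)  # small irradiated-only lesion
  rt <- rt_fractions(start_time = 0, n_fractions = 4, dose_tumor = 12,
                     dose_lymph = 0)
  traj <- simulate_patient(st, p, treatment_schedule(rt, horizon = 365))
  # four 12 Gy fractions reduce 1e4 cells far below one cell
  expect_equal(traj$T_I[traj$time_d > 30], rep(0, sum(traj$time_d > 30)))
  expect_equal(final_tumor(traj), 0)
})

test_that("solver agrees with an independent integration at the horizon", {
  p <- default_p
  st <- mid_patient()
  sch <- treatment_schedule(rt = NULL, ici = ici_single(half_life = Inf),
                            horizon = 365)
  a <- simulate_patient(st, p, sch, method = "lsoda")
  # implicit Runge-Kutta at halved tolerances as the independent reference
  b <- simulate_patient(st, p, sch, method = "radau", rtol = 5e-9, atol = 5e-3)
  fa <- a[nrow(a), c("T_I", "T_NI", "L")]
  fb <- b[nrow(b), c("T_I", "T_NI", "L")]
  expect_true(all(abs(fa - fb) / abs(fb) < 1e-6))
})

test_that("final tumor burden is monotone in drug efficacy and in dose", {
  p <- default_p
  st <- mid_patient()
  finals <- vapply(c(0, 10, 20, 40, 60, 80), function(d0) {
    sch <- treatment_schedule(ici = ici_pharmacodynamics(delta0 = d0),
                              horizon = 365)
    final_tumor(simulate_patient(st, p, sch))
  }, numeric(1))
  expect_true(all(diff(finals) <= 1e-8 * finals[-length(finals)]))
  # tumor-only dose response (no lymphocyte dose)
  finals_d <- vapply(c(0, 2, 4, 8, 12), function(d) {
    rt <- rt_fractions(n_fractions = 3, dose_tumor = d, dose_lymph = 0)
    sch <- treatment_schedule(rt, horizon = 180)
    tr <- simulate_patient(st, p, sch)
    tr$T_I[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(finals_d) <= 1e-8 * pmax(finals_d[-length(finals_d)], 1)))
})

test_that("zero drug efficacy reduces exactly to the RT-only model", {
  p <- default_p
  st <- mid_patient()
  rt <- rt_fractions()
  sch_ici0 <- treatment_schedule(rt, ici_pharmacodynamics(delta0 = 0),
                                 horizon = 365)
  sch_none <- treatment_schedule(rt, NULL, horizon = 365)
  t1 <- simulate_patient(st, p, sch_ici0)
  t2 <- simulate_patient(st, p, sch_none)
  expect_identical(t1$T_I, t2$T_I)
  expect_identical(t1$I, t2$I)
  expect_identical(t1$T_NI, t2$T_NI)
  expect_identical(t1$L, t2$L)
})

test_that("the cohort simulator matches the single-patient path", {
  p <- default_p
  cfg <- tiny_cfg(n = 3, seed = 5)
  cohort <- sample_cohort(cfg, p)
  sch <- treatment_schedule(rt_fractions(), ici_pharmacodynamics(),
                            horizon = 365)
  sim <- simulate_cohort(cohort, p, sch)
  for (i in 1:3) {
    st <- system_state(cohort$T_I[i], cohort$I[i], cohort$T_NI[i], cohort$L[i])
    ici_i <- ici_pharmacodynamics(delta0 = cohort$delta0[i])
    tr <- simulate_patient(st, p, treatment_schedule(rt_fractions(), ici_i,
                                                     horizon = 365),
                           alpha_T = cohort$alpha_T[i])
    # compare at the common monthly grid (different solver methods)
    grid <- sim$times[sim$times > 4]
    tr_grid <- tr[match(grid, tr$time_d), ]
    rel <- abs(sim$T_NI[match(grid, sim$times), i] - tr_grid$T_NI) /
      pmax(tr_grid$T_NI, 1)
    expect_lt(max(rel), 1e-5)
    rel_l <- abs(sim$L[match(grid, sim$times), i] - tr_grid$L) /
      pmax(tr_grid$L, 1)
    expect_lt(max(rel_l), 1e-5)
  }
})

test_that("trajectories are written as tidy CSV", {
  p <- default_p
  tr <- simulate_patient(mid_patient(), p, treatment_schedule(horizon = 60),
                         patient_id = 7L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_named(back, c("time_d", "T_I", "I", "T_NI", "L", "delta_trem",
                       "diameter_irr_cm", "diameter_nonirr_cm", "patient_id"))
  expect_equal(unique(back$patient_id), 7L)
})
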