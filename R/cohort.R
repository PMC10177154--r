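#' Virtual-population sampling configuration
#'
#' Describes the distributions from which per-patient baseline quantities
#' are drawn.  Each quantity is sampled from a normal distribution
#' truncated at zero (by rejection).  The baseline tumor-diameter and
#' lymphocyte distributions are declared assumptions: the calibrating
#' trial's baseline distributions are not published, so the defaults place
#' tumors at 5 +/- 1.5 cm and lymphocyte counts at the model's tumor-free
#' equilibrium `s/f` (about 4.45e9 cells) +/- 1e9.  Radiosensitivity varies
#' with a 10% coefficient of variation around the population alpha_T.
#'
#' @param n_patients Number of virtual patients (>= 1).
#' @param tumor_diameter_mean,tumor_diameter_sd Baseline total tumor
#'   diameter distribution (cm).
#' @param lymphocyte_mean,lymphocyte_sd Baseline circulating lymphocyte
#'   distribution (cells).
#' @param alpha_T_mean,alpha_T_sd Tumor radiosensitivity distribution
#'   (1/Gy).
#' @param delta0_mean,delta0_sd Checkpoint-inhibitor efficacy distribution
#'   (dimensionless).
#' @param itf Irradiated tumor fraction used to split the baseline burden,
#'   in `(0, 1]`.
#' @param seed RNG seed; identical seeds give identical cohorts.
#'
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_patients = 10000,
                              tumor_diameter_mean = 5, tumor_diameter_sd = 1.5,
                              lymphocyte_mean = 4.45e9, lymphocyte_sd = 1e9,
                              alpha_T_mean = 0.139, alpha_T_sd = 0.0139,
                              delta0_mean = 37, delta0_sd = 4,
                              itf = 0.5, seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop("n_patients must be a positive count", call. = FALSE)
  sds <- c(tumor_diameter_sd, lymphocyte_sd, alpha_T_sd, delta0_sd)
  if (any(sds < 0)) stop("standard deviations must be non-negative", call. = FALSE)
  means <- c(tumor_diameter_mean, lymphocyte_mean, alpha_T_mean)
  if (any(means <= 0)) stop("means of physical quantities must be positive", call. = FALSE)
  if (delta0_mean < 0) stop("delta0_mean must be non-negative", call. = FALSE)
  if (itf <= 0 || itf > 1) stop("itf must lie in (0, 1]", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 tumor_diameter_mean = tumor_diameter_mean,
                 tumor_diameter_sd = tumor_diameter_sd,
                 lymphocyte_mean = lymphocyte_mean,
                 lymphocyte_sd = lymphocyte_sd,
                 alpha_T_mean = alpha_T_mean, alpha_T_sd = alpha_T_sd,
                 delta0_mean = delta0_mean, delta0_sd = delta0_sd,
                 itf = itf, seed = as.integer(seed)),
            class = "population_config")
}

# positive-truncated normal draws by rejection; sd = 0 degenerates to the
# mean.  Rejection (rather than clipping) preserves the shape of the
# retained mass.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Initial system state from a total tumor burden
#'
#' Converts a total tumor diameter to a cell count through the spherical
#' volume `(pi/6) d^3` and the tumor cell density, then splits it between
#' the irradiated and non-irradiated compartments according to the
#' prescribed irradiated tumor fraction.  The dying-cell compartment starts
#' empty.  All arguments may be vectors.
#'
#' @param diameter Total tumor diameter (cm, > 0).
#' @param itf Irradiated tumor fraction in `(0, 1]`.
#' @param lymphocytes Baseline circulating lymphocytes (cells).
#' @param density Tumor cell density (cells/cm^3).
#'
#' @return A data.frame with columns `T_I`, `I`, `T_NI`, `L`.
#' @export
burden_to_initial_state <- function(diameter, itf, lymphocytes, density = 1e9) {
  if (any(diameter <= 0)) stop("diameter must be positive", call. = FALSE)
  if (any(itf <= 0) || any(itf > 1)) stop("itf must lie in (0, 1]", call. = FALSE)
  total <- density * pi / 6 * diameter^3
  data.frame(T_I = itf * total, I = 0, T_NI = (1 - itf) * total,
             L = lymphocytes)
}

#' Sample a virtual-patient cohort
#'
#' Draws `n_patients` virtual patients from the distributions in `cfg`
#' using the configured seed (the caller's RNG state is left untouched).
#' Every draw is truncated at zero by rejection, so all sampled physical
#' quantities are strictly positive.
#'
#' @param cfg A [population_config()].
#' @param p [model_parameters()]; provides the tumor cell density for the
#'   diameter-to-count conversion.
#'
#' @return A data.frame of class `virtual_cohort` with one row per patient:
#'   `id`, `tumor_diameter_cm`, `alpha_T`, `delta0`, and the initial
#'   compartments `T_I`, `I`, `T_NI`, `L`.
#' @export
sample_cohort <- function(cfg, p = model_parameters()) {
  stopifnot(inherits(cfg, "population_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(cfg$seed)
  n <- cfg$n_patients
  diameter <- rtruncnorm_pos(n, cfg$tumor_diameter_mean, cfg$tumor_diameter_sd)
  lymph <- rtruncnorm_pos(n, cfg$lymphocyte_mean, cfg$lymphocyte_sd)
  alpha <- rtruncnorm_pos(n, cfg$alpha_T_mean, cfg$alpha_T_sd)
  delta0 <- if (cfg$delta0_mean == 0 && cfg$delta0_sd == 0) rep(0, n)
            else rtruncnorm_pos(n, cfg$delta0_mean, cfg$delta0_sd)
  st <- burden_to_initial_state(diameter, cfg$itf, lymph, p$tumor_density)
  cohort <- data.frame(id = seq_len(n), tumor_diameter_cm = diameter,
                       alpha_T = alpha, delta0 = delta0,
                       T_I = st$T_I, I = st$I, T_NI = st$T_NI, L = st$L)
  attr(cohort, "config") <- cfg
  class(cohort) <- c("virtual_cohort", "data.frame")
  cohort
}

#' Simulate a whole cohort through a shared treatment schedule
#'
#' Vectorized counterpart of [simulate_patient()]: all patients are
#' advanced together as one stacked ODE system, stopping and restarting the
#' integrator at every scheduled event.  Radiation kill uses each patient's
#' own `alpha_T`; the checkpoint-inhibitor efficacy uses each patient's own
#' `delta0` (overridable through `delta0`).  The eradication floor (viable
#' compartments below one cell are zeroed) is applied at event times and
#' segment ends.
#'
#' The stacked system is integrated with a non-stiff adaptive method
#' (Adams) by default: between events the dynamics are smooth with rate
#' constants well below 1/d, and a stiff solver would allocate a dense
#' Jacobian quadratic in the stacked dimension.
#'
#' @param cohort A `virtual_cohort` (or any data.frame with columns `T_I`,
#'   `I`, `T_NI`, `L`, `alpha_T`).
#' @param p [model_parameters()].
#' @param schedule A [treatment_schedule()] shared by all patients.
#' @param dt_out Output sampling interval (d); monthly by default.
#' @param delta0 Optional per-patient (or scalar) override of the cohort's
#'   `delta0` column.
#' @param method deSolve method for the stacked system.
#' @param rtol,atol Integration tolerances.
#'
#' @return An object of class `cohort_sim`: a list with `times` (length m)
#'   and m-by-n matrices `T_I`, `I`, `T_NI`, `L`, plus the evaluated
#'   per-patient `delta0`.
#' @export
simulate_cohort <- function(cohort, p, schedule, dt_out = 365 / 12,
                            delta0 = NULL, method = "adams",
                            rtol = 1e-8, atol = 1e-2) {
  n <- nrow(cohort)
  if (is.null(delta0)) {
    delta0 <- if ("delta0" %in% names(cohort)) cohort$delta0 else rep(0, n)
  }
  delta0 <- rep_len(delta0, n)
  if (is.null(schedule$ici)) delta0 <- rep(0, n)
  ici <- schedule$ici
  inert <- is.null(ici) || all(delta0 == 0)
  alpha <- if ("alpha_T" %in% names(cohort)) cohort$alpha_T else rep(p$alpha_T, n)
  rt <- schedule$rt
  breaks <- schedule_breakpoints(schedule, inert_ici = inert)
  out_times <- sort(unique(c(seq(0, schedule$horizon, by = dt_out),
                             schedule$horizon)))

  idx <- function(k) ((k - 1) * n + 1):(k * n)
  deriv <- function(t, y, parms) {
    T_I <- y[idx(1)]; I <- y[idx(2)]; T_NI <- y[idx(3)]; L <- y[idx(4)]
    delta <- if (inert) 0 else delta0 * ici_decay_factor(t, ici)
    r <- compartment_rates(T_I, I, T_NI, L, p, delta)
    list(c(r$T_I, r$I, r$T_NI, r$L))
  }
  floor_state <- function(y) {
    y <- pmax(y, 0)
    ti <- y[idx(1)]; tni <- y[idx(3)]
    ti[ti < 1] <- 0; tni[tni < 1] <- 0
    y[idx(1)] <- ti; y[idx(3)] <- tni
    y
  }

  y <- floor_state(c(cohort$T_I, cohort$I, cohort$T_NI, cohort$L))
  m <- length(out_times)
  res <- list(T_I = matrix(NA_real_, m, n), I = matrix(NA_real_, m, n),
              T_NI = matrix(NA_real_, m, n), L = matrix(NA_real_, m, n))
  store <- function(row, y) {
    res$T_I[row, ] <<- y[idx(1)]; res$I[row, ] <<- y[idx(2)]
    res$T_NI[row, ] <<- y[idx(3)]; res$L[row, ] <<- y[idx(4)]
  }
  if (out_times[1] == 0) store(1L, y)

  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    if (!is.null(rt) && any(rt$time == t0)) {
      i <- which(rt$time == t0)
      beta <- alpha / p$alphabeta_ratio_T
      sf_t <- exp(-alpha * rt$dose_tumor[i] - beta * rt$dose_tumor[i]^2)
      ti <- y[idx(1)]
      y[idx(2)] <- y[idx(2)] + ti * (1 - sf_t)
      y[idx(1)] <- ti * sf_t
      y[idx(4)] <- y[idx(4)] * exp(-p$alpha_L * rt$dose_lymph[i])
      y <- floor_state(y)
    }
    tt <- sort(unique(c(t0, out_times[out_times > t0 & out_times <= t1], t1)))
    sol <- deSolve::ode(y = y, times = tt, func = deriv, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    if (nrow(sol) < length(tt) || anyNA(sol[nrow(sol), ]))
      stop(sprintf("cohort integration failed near t = %.3f d", t1),
           call. = FALSE)
    for (j in seq_along(tt)) {
      if (tt[j] > t0 && tt[j] %in% out_times)
        store(match(tt[j], out_times), pmax(sol[j, -1], 0))
    }
    y <- floor_state(sol[nrow(sol), -1])
  }
  structure(list(times = out_times, T_I = res$T_I, I = res$I,
                 T_NI = res$T_NI, L = res$L, delta0 = delta0,
                 density = p$tumor_density),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Cohort simulation: %d patients, %d time points over %g d\n",
              ncol(x$T_I), length(x$times), max(x$times)))
  invisible(x)
}
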