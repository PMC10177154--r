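#' System state of the four-compartment model
#'
#' @param T_I Irradiated viable tumor cells (count).
#' @param I Dying (inactivated) tumor cells (count).
#' @param T_NI Non-irradiated (metastatic) viable tumor cells (count).
#' @param L Circulating lymphocytes (count).
#' @param t Time (d).
#'
#' @return An object of class `system_state` (a named list).
#' @export
system_state <- function(T_I = 0, I = 0, T_NI = 0, L = 0, t = 0) {
  v <- c(T_I = T_I, I = I, T_NI = T_NI, L = L)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all compartments must be finite and non-negative", call. = FALSE)
  structure(list(T_I = T_I, I = I, T_NI = T_NI, L = L, t = t),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("State at t = %g d: T_I = %.4g, I = %.4g, T_NI = %.4g, L = %.4g cells\n",
              x$t, x$T_I, x$I, x$T_NI, x$L))
  invisible(x)
}

#' Checkpoint-inhibitor efficacy at a given time
#'
#' Evaluates the decaying tremelimumab efficacy
#' `delta(t) = delta0 * exp(-lambda * (t - t_dose))`, where `t_dose` is the
#' most recent administration at or before `t` and
#' `lambda = log(2) / half_life`.  Before the first administration the
#' efficacy is 0.
#'
#' @param t Time (d); may be a vector.
#' @param pd An [ici_pharmacodynamics()] object, or `NULL` (no drug,
#'   efficacy identically 0).
#'
#' @return Efficacy value(s), same length as `t`.
#' @examples
#' pd <- ici_pharmacodynamics(delta0 = 37, half_life = 22, repeat_interval = NULL)
#' delta_trem_at(0, pd)   # 37
#' delta_trem_at(22, pd)  # 18.5
#' @export
delta_trem_at <- function(t, pd) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (is.null(pd)) return(rep(0, length(t)))
  if (!inherits(pd, "ici_pharmacodynamics"))
    stop("pd must be an ici_pharmacodynamics object or NULL", call. = FALSE)
  tl <- t - pd$start_time
  out <- numeric(length(t))
  on_drug <- tl >= 0
  if (!is.null(pd$repeat_interval)) tl <- tl %% pd$repeat_interval
  out[on_drug] <- pd$delta0 * exp(-pd$lambda * tl[on_drug])
  out
}

# continuous-part right-hand side, vectorized over patients.
# delta may be a scalar or a per-patient vector.
compartment_rates <- function(T_I, I, T_NI, L, p, delta = 0) {
  Tt <- T_I + T_NI
  kill <- p$omega1 * L / (p$g + Tt)
  w2 <- if (p$delta_target == "omega2") p$omega2 * (1 + delta) else p$omega2
  w3 <- if (p$delta_target == "omega3") p$omega3 * (1 + delta) else p$omega3
  list(T_I = p$a * T_I - kill * T_I,
       I = -p$r * I,
       T_NI = p$a * T_NI - kill * T_NI,
       L = w2 * Tt / (p$g + Tt) * L + w3 * I / (p$g + I) * L + p$s - p$f * L)
}

#' Continuous rates of change of the four compartments
#'
#' The between-fraction (continuous) dynamics: exponential tumor growth
#' opposed by saturating lymphocyte-mediated kill, first-order clearance of
#' dying cells, and lymphocyte recruitment driven by viable and dying tumor
#' burden with regeneration and decay.  The checkpoint-inhibitor efficacy
#' `delta` amplifies the viable-tumor recruitment term (or, with
#' `delta_target = "omega3"`, the dying-cell term).  Radiation impulses are
#' not part of these rates; see [apply_rt_fraction()].
#'
#' @param state A [system_state()] (or a list with fields `T_I`, `I`,
#'   `T_NI`, `L`).
#' @param p [model_parameters()].
#' @param delta Checkpoint-inhibitor efficacy at the evaluation time
#'   (dimensionless).
#'
#' @return Named numeric vector of rates (cells/d) for `T_I`, `I`, `T_NI`, `L`.
#' @export
tumor_immune_rates <- function(state, p, delta = 0) {
  v <- c(state$T_I, state$I, state$T_NI, state$L)
  if (any(v < 0)) stop("state compartments must be non-negative", call. = FALSE)
  r <- compartment_rates(state$T_I, state$I, state$T_NI, state$L, p, delta)
  c(T_I = r$T_I, I = r$I, T_NI = r$T_NI, L = r$L)
}

#' Apply one radiotherapy fraction as an instantaneous state map
#'
#' Linear-quadratic kill of the irradiated tumor compartment,
#' `SF_T = exp(-alpha_T * D_T - beta_T * D_T^2)`; the killed cells move to
#' the dying compartment, so viable-tumor loss exactly equals dying-cell
#' gain.  Lymphocytes are depleted linearly in dose,
#' `SF_L = exp(-alpha_L * D_L)`.  The non-irradiated compartment and the
#' clock are unchanged.
#'
#' @param state A [system_state()].
#' @param dose_tumor Tumor dose of the fraction (Gy).
#' @param dose_lymph Effective lymphocyte dose of the fraction (Gy).
#' @param p [model_parameters()].
#' @param alpha_T Tumor LQ alpha override (1/Gy), e.g. a patient-specific
#'   radiosensitivity; `beta_T` co-varies through the fixed alpha/beta
#'   ratio.
#'
#' @return The post-fraction `system_state`.
#' @export
apply_rt_fraction <- function(state, dose_tumor, dose_lymph, p,
                              alpha_T = p$alpha_T) {
  if (dose_tumor < 0 || dose_lymph < 0)
    stop("doses must be non-negative", call. = FALSE)
  beta_T <- alpha_T / p$alphabeta_ratio_T
  sf_t <- exp(-alpha_T * dose_tumor - beta_T * dose_tumor^2)
  sf_l <- exp(-p$alpha_L * dose_lymph)
  system_state(T_I = state$T_I * sf_t,
               I = state$I + state$T_I * (1 - sf_t),
               T_NI = state$T_NI,
               L = state$L * sf_l,
               t = state$t)
}

#' Irradiated tumor fraction
#'
#' The share of the total viable tumor burden that receives radiation,
#' `ITF = T_I / (T_I + T_NI)`.
#'
#' @param T_I Irradiated viable tumor cells, or a `system_state`.
#' @param T_NI Non-irradiated viable tumor cells (ignored when `T_I` is a
#'   state object).
#'
#' @return A fraction in `[0, 1]`.
#' @export
irradiated_tumor_fraction <- function(T_I, T_NI = NULL) {
  if (inherits(T_I, "system_state")) {
    T_NI <- T_I$T_NI
    T_I <- T_I$T_I
  }
  if (any(T_I < 0) || any(T_NI < 0))
    stop("compartments must be non-negative", call. = FALSE)
  if (any(T_I + T_NI == 0))
    stop("irradiated tumor fraction is undefined for zero total burden",
         call. = FALSE)
  T_I / (T_I + T_NI)
}

# Segment boundaries of a schedule: start, horizon, RT fraction times and
# (unless the drug is inert) ICI administration times, where the right-hand
# side is discontinuous and the integrator must be stopped and restarted.
schedule_breakpoints <- function(schedule, inert_ici = FALSE) {
  b <- c(0, schedule$horizon)
  if (!is.null(schedule$rt)) b <- c(b, schedule$rt$time)
  if (!is.null(schedule$ici) && !inert_ici)
    b <- c(b, ici_dose_times(schedule$ici, schedule$horizon))
  sort(unique(b))
}

# multiplicative decay factor of the ICI efficacy at time t (scalar t)
ici_decay_factor <- function(t, ici) {
  if (is.null(ici)) return(0)
  tl <- t - ici$start_time
  if (tl < 0) return(0)
  if (!is.null(ici$repeat_interval)) tl <- tl %% ici$repeat_interval
  exp(-ici$lambda * tl)
}

#' Simulate one virtual patient through a treatment schedule
#'
#' Integrates the continuous dynamics between events with the decaying
#' checkpoint-inhibitor efficacy, applies [apply_rt_fraction()] exactly at
#' each scheduled fraction time (the integrator is stopped and restarted at
#' every event so impulses are not smeared), clamps compartments at zero
#' and applies the eradication floor: a viable tumor compartment that has
#' fallen below one cell at an event time or segment end is set to zero.
#'
#' When the drug efficacy is identically zero (no ICI in the schedule, or
#' `delta0 = 0`) the administration times are not treated as events, so the
#' reduced model reproduces the radiotherapy-only model exactly.
#'
#' @param state0 Initial [system_state()].
#' @param p [model_parameters()].
#' @param schedule A [treatment_schedule()].
#' @param dt_out Output sampling interval (d); defaults to monthly
#'   (365/12 d).
#' @param alpha_T Patient-specific tumor radiosensitivity (1/Gy).
#' @param method deSolve integration method; the default `"lsoda"` is
#'   adaptive and stiff-capable.
#' @param rtol,atol Relative and absolute integration tolerances; the
#'   absolute tolerance is in cells.
#' @param patient_id Identifier used in diagnostics and the trajectory
#'   table.
#'
#' @return A data.frame of class `tumor_trajectory` with columns `time_d`,
#'   `T_I`, `I`, `T_NI`, `L`, `delta_trem`, `diameter_irr_cm`,
#'   `diameter_nonirr_cm`, `patient_id`, sampled every `dt_out` plus
#'   duplicated pre/post rows at every RT fraction time.  The pre/post
#'   states are also available via `attr(x, "events")`.
#' @export
simulate_patient <- function(state0, p, schedule, dt_out = 365 / 12,
                             alpha_T = p$alpha_T, method = "lsoda",
                             rtol = 1e-8, atol = 1e-2, patient_id = 1L) {
  ici <- schedule$ici
  inert <- is.null(ici) || ici$delta0 == 0
  breaks <- schedule_breakpoints(schedule, inert_ici = inert)
  out_times <- sort(unique(c(seq(0, schedule$horizon, by = dt_out),
                             schedule$horizon)))
  rt <- schedule$rt

  deriv <- function(t, y, parms) {
    delta <- if (inert) 0 else ici$delta0 * ici_decay_factor(t, ici)
    r <- compartment_rates(y[1], y[2], y[3], y[4], p, delta)
    list(c(r$T_I, r$I, r$T_NI, r$L))
  }

  floor_state <- function(y) {
    y <- pmax(y, 0)
    if (y[1] < 1) y[1] <- 0
    if (y[3] < 1) y[3] <- 0
    y
  }

  y <- floor_state(c(state0$T_I, state0$I, state0$T_NI, state0$L))
  rows <- list()
  events <- list()
  add_row <- function(t, y, phase = "sample") {
    rows[[length(rows) + 1L]] <<- list(t = t, y = as.numeric(y), phase = phase)
  }
  if (0 %in% out_times) add_row(0, y)

  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1L]
    # events scheduled at the segment start are applied before integrating
    if (!is.null(rt) && any(rt$time == t0)) {
      i <- which(rt$time == t0)
      pre <- y
      st <- apply_rt_fraction(system_state(y[1], y[2], y[3], y[4], t0),
                              rt$dose_tumor[i], rt$dose_lymph[i], p, alpha_T)
      y <- floor_state(c(st$T_I, st$I, st$T_NI, st$L))
      events[[length(events) + 1L]] <-
        data.frame(time = t0,
                   T_I_pre = pre[1], I_pre = pre[2], T_NI_pre = pre[3], L_pre = pre[4],
                   T_I_post = y[1], I_post = y[2], T_NI_post = y[3], L_post = y[4])
      add_row(t0, pre, "pre_rt")
      add_row(t0, y, "post_rt")
    }
    tt <- sort(unique(c(t0, out_times[out_times > t0 & out_times < t1], t1)))
    sol <- deSolve::ode(y = y, times = tt, func = deriv, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    if (nrow(sol) < length(tt) || anyNA(sol))
      stop(sprintf("integration failed for patient %s near t = %.3f d",
                   patient_id, sol[nrow(sol), 1]), call. = FALSE)
    for (j in seq_along(tt)) {
      if (tt[j] > t0 && tt[j] %in% out_times && !(tt[j] == t1 && !is.null(rt) &&
          any(rt$time == t1)))
        add_row(tt[j], pmax(sol[j, -1], 0))
    }
    y <- floor_state(sol[nrow(sol), -1])
  }
  # an RT fraction exactly at the horizon would be applied after the loop
  if (!is.null(rt) && any(rt$time == schedule$horizon)) {
    i <- which(rt$time == schedule$horizon)
    pre <- y
    st <- apply_rt_fraction(system_state(y[1], y[2], y[3], y[4], schedule$horizon),
                            rt$dose_tumor[i], rt$dose_lymph[i], p, alpha_T)
    y <- floor_state(c(st$T_I, st$I, st$T_NI, st$L))
    events[[length(events) + 1L]] <-
      data.frame(time = schedule$horizon,
                 T_I_pre = pre[1], I_pre = pre[2], T_NI_pre = pre[3], L_pre = pre[4],
                 T_I_post = y[1], I_post = y[2], T_NI_post = y[3], L_post = y[4])
    add_row(schedule$horizon, pre, "pre_rt")
    add_row(schedule$horizon, y, "post_rt")
  }

  m <- do.call(rbind, lapply(rows, function(r) c(r$t, r$y)))
  phase <- vapply(rows, function(r) r$phase, character(1))
  ord <- order(m[, 1], match(phase, c("pre_rt", "sample", "post_rt")))
  m <- m[ord, , drop = FALSE]
  phase <- phase[ord]
  delta <- if (inert) rep(0, nrow(m))
           else ici$delta0 * vapply(m[, 1], ici_decay_factor, numeric(1), ici = ici)
  traj <- data.frame(time_d = m[, 1], T_I = m[, 2], I = m[, 3],
                     T_NI = m[, 4], L = m[, 5], delta_trem = delta,
                     diameter_irr_cm = cells_to_diameter(m[, 2] + m[, 3],
                                                         p$tumor_density),
                     diameter_nonirr_cm = cells_to_diameter(m[, 4],
                                                            p$tumor_density),
                     patient_id = patient_id)
  attr(traj, "events") <- if (length(events)) do.call(rbind, events)
                          else data.frame()
  attr(traj, "phase") <- phase
  class(traj) <- c("tumor_trajectory", "data.frame")
  traj
}

#' Write a trajectory to a tidy CSV file
#'
#' @param traj A `tumor_trajectory` (or a list of them).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (inherits(traj, "tumor_trajectory")) traj <- list(traj)
  tab <- do.call(rbind, lapply(traj, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
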