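#' Model parameters of the tumor-immune interaction system
#'
#' Fixed population-average rate constants of the four-compartment
#' tumor-immune model and the radiobiological (linear-quadratic, LQ)
#' parameters.  Defaults are the published population averages for
#' hepatocellular carcinoma; the tumor LQ beta is derived from the
#' alpha/beta ratio and is not set directly.
#'
#' @param a Tumor growth rate (1/d).
#' @param omega1 Tumor-directed lymphocyte killing efficiency (1/d).
#' @param omega2 Lymphocyte recruitment constant driven by viable tumor (1/d).
#' @param omega3 Lymphocyte recruitment constant driven by dying
#'   (inactivated) tumor cells (1/d).
#' @param g Half-saturation constant (cells).
#' @param s Lymphocyte regeneration rate (cells/d).
#' @param f Lymphocyte decay rate (1/d).
#' @param r Decay rate of the dying-cell compartment (1/d).
#' @param alpha_T Tumor LQ alpha (1/Gy).
#' @param alphabeta_ratio_T Tumor alpha/beta ratio (Gy); beta_T is derived
#'   as `alpha_T / alphabeta_ratio_T`.
#' @param alpha_L Lymphocyte LQ alpha (1/Gy).  Lymphocyte radiation kill is
#'   purely linear in dose (no beta term).
#' @param tumor_density Tumor cell density (cells/cm^3) used to convert
#'   between cell counts and lesion diameters.
#' @param delta_target Which recruitment term the checkpoint-inhibitor
#'   efficacy multiplies: `"omega2"` (default, viable-tumor-driven
#'   recruitment) or `"omega3"` (dying-cell-driven recruitment, provided as
#'   a sensitivity switch).
#'
#' @return An object of class `model_parameters`: a named list of the rates
#'   above plus the derived `beta_T`.
#' @examples
#' p <- model_parameters()
#' p$beta_T  # 0.139 / 14.3
#' @export
model_parameters <- function(a = 0.01, omega1 = 0.119, omega2 = 0.003,
                             omega3 = 0.009, g = 7.33e10, s = 1.47e8,
                             f = 0.033, r = 0.14, alpha_T = 0.139,
                             alphabeta_ratio_T = 14.3, alpha_L = 0.737,
                             tumor_density = 1e9,
                             delta_target = c("omega2", "omega3")) {
  delta_target <- match.arg(delta_target)
  p <- list(a = a, omega1 = omega1, omega2 = omega2, omega3 = omega3,
            g = g, s = s, f = f, r = r, alpha_T = alpha_T,
            alphabeta_ratio_T = alphabeta_ratio_T, alpha_L = alpha_L,
            tumor_density = tumor_density)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("model parameter '", nm, "' must be a single strictly positive number",
           call. = FALSE)
    }
  }
  p$beta_T <- alpha_T / alphabeta_ratio_T
  p$delta_target <- delta_target
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Tumor-immune model parameters\n")
  cat(sprintf("  growth a = %g /d;  kill omega1 = %g /d\n", x$a, x$omega1))
  cat(sprintf("  recruitment omega2 = %g /d (ICI target: %s), omega3 = %g /d\n",
              x$omega2, x$delta_target, x$omega3))
  cat(sprintf("  g = %g cells;  s = %g cells/d;  f = %g /d;  r = %g /d\n",
              x$g, x$s, x$f, x$r))
  cat(sprintf("  LQ: alpha_T = %g /Gy, alpha/beta = %g Gy (beta_T = %g), alpha_L = %g /Gy\n",
              x$alpha_T, x$alphabeta_ratio_T, x$beta_T, x$alpha_L))
  cat(sprintf("  tumor density = %g cells/cm^3\n", x$tumor_density))
  invisible(x)
}

#' Checkpoint-inhibitor pharmacodynamics
#'
#' Describes the time course of the dimensionless tremelimumab efficacy
#' term.  The efficacy is `delta0` at each administration and decays
#' exponentially with rate `lambda = log(2) / half_life`; with repeat
#' dosing the decay clock resets at every administration.
#'
#' The default dosing schedule is one administration every 90 days,
#' matching the quarterly regimen of the tremelimumab monotherapy trial the
#' efficacy distribution is calibrated against; the default 22-day
#' half-life is the published elimination half-life of tremelimumab.  Both
#' are assumptions (neither is a fitted model constant) and both are
#' configurable.
#'
#' @param delta0 Initial efficacy at each administration (dimensionless,
#'   >= 0).
#' @param half_life Drug half-life (d, > 0; `Inf` gives a constant,
#'   non-decaying efficacy).
#' @param start_time First administration time (d).
#' @param repeat_interval Re-dosing interval (d), or `NULL` for a single
#'   administration.
#'
#' @return An object of class `ici_pharmacodynamics` with the fields above
#'   plus the decay constant `lambda`.
#' @seealso [delta_trem_at()]
#' @export
ici_pharmacodynamics <- function(delta0 = 37, half_life = 22, start_time = 0,
                                 repeat_interval = 90) {
  if (!is.numeric(delta0) || length(delta0) != 1L || is.na(delta0) || delta0 < 0)
    stop("delta0 must be a single non-negative number", call. = FALSE)
  if (!is.numeric(half_life) || length(half_life) != 1L || is.na(half_life) ||
      half_life <= 0)
    stop("half_life must be a single positive number (Inf allowed)", call. = FALSE)
  if (!is.numeric(start_time) || length(start_time) != 1L || !is.finite(start_time) ||
      start_time < 0)
    stop("start_time must be a single non-negative number", call. = FALSE)
  if (!is.null(repeat_interval)) {
    if (!is.numeric(repeat_interval) || length(repeat_interval) != 1L ||
        !is.finite(repeat_interval) || repeat_interval <= 0)
      stop("repeat_interval must be NULL or a single positive number", call. = FALSE)
  }
  structure(list(delta0 = delta0, half_life = half_life,
                 start_time = start_time, repeat_interval = repeat_interval,
                 lambda = log(2) / half_life),
            class = "ici_pharmacodynamics")
}

#' @export
print.ici_pharmacodynamics <- function(x, ...) {
  dosing <- if (is.null(x$repeat_interval)) "single dose"
            else sprintf("re-dosed every %g d", x$repeat_interval)
  cat(sprintf("ICI pharmacodynamics: delta0 = %g, half-life = %g d (lambda = %.4g /d)\n",
              x$delta0, x$half_life, x$lambda))
  cat(sprintf("  first dose at day %g, %s\n", x$start_time, dosing))
  invisible(x)
}

#' Radiotherapy fraction table
#'
#' Convenience constructor for a table of radiotherapy fractions.  The
#' default regimen -- 8 Gy per fraction to the tumor in 5 daily fractions,
#' with an effective whole-blood (lymphocyte) dose of 0.5 Gy per fraction --
#' is a declared assumption: the calibrating trial's regimen is not part of
#' the model and every component is configurable.
#'
#' @param start_time Time of the first fraction (d).
#' @param n_fractions Number of fractions.
#' @param dose_tumor Tumor dose per fraction (Gy).
#' @param dose_lymph Effective lymphocyte (whole blood) dose per fraction (Gy).
#' @param interval Time between fractions (d).
#'
#' @return A data.frame with columns `time`, `dose_tumor`, `dose_lymph`,
#'   one row per fraction.
#' @export
rt_fractions <- function(start_time = 0, n_fractions = 5, dose_tumor = 8,
                         dose_lymph = 0.5, interval = 1) {
  stopifnot(n_fractions >= 1, interval > 0, start_time >= 0)
  data.frame(time = start_time + (seq_len(n_fractions) - 1) * interval,
             dose_tumor = dose_tumor, dose_lymph = dose_lymph)
}

#' Treatment schedule
#'
#' Combines timed radiotherapy fraction events, an optional
#' checkpoint-inhibitor administration plan and the follow-up horizon into
#' a validated schedule object consumed by [simulate_patient()] and
#' [simulate_cohort()].
#'
#' @param rt A data.frame of RT fractions as produced by [rt_fractions()]
#'   (columns `time`, `dose_tumor`, `dose_lymph`), or `NULL` for no
#'   radiotherapy.
#' @param ici An [ici_pharmacodynamics()] object, or `NULL` for no
#'   checkpoint inhibition.
#' @param horizon Follow-up duration (d); all event times must lie within
#'   `[0, horizon]`.
#'
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(rt = NULL, ici = NULL, horizon = 365) {
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0)
    stop("horizon must be a single positive number", call. = FALSE)
  if (!is.null(rt)) {
    rt <- as.data.frame(rt)
    need <- c("time", "dose_tumor", "dose_lymph")
    if (!all(need %in% names(rt)))
      stop("rt must have columns time, dose_tumor, dose_lymph", call. = FALSE)
    if (nrow(rt) == 0L) rt <- NULL
  }
  if (!is.null(rt)) {
    if (any(diff(rt$time) <= 0))
      stop("RT fraction times must be strictly increasing", call. = FALSE)
    if (any(rt$time < 0) || any(rt$time > horizon))
      stop("RT fraction times must lie within [0, horizon]", call. = FALSE)
    if (any(rt$dose_tumor < 0) || any(rt$dose_lymph < 0))
      stop("RT doses must be non-negative", call. = FALSE)
  }
  if (!is.null(ici)) {
    if (!inherits(ici, "ici_pharmacodynamics"))
      stop("ici must be an ici_pharmacodynamics object or NULL", call. = FALSE)
    if (ici$start_time > horizon)
      stop("ICI start time lies beyond the schedule horizon", call. = FALSE)
  }
  structure(list(rt = rt, ici = ici, horizon = horizon),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("Treatment schedule over %g d\n", x$horizon))
  if (is.null(x$rt)) cat("  RT: none\n")
  else cat(sprintf("  RT: %d fraction(s), tumor dose %s Gy, lymphocyte dose %s Gy, days %s\n",
                   nrow(x$rt), paste(unique(x$rt$dose_tumor), collapse = "/"),
                   paste(unique(x$rt$dose_lymph), collapse = "/"),
                   paste(signif(x$rt$time, 4), collapse = ", ")))
  if (is.null(x$ici)) cat("  ICI: none\n")
  else print(x$ici)
  invisible(x)
}

# administration times of the ICI within [0, horizon]
ici_dose_times <- function(ici, horizon) {
  if (is.null(ici)) return(numeric(0))
  if (is.null(ici$repeat_interval)) return(ici$start_time)
  seq(ici$start_time, horizon, by = ici$repeat_interval)
}

# short deterministic fingerprint of a parameter set, for provenance blocks
param_fingerprint <- function(p) {
  nm <- setdiff(names(p), "delta_target")
  s <- paste(nm, vapply(p[nm], function(v) formatC(v, digits = 17, format = "g"),
                        character(1)), sep = "=", collapse = ";")
  s <- paste0(s, ";delta_target=", p$delta_target)
  codes <- utf8ToInt(s)
  sprintf("%08x", sum(codes * seq_along(codes)) %% 4294967296)
}
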