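#' @keywords internal
fit_mu_sigma <- function(fit) {
  if (is.null(fit))
    stop(paste("no calibrated efficacy distribution supplied; run",
               "fit_delta_distribution() on a response_curve() first",
               "(CLI: the 'calibrate' subcommand)"), call. = FALSE)
  if (inherits(fit, "delta_fit")) return(c(mu = fit$mu, sigma = fit$sigma))
  if (is.list(fit)) return(c(mu = fit$mu, sigma = fit$sigma))
  if (is.numeric(fit) && length(fit) == 2L)
    return(c(mu = fit[[1]], sigma = fit[[2]]))
  stop("fit must be a delta_fit object or c(mu, sigma)", call. = FALSE)
}

modality_levels <- c("none", "ici", "rt", "rt_ici")

# schedule for one treatment arm
arm_schedule <- function(modality, horizon, ici_template, rt_template,
                         rt_start = 0, ici_start = 0) {
  rt <- NULL
  ici <- NULL
  if (modality %in% c("rt", "rt_ici")) {
    rt <- rt_template
    rt$time <- rt$time - min(rt$time) + rt_start
  }
  if (modality %in% c("ici", "rt_ici")) {
    ici <- ici_template
    ici$start_time <- ici_start
  }
  treatment_schedule(rt = rt, ici = ici, horizon = horizon)
}

experiment_provenance <- function(seed, p, ici, rt, extra = list()) {
  c(list(seed = seed,
         parameter_fingerprint = param_fingerprint(p),
         ici_half_life_d = ici$half_life,
         ici_repeat_interval_d = if (is.null(ici$repeat_interval)) NA
                                 else ici$repeat_interval,
         ici_assumption = "half-life and dosing interval are configuration assumptions, not fitted constants",
         rt_regimen = sprintf("%d x %g Gy (tumor), %g Gy effective lymphocyte dose per fraction, every %g d [assumed regimen]",
                              nrow(rt), rt$dose_tumor[1], rt$dose_lymph[1],
                              if (nrow(rt) > 1) diff(rt$time)[1] else NA),
         package_version = as.character(utils::packageVersion("rtici"))),
    extra)
}

#' Compare treatment modalities on a shared virtual cohort
#'
#' Simulates the same seeded cohort under four arms -- no treatment,
#' checkpoint inhibition alone, radiotherapy alone, and the combination --
#' and summarizes per-lesion and whole-patient RECIST responses together
#' with waterfall values (best percent diameter change).  The no-treatment
#' and RT-only arms use zero drug efficacy; the drug-containing arms draw
#' each patient's efficacy from the calibrated distribution.
#'
#' @param fit Calibrated efficacy distribution: a `delta_fit` or
#'   `c(mu, sigma)`.
#' @param n_patients Cohort size (default 100, the size used for waterfall
#'   displays).
#' @param itf Irradiated tumor fraction splitting each patient's baseline
#'   burden (default 0.5, an assumption).
#' @param seed Cohort RNG seed.
#' @param p [model_parameters()].
#' @param ici [ici_pharmacodynamics()] timing template (its `delta0` is
#'   ignored; patients carry their own).
#' @param rt RT fraction table template, see [rt_fractions()].
#' @param horizon Follow-up horizon (d).
#' @param rules [recist_rules()].
#' @param cohort_cfg Optional full [population_config()]; when supplied,
#'   `n_patients`, `itf` and `seed` are taken from it.
#' @param ... Passed to [simulate_cohort()].
#'
#' @return An object of class `modality_comparison`: `summaries` (tidy
#'   data.frame of category fractions and CBR per arm and lesion class),
#'   `waterfall` (per patient, arm and lesion), and a `provenance` list.
#' @export
run_modality_comparison <- function(fit, n_patients = 100, itf = 0.5,
                                    seed = 1L, p = model_parameters(),
                                    ici = ici_pharmacodynamics(),
                                    rt = rt_fractions(), horizon = 365,
                                    rules = recist_rules(),
                                    cohort_cfg = NULL, ...) {
  ms <- fit_mu_sigma(fit)
  if (is.null(cohort_cfg))
    cohort_cfg <- population_config(n_patients = n_patients, itf = itf,
                                    delta0_mean = ms[["mu"]],
                                    delta0_sd = ms[["sigma"]], seed = seed)
  else {
    cohort_cfg$delta0_mean <- ms[["mu"]]
    cohort_cfg$delta0_sd <- ms[["sigma"]]
  }
  cohort <- sample_cohort(cohort_cfg, p)
  summaries <- list()
  waterfall <- list()
  for (arm in modality_levels) {
    sch <- arm_schedule(arm, horizon, ici, rt)
    d0 <- if (arm %in% c("ici", "rt_ici")) cohort$delta0 else 0
    sim <- simulate_cohort(cohort, p, sch, delta0 = d0, ...)
    for (lesion in c("irradiated", "non_irradiated", "sum")) {
      ev <- evaluate_cohort(sim, lesion = lesion, rules = rules)
      summaries[[length(summaries) + 1L]] <- if (all(is.na(ev$category))) {
        # lesion class absent at baseline (e.g. ITF = 1): non-evaluable
        data.frame(arm = arm, lesion = lesion, n_evaluable = 0L,
                   CR = NA_real_, PR = NA_real_, SD = NA_real_,
                   PD = NA_real_, cbr = NA_real_)
      } else {
        sm <- summarize_response(ev$category, ev$best_change_pct)
        data.frame(arm = arm, lesion = lesion, n_evaluable = sm$n,
                   CR = sm$fractions[["CR"]], PR = sm$fractions[["PR"]],
                   SD = sm$fractions[["SD"]], PD = sm$fractions[["PD"]],
                   cbr = sm$cbr)
      }
      waterfall[[length(waterfall) + 1L]] <-
        data.frame(arm = arm, lesion = lesion, id = ev$id,
                   best_change_pct = ev$best_change_pct,
                   final_change_pct = ev$final_change_pct,
                   category = ev$category)
    }
  }
  structure(list(summaries = do.call(rbind, summaries),
                 waterfall = do.call(rbind, waterfall),
                 provenance = experiment_provenance(
                   cohort_cfg$seed, p, ici, rt,
                   list(n_patients = cohort_cfg$n_patients,
                        itf = cohort_cfg$itf,
                        delta_mu = ms[["mu"]], delta_sigma = ms[["sigma"]]))),
            class = "modality_comparison")
}

#' @export
print.modality_comparison <- function(x, ...) {
  cat("Modality comparison (fractions by arm and lesion class)\n")
  print(transform(x$summaries, CR = round(CR, 3), PR = round(PR, 3),
                  SD = round(SD, 3), PD = round(PD, 3), cbr = round(cbr, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Sweep the irradiated tumor fraction
#'
#' For each irradiated-tumor-fraction value and each treatment arm, the
#' seeded cohort is re-split (the sampled patients are identical across
#' the sweep; only the burden split changes) and the mean one-year
#' diameter change of the irradiated and non-irradiated lesions is
#' recorded.
#'
#' Fractions above 1 are rejected: the irradiated tumor fraction is
#' `T_I / (T_I + T_NI)` and cannot exceed 1.
#'
#' @param fit,n_patients,seed,p,ici,rt,horizon,rules,... As in
#'   [run_modality_comparison()].
#' @param itf_values Sweep values in `(0, 1]`.
#' @param modalities Arms to run (subset of `none`, `ici`, `rt`, `rt_ici`).
#'
#' @return An object of class `itf_sweep`: a tidy data.frame `table` with
#'   columns `itf`, `arm`, `lesion`, `mean_change_pct`, `sd_change_pct`,
#'   `n_evaluable`, plus `provenance`.
#' @export
run_itf_sweep <- function(fit, itf_values = c(0.001, 0.01, 0.05, 0.1, 0.25,
                                              0.5, 0.75, 0.9, 0.99, 1),
                          modalities = modality_levels, n_patients = 100,
                          seed = 1L, p = model_parameters(),
                          ici = ici_pharmacodynamics(), rt = rt_fractions(),
                          horizon = 365, rules = recist_rules(), ...) {
  if (any(itf_values > 1))
    stop(paste("irradiated tumor fractions above 1 are not expressible:",
               "ITF = T_I / (T_I + T_NI) is bounded by 1"), call. = FALSE)
  if (any(itf_values <= 0))
    stop("irradiated tumor fractions must be positive", call. = FALSE)
  modalities <- match.arg(modalities, modality_levels, several.ok = TRUE)
  ms <- fit_mu_sigma(fit)
  rows <- list()
  for (itf in itf_values) {
    cfg <- population_config(n_patients = n_patients, itf = itf,
                             delta0_mean = ms[["mu"]], delta0_sd = ms[["sigma"]],
                             seed = seed)
    cohort <- sample_cohort(cfg, p)
    for (arm in modalities) {
      sch <- arm_schedule(arm, horizon, ici, rt)
      d0 <- if (arm %in% c("ici", "rt_ici")) cohort$delta0 else 0
      sim <- simulate_cohort(cohort, p, sch, delta0 = d0, ...)
      for (lesion in c("irradiated", "non_irradiated")) {
        ev <- evaluate_cohort(sim, lesion = lesion, rules = rules)
        chg <- ev$final_change_pct[!is.na(ev$final_change_pct)]
        rows[[length(rows) + 1L]] <-
          data.frame(itf = itf, arm = arm, lesion = lesion,
                     mean_change_pct = if (length(chg)) mean(chg) else NA_real_,
                     sd_change_pct = if (length(chg) > 1) stats::sd(chg) else NA_real_,
                     n_evaluable = length(chg))
      }
    }
  }
  structure(list(table = do.call(rbind, rows),
                 provenance = experiment_provenance(
                   seed, p, ici, rt,
                   list(n_patients = n_patients,
                        itf_values = paste(itf_values, collapse = ","),
                        delta_mu = ms[["mu"]], delta_sigma = ms[["sigma"]]))),
            class = "itf_sweep")
}

#' Sweep the sequencing offset between radiotherapy and checkpoint blockade
#'
#' Runs the combination arm with the two modalities offset by whole
#' months.  Radiotherapy is anchored at `rt_anchor_d` and the checkpoint
#' inhibitor starts `offset` months before it: a positive offset starts
#' the drug first, a negative offset starts radiotherapy first, and with
#' an inert drug every offset yields the same outcome by construction.
#' Offsets are evaluated for high and low irradiated tumor fractions.  If
#' the shifted schedule would extend beyond the horizon, the horizon is
#' extended to cover it with a warning.
#'
#' @param fit,n_patients,seed,p,ici,rt,horizon,rules,... As in
#'   [run_modality_comparison()].
#' @param offsets_months Whole-month offsets within +/- 6 (positive: drug
#'   first).
#' @param itf_values Irradiated tumor fractions to evaluate.
#' @param month_d Days per month used to place the schedules (default 30).
#' @param rt_anchor_d Day the first radiotherapy fraction is delivered
#'   (default 180, the middle of the one-year horizon, so the drug start
#'   stays non-negative across the full offset range).
#'
#' @return An object of class `sequencing_sweep`: a tidy data.frame
#'   `table` with columns `offset_months`, `itf`, `lesion`,
#'   `mean_change_pct`, `sd_change_pct`, `n_evaluable`, plus `provenance`
#'   and the per-offset schedules in `schedules` (for introspection).
#' @export
run_sequencing_sweep <- function(fit, offsets_months = -6:6,
                                 itf_values = c(0.99, 0.01),
                                 n_patients = 100, seed = 1L,
                                 p = model_parameters(),
                                 ici = ici_pharmacodynamics(),
                                 rt = rt_fractions(), horizon = 365,
                                 rules = recist_rules(), month_d = 30,
                                 rt_anchor_d = 180, ...) {
  if (any(offsets_months != round(offsets_months)))
    stop("offsets must be whole months", call. = FALSE)
  if (any(abs(offsets_months) > 6))
    stop("offsets must lie within +/- 6 months", call. = FALSE)
  if (rt_anchor_d - max(offsets_months) * month_d < 0)
    stop("rt_anchor_d too early: the drug would have to start before day 0",
         call. = FALSE)
  ms <- fit_mu_sigma(fit)
  rows <- list()
  schedules <- list()
  for (itf in itf_values) {
    cfg <- population_config(n_patients = n_patients, itf = itf,
                             delta0_mean = ms[["mu"]], delta0_sd = ms[["sigma"]],
                             seed = seed)
    cohort <- sample_cohort(cfg, p)
    for (off in offsets_months) {
      rt_start <- rt_anchor_d
      ici_start <- rt_anchor_d - off * month_d
      last_event <- max(rt_start + max(rt$time) - min(rt$time), ici_start)
      h <- horizon
      if (last_event > h) {
        h <- last_event + 1
        warning(sprintf("offset %+d months extends past the horizon; extended to %g d",
                        off, h))
      }
      sch <- arm_schedule("rt_ici", h, ici, rt, rt_start = rt_start,
                          ici_start = ici_start)
      schedules[[sprintf("itf%g_off%+d", itf, off)]] <- sch
      sim <- simulate_cohort(cohort, p, sch, delta0 = cohort$delta0, ...)
      at_year <- which.min(abs(sim$times - 365))
      for (lesion in c("irradiated", "non_irradiated")) {
        d <- switch(lesion,
                    irradiated = cells_to_diameter(sim$T_I + sim$I, sim$density),
                    non_irradiated = cells_to_diameter(sim$T_NI, sim$density))
        ok <- d[1, ] > 0
        chg <- 100 * (d[at_year, ok] / d[1, ok] - 1)
        rows[[length(rows) + 1L]] <-
          data.frame(offset_months = off, itf = itf, lesion = lesion,
                     mean_change_pct = if (length(chg)) mean(chg) else NA_real_,
                     sd_change_pct = if (length(chg) > 1) stats::sd(chg) else NA_real_,
                     n_evaluable = sum(ok))
      }
    }
  }
  structure(list(table = do.call(rbind, rows), schedules = schedules,
                 provenance = experiment_provenance(
                   seed, p, ici, rt,
                   list(n_patients = n_patients,
                        offsets_months = paste(offsets_months, collapse = ","),
                        itf_values = paste(itf_values, collapse = ","),
                        delta_mu = ms[["mu"]], delta_sigma = ms[["sigma"]]))),
            class = "sequencing_sweep")
}

#' Write an experiment's tables and run manifest to a directory
#'
#' Writes every tabular component of a [run_modality_comparison()],
#' [run_itf_sweep()] or [run_sequencing_sweep()] result as a tidy CSV and
#' the provenance block as `manifest.json`.  Output is deterministic:
#' identical inputs produce byte-identical files.
#'
#' @param x An experiment result object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_experiment_tables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- Filter(is.data.frame, unclass(x))
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(x$provenance)) {
    jsonlite::write_json(x$provenance, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}
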