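#' Reference response rates of the calibrating tremelimumab trial
#'
#' RECIST 1.1 response rates reported for tremelimumab monotherapy in
#' hepatocellular carcinoma: CR 0%, PR 17.6%, SD 58.8%; PD (23.6%) is the
#' complement.
#'
#' @return Named numeric vector of fractions over `CR`, `PR`, `SD`, `PD`.
#' @export
reference_trial_rates <- function() {
  c(CR = 0, PR = 0.176, SD = 0.588, PD = 0.236)
}

#' Response-rate curve over a grid of fixed efficacy values
#'
#' First stage of the calibration procedure: one cohort is sampled and
#' reused across the whole grid (common random numbers), every patient's
#' `delta0` is fixed to each grid value in turn, the drug-only (no
#' radiotherapy) schedule is simulated, and the whole-patient RECIST
#' category fractions are recorded per grid value.
#'
#' @param cohort_cfg A [population_config()]; its `delta0` distribution is
#'   ignored (the grid overrides it).
#' @param p [model_parameters()].
#' @param ici An [ici_pharmacodynamics()] giving the administration timing
#'   and half-life; its `delta0` is overridden by the grid.
#' @param grid Efficacy values; integers 0..99 by default.
#' @param horizon Follow-up horizon (d).
#' @param rules [recist_rules()] used for classification.
#' @param dt_out Assessment interval (d); monthly by default.
#' @param ... Passed to [simulate_cohort()] (e.g. `rtol`, `method`).
#'
#' @return A data.frame of class `response_curve` with columns `delta`,
#'   `CR`, `PR`, `SD`, `PD` (fractions summing to 1 in each row).
#' @export
response_curve <- function(cohort_cfg, p = model_parameters(),
                           ici = ici_pharmacodynamics(), grid = 0:99,
                           horizon = 365, rules = recist_rules(),
                           dt_out = 365 / 12, ...) {
  cohort <- sample_cohort(cohort_cfg, p)
  schedule <- treatment_schedule(rt = NULL, ici = ici, horizon = horizon)
  rates <- matrix(NA_real_, length(grid), 4,
                  dimnames = list(NULL, recist_levels))
  for (i in seq_along(grid)) {
    sim <- tryCatch(
      simulate_cohort(cohort, p, schedule, dt_out = dt_out,
                      delta0 = grid[i], ...),
      error = function(e) stop("response_curve failed at delta = ", grid[i],
                               ": ", conditionMessage(e), call. = FALSE))
    ev <- evaluate_cohort(sim, lesion = "sum", rules = rules)
    rates[i, ] <- summarize_response(ev$category)$fractions
  }
  out <- data.frame(delta = grid, rates)
  class(out) <- c("response_curve", "data.frame")
  out
}

#' Convolve a response curve with a normal efficacy distribution
#'
#' Mixes the per-efficacy category rates with normal-density weights
#' evaluated at the grid points, truncated to the grid and renormalized to
#' sum to one.  `sigma = 0` degenerates to the grid point nearest `mu`.
#'
#' @param curve A [response_curve()] (or data.frame with columns `delta`,
#'   `CR`, `PR`, `SD`, `PD`).
#' @param mu,sigma Mean and standard deviation of the efficacy
#'   distribution (`sigma >= 0`).
#'
#' @return Named numeric vector of mixed category fractions.
#' @export
convolve_rates <- function(curve, mu, sigma) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  rates <- as.matrix(curve[, recist_levels])
  if (sigma == 0) {
    i <- which.min(abs(curve$delta - mu))
    out <- rates[i, ]
  } else {
    w <- stats::dnorm(curve$delta, mu, sigma)
    sw <- sum(w)
    if (!is.finite(sw) || sw < 1e-12)
      stop(sprintf(paste0("degenerate convolution weights at mu = %g, ",
                          "sigma = %g: the distribution places essentially ",
                          "no mass on the efficacy grid"), mu, sigma),
           call. = FALSE)
    out <- colSums(rates * (w / sw))
  }
  names(out) <- recist_levels
  out
}

#' Fit the efficacy distribution to reference response rates
#'
#' Second stage of the calibration procedure: a grid search over candidate
#' `(mu, sigma)` pairs, scoring each by the sum of absolute differences
#' between the convolved category rates and the reference rates.  CR is
#' excluded from the score by default (its reference is exactly zero and
#' the curve's CR column is zero over most of the grid); pass
#' `categories = c("CR", "PR", "SD", "PD")` to include it.  Ties are broken
#' toward the smallest `sigma`, then the smallest `mu`.
#'
#' @param curve A [response_curve()].
#' @param reference Named fractions over the four categories; defaults to
#'   [reference_trial_rates()].
#' @param mu_grid,sigma_grid Search grids (non-empty).
#' @param categories Categories entering the discrepancy score.
#'
#' @return An object of class `delta_fit`: the fitted `mu` and `sigma`,
#'   the full discrepancy `heatmap` (mu by sigma), the `predicted` rates at
#'   the optimum, the attained minimum `discrepancy`, the grids and the
#'   reference.
#' @export
fit_delta_distribution <- function(curve, reference = reference_trial_rates(),
                                   mu_grid = 0:99,
                                   sigma_grid = seq(0.5, 20, by = 0.5),
                                   categories = c("PR", "SD", "PD")) {
  if (length(mu_grid) == 0L || length(sigma_grid) == 0L)
    stop("mu_grid and sigma_grid must be non-empty", call. = FALSE)
  stopifnot(all(categories %in% recist_levels))
  if (abs(sum(reference[recist_levels]) - 1) > 1e-8)
    stop("reference rates must sum to 1 over CR/PR/SD/PD", call. = FALSE)
  heat <- matrix(NA_real_, length(mu_grid), length(sigma_grid),
                 dimnames = list(mu = mu_grid, sigma = sigma_grid))
  for (j in seq_along(sigma_grid)) {
    for (i in seq_along(mu_grid)) {
      # candidates whose mass misses the grid entirely score +Inf
      heat[i, j] <- tryCatch({
        pred <- convolve_rates(curve, mu_grid[i], sigma_grid[j])
        sum(abs(pred[categories] - reference[categories]))
      }, error = function(e) Inf)
    }
  }
  if (!any(is.finite(heat)))
    stop("no (mu, sigma) candidate places mass on the efficacy grid",
         call. = FALSE)
  best <- min(heat)
  cand <- which(heat <= best + 1e-15, arr.ind = TRUE)
  # smallest sigma first, then smallest mu
  cand <- cand[order(sigma_grid[cand[, 2]], mu_grid[cand[, 1]]), , drop = FALSE]
  mu <- mu_grid[cand[1, 1]]
  sigma <- sigma_grid[cand[1, 2]]
  structure(list(mu = mu, sigma = sigma, heatmap = heat,
                 predicted = convolve_rates(curve, mu, sigma),
                 discrepancy = heat[cand[1, 1], cand[1, 2]],
                 mu_grid = mu_grid, sigma_grid = sigma_grid,
                 reference = reference, categories = categories),
            class = "delta_fit")
}

#' @export
print.delta_fit <- function(x, ...) {
  cat(sprintf("Fitted efficacy distribution: mu = %g, sigma = %g (discrepancy %.4f over %s)\n",
              x$mu, x$sigma, x$discrepancy, paste(x$categories, collapse = "/")))
  cat(sprintf("  predicted: CR %.1f%%  PR %.1f%%  SD %.1f%%  PD %.1f%%\n",
              100 * x$predicted[["CR"]], 100 * x$predicted[["PR"]],
              100 * x$predicted[["SD"]], 100 * x$predicted[["PD"]]))
  cat(sprintf("  reference: CR %.1f%%  PR %.1f%%  SD %.1f%%  PD %.1f%%\n",
              100 * x$reference[["CR"]], 100 * x$reference[["PR"]],
              100 * x$reference[["SD"]], 100 * x$reference[["PD"]]))
  invisible(x)
}

#' Validate a fitted efficacy distribution on a fresh cohort
#'
#' Samples a fresh cohort whose `delta0` values are drawn from the fitted
#' normal distribution (truncated at zero), simulates the drug-only
#' schedule and summarizes the RECIST responses, for comparison with the
#' reference rates.
#'
#' @param fit A `delta_fit` (or a list/vector with `mu` and `sigma`).
#' @param cohort_cfg A [population_config()]; its `delta0` mean/sd are
#'   replaced by the fitted values.
#' @param p,ici,horizon,rules,dt_out,... As in [response_curve()].
#'
#' @return A [summarize_response()] object.
#' @export
validate_calibration <- function(fit, cohort_cfg, p = model_parameters(),
                                 ici = ici_pharmacodynamics(), horizon = 365,
                                 rules = recist_rules(), dt_out = 365 / 12, ...) {
  cfg <- cohort_cfg
  cfg$delta0_mean <- fit$mu
  cfg$delta0_sd <- fit$sigma
  cohort <- sample_cohort(cfg, p)
  schedule <- treatment_schedule(rt = NULL, ici = ici, horizon = horizon)
  sim <- simulate_cohort(cohort, p, schedule, dt_out = dt_out, ...)
  ev <- evaluate_cohort(sim, lesion = "sum", rules = rules)
  summarize_response(ev$category, ev$best_change_pct)
}
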