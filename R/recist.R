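#' Convert a cell count to a spherical-lesion diameter
#'
#' Inverts the spherical volume relation `n = density * (pi/6) * d^3`;
#' zero cells give a zero diameter.
#'
#' @param n_cells Cell count (>= 0); may be a vector or matrix.
#' @param density Tumor cell density (cells/cm^3).
#'
#' @return Diameter(s) in cm, same shape as `n_cells`.
#' @export
cells_to_diameter <- function(n_cells, density = 1e9) {
  if (any(n_cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  (6 * n_cells / (pi * density))^(1 / 3)
}

#' RECIST 1.1 classification thresholds
#'
#' The numeric thresholds of the RECIST 1.1 rules as adopted here: partial
#' response at a best diameter change of -30% or better from baseline,
#' progression at a +20% increase over the running nadir together with an
#' absolute increase of at least 5 mm, and complete response when the
#' diameter falls below a 1 mm floor (a concrete surrogate for lesion
#' disappearance).  All values are configurable.
#'
#' @param pr_change Best fractional change from baseline at or below which
#'   the response is PR (default -0.30).
#' @param pd_change Fractional increase over the nadir at or above which
#'   progression is declared (default 0.20).
#' @param pd_min_abs_cm Minimum absolute increase over the nadir (cm)
#'   required for progression (default 0.5 cm = 5 mm); set to 0 to drop
#'   the absolute guard.
#' @param cr_floor_cm Diameter (cm) below which a lesion counts as having
#'   disappeared (default 0.1 cm = 1 mm).
#'
#' @return A list of class `recist_rules`.
#' @export
recist_rules <- function(pr_change = -0.30, pd_change = 0.20,
                         pd_min_abs_cm = 0.5, cr_floor_cm = 0.1) {
  stopifnot(pr_change < 0, pd_change > 0, pd_min_abs_cm >= 0, cr_floor_cm >= 0)
  structure(list(pr_change = pr_change, pd_change = pd_change,
                 pd_min_abs_cm = pd_min_abs_cm, cr_floor_cm = cr_floor_cm),
            class = "recist_rules")
}

recist_levels <- c("CR", "PR", "SD", "PD")

# vectorized classifier: baseline (length n) and follow-up diameter matrix
# (n x m, assessments in time order).  Returns a factor of categories.
classify_matrix <- function(baseline, followup, rules) {
  n <- length(baseline)
  followup <- matrix(followup, nrow = n)
  m <- ncol(followup)
  # running nadir *before* each assessment, baseline included
  nadir <- matrix(0, n, m)
  cur <- baseline
  for (j in seq_len(m)) {
    nadir[, j] <- cur
    cur <- pmin(cur, followup[, j])
  }
  pd <- rowSums(followup >= nadir * (1 + rules$pd_change) &
                followup - nadir >= rules$pd_min_abs_cm) > 0
  best <- apply(followup, 1, min)
  best_change <- (best - baseline) / baseline
  out <- rep("SD", n)
  out[best_change <= rules$pr_change] <- "PR"
  out[best < rules$cr_floor_cm] <- "CR"
  out[pd] <- "PD"
  factor(out, levels = recist_levels)
}

#' Classify one lesion's response under RECIST 1.1
#'
#' Progression takes precedence: if any assessment is at least
#' `pd_change` above the running nadir (baseline included) and at least
#' `pd_min_abs_cm` above it in absolute terms, the response is PD
#' regardless of later shrinkage.  Otherwise the best (smallest) diameter
#' over follow-up determines the category: CR below the disappearance
#' floor, PR at a change of `pr_change` or better from baseline, SD
#' otherwise.
#'
#' @param baseline_d Baseline diameter (cm, > 0).
#' @param followup_d Follow-up diameters (cm) in time order, or a
#'   data.frame with columns `time` and `diameter`.
#' @param rules A [recist_rules()] object.
#'
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"` (factor).
#' @export
classify_response <- function(baseline_d, followup_d, rules = recist_rules()) {
  if (is.data.frame(followup_d)) {
    followup_d <- followup_d$diameter[order(followup_d$time)]
  }
  if (length(followup_d) == 0L)
    stop("at least one follow-up assessment is required", call. = FALSE)
  if (!is.numeric(baseline_d) || length(baseline_d) != 1L || baseline_d <= 0)
    stop("baseline_d must be a single positive diameter", call. = FALSE)
  classify_matrix(baseline_d, matrix(followup_d, nrow = 1), rules)[1]
}

#' Summarize per-patient response categories
#'
#' @param categories Vector (factor or character) of per-patient RECIST
#'   categories; `NA` entries (non-evaluable patients, e.g. absent
#'   lesions) are dropped with a count kept.
#' @param percent_change Optional per-patient percent changes used as
#'   waterfall values (stored sorted, decreasing).
#'
#' @return An object of class `response_summary`: category fractions
#'   (summing to 1), the clinical benefit rate `CBR = 1 - PD`, the number
#'   of evaluable patients, and the waterfall values if given.
#' @export
summarize_response <- function(categories, percent_change = NULL) {
  categories <- factor(categories, levels = recist_levels)
  keep <- !is.na(categories)
  if (!any(keep)) stop("no evaluable patients", call. = FALSE)
  n <- sum(keep)
  frac <- as.numeric(table(categories[keep])) / n
  names(frac) <- recist_levels
  structure(list(fractions = frac, cbr = 1 - frac[["PD"]], n = n,
                 n_missing = sum(!keep),
                 waterfall = if (!is.null(percent_change))
                   sort(percent_change[keep], decreasing = TRUE)),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("RECIST summary over %d evaluable patient(s)%s\n", x$n,
              if (x$n_missing) sprintf(" (%d non-evaluable)", x$n_missing) else ""))
  cat(sprintf("  CR %.1f%%  PR %.1f%%  SD %.1f%%  PD %.1f%%   CBR %.1f%%\n",
              100 * x$fractions[["CR"]], 100 * x$fractions[["PR"]],
              100 * x$fractions[["SD"]], 100 * x$fractions[["PD"]],
              100 * x$cbr))
  invisible(x)
}

#' Evaluate RECIST responses for a simulated cohort
#'
#' Converts the simulated compartments to lesion diameters (the irradiated
#' lesion comprises viable irradiated plus dying cells, which still occupy
#' volume; the non-irradiated lesion is the metastatic compartment),
#' takes the first sample (t = 0) as baseline and the remaining samples as
#' the assessment schedule, and classifies each patient.
#'
#' `lesion = "sum"` classifies the RECIST-style sum of the two lesion
#' diameters (whole-patient, trial style); `"irradiated"` and
#' `"non_irradiated"` classify each lesion separately.  A lesion absent at
#' baseline yields `NA` (non-evaluable).
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param lesion Which diameter to classify.
#' @param rules A [recist_rules()] object.
#'
#' @return A data.frame with one row per patient: `id`, `baseline_cm`,
#'   `best_change_pct`, `final_change_pct`, `category`.
#' @export
evaluate_cohort <- function(sim, lesion = c("sum", "irradiated", "non_irradiated"),
                            rules = recist_rules()) {
  lesion <- match.arg(lesion)
  d_irr <- cells_to_diameter(sim$T_I + sim$I, sim$density)
  d_non <- cells_to_diameter(sim$T_NI, sim$density)
  d <- switch(lesion, sum = d_irr + d_non, irradiated = d_irr,
              non_irradiated = d_non)
  baseline <- d[1, ]
  followup <- t(d[-1, , drop = FALSE])   # n x m
  n <- length(baseline)
  category <- factor(rep(NA_character_, n), levels = recist_levels)
  ok <- baseline > 0
  if (any(ok)) {
    category[ok] <- classify_matrix(baseline[ok],
                                    followup[ok, , drop = FALSE], rules)
  }
  best <- apply(followup, 1, min)
  final <- followup[, ncol(followup)]
  data.frame(id = seq_len(n), baseline_cm = baseline,
             best_change_pct = ifelse(ok, 100 * (best / baseline - 1), NA_real_),
             final_change_pct = ifelse(ok, 100 * (final / baseline - 1), NA_real_),
             category = category)
}
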