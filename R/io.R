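#' Read model, treatment and cohort configuration from a YAML file
#'
#' The file may contain any of the top-level sections `parameters`, `ici`,
#' `rt`, `cohort` and `horizon`; keys within each section override the
#' package defaults (flat key/value maps; the RT section describes the
#' fraction pattern).  See
#' `system.file("extdata", "default_config.yaml", package = "rtici")` for a
#' complete annotated example.
#'
#' @param path Path to a YAML configuration file.
#'
#' @return A list with components `parameters` ([model_parameters()]),
#'   `ici` ([ici_pharmacodynamics()] or `NULL`), `rt` (fraction table or
#'   `NULL`), `cohort` ([population_config()]), and `horizon` (days).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  # tolerate YAML-1.1 scalars like "1e9" that parse as strings
  numify <- function(x) {
    lapply(x, function(v) {
      if (is.character(v) && !is.na(suppressWarnings(as.numeric(v))))
        as.numeric(v) else v
    })
  }
  for (sect in c("parameters", "ici", "rt", "cohort"))
    if (is.list(cfg[[sect]])) cfg[[sect]] <- numify(cfg[[sect]])
  horizon <- if (!is.null(cfg$horizon)) cfg$horizon else 365
  parameters <- do.call(model_parameters, as.list(cfg$parameters))
  ici <- if (isFALSE(cfg$ici)) NULL else do.call(ici_pharmacodynamics,
                                                 as.list(cfg$ici))
  rt <- if (isFALSE(cfg$rt)) NULL else do.call(rt_fractions, as.list(cfg$rt))
  cohort <- do.call(population_config, as.list(cfg$cohort))
  list(parameters = parameters, ici = ici, rt = rt, cohort = cohort,
       horizon = horizon)
}
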