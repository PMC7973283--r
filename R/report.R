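#' Write a machine-readable pipeline report
#'
#' Serializes a fitted [ba_panel()] to JSON: every threshold used, the full
#' step log with per-step rejections and their numeric evidence, the final
#' panel (members, weights, rounded coefficients, divisor convention), the
#' rendered formula and the cohort statistics. A human-readable formula file
#' is written alongside. A run in which every biomarker was rejected is
#' written with an explicit `"no_panel"` status.
#'
#' @param fit a fitted `ba_panel`.
#' @param path output JSON path.
#' @param formula_path path for the plain-text formula rendering; defaults to
#'   `path` with a `.txt` extension.
#' @return Invisibly, `path`.
#' @export
write_report <- function(fit, path, formula_path = NULL) {
  stopifnot(inherits(fit, "ba_panel"))
  formula_path <- formula_path %||% paste0(sub("\\.json$", "", path), ".txt")
  cfg <- fit$config
  report <- list(
    status = fit$status,
    accepted = fit$accepted,
    config = list(
      ca_correlation_threshold = cfg$ca_correlation_threshold,
      cross_correlation_threshold = cfg$cross_correlation_threshold,
      max_accuracy_years = cfg$max_accuracy_years,
      task = cfg$task,
      sigma_k = cfg$sigma_policy$k,
      n_trim_ba = cfg$sigma_policy$n_trim_ba,
      coefficient_decimals = cfg$coefficient_decimals,
      ba_ca_sigma_limit = cfg$ba_ca_sigma_limit,
      ba_ca_r_limits = cfg$ba_ca_r_limits,
      divisor_convention = cfg$divisor_convention,
      min_availability = cfg$min_availability,
      mode = cfg$mode, seed = cfg$seed
    ),
    n_input_biomarkers = fit$n_input,
    step_log = fit$step_log,
    rejections = fit$rejections
  )
  if (!is.null(fit$panel)) {
    report$panel <- list(
      members = fit$panel$members,
      weights = as.list(fit$panel$weights),
      divisor_convention = fit$panel$divisor_convention,
      inverses = lapply(fit$panel$inverses, function(m) {
        list(family = m$family, rounded = as.list(m$rounded),
             inverse = if (!is.null(m$inverse)) as.list(m$inverse),
             ca_range = m$ca_range, r2 = m$r2)
      })
    )
    report$formula <- fit$formula
    report$cohort_stats <- fit$stats[c("mean", "sigma", "r_ba_ca", "n",
                                       "n_trimmed", "accepted")]
  } else {
    report$panel <- NULL
    report$formula <- "no panel: every biomarker was rejected"
  }
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE,
                           dataframe = "rows")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(json, con)
  writeLines(report$formula, formula_path)
  invisible(path)
}

#' Read back a pipeline report
#'
#' @param path JSON path written by [write_report()].
#' @return The report as a list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
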