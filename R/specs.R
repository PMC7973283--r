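#' Biomarker metadata
#'
#' Per-biomarker measurement metadata used by the accuracy screen: the
#' instrument accuracy of the measurement procedure (in the biomarker's own
#' units) and, optionally, the biomarker's typical change over a reference
#' age interval. When the reference change is not supplied it can be
#' estimated empirically from a fitted age regression
#' (see [empirical_change()]).
#'
#' @param name biomarker name (must match a cohort column).
#' @param units unit label; treated as opaque.
#' @param instrument_accuracy measurement accuracy in the biomarker's units
#'   (> 0), or `NA` when unknown.
#' @param reference_change biomarker change over `reference_interval`, in the
#'   biomarker's units (> 0), or `NA`.
#' @param reference_interval length of the reference age interval in years
#'   (> 0); required when `reference_change` is given.
#' @return A one-row data frame of class `biomarker_spec`.
#' @export
biomarker_spec <- function(name, units = "", instrument_accuracy = NA_real_,
                           reference_change = NA_real_,
                           reference_interval = NA_real_) {
  if (!is.na(instrument_accuracy) && instrument_accuracy <= 0) {
    stop("instrument_accuracy must be > 0")
  }
  if (!is.na(reference_change)) {
    if (is.na(reference_interval)) {
      stop("reference_interval must accompany reference_change")
    }
    if (reference_change <= 0 || reference_interval <= 0) {
      stop("reference_change and reference_interval must be > 0")
    }
  }
  structure(
    data.frame(name = name, units = units,
               instrument_accuracy = as.numeric(instrument_accuracy),
               reference_change = as.numeric(reference_change),
               reference_interval = as.numeric(reference_interval),
               stringsAsFactors = FALSE),
    class = c("biomarker_spec", "data.frame")
  )
}

#' Read biomarker metadata from CSV
#'
#' Expects columns `name`, and optionally `units`, `instrument_accuracy`,
#' `reference_change`, `reference_interval`.
#'
#' @param path CSV path.
#' @return A `biomarker_spec` data frame, one row per biomarker.
#' @export
read_biomarker_specs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("name" %in% names(df))) stop("metadata table needs a 'name' column")
  rows <- lapply(seq_len(nrow(df)), function(i) {
    biomarker_spec(
      name = df$name[i],
      units = if ("units" %in% names(df)) df$units[i] else "",
      instrument_accuracy = if ("instrument_accuracy" %in% names(df))
        df$instrument_accuracy[i] else NA_real_,
      reference_change = if ("reference_change" %in% names(df))
        df$reference_change[i] else NA_real_,
      reference_interval = if ("reference_interval" %in% names(df))
        df$reference_interval[i] else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("biomarker_spec", "data.frame")
  out
}
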