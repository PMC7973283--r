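#' Achievable accuracy of a biomarker in years
#'
#' Converts instrument accuracy into the granularity with which a biomarker
#' can date a subject: the number of instrumentally resolvable units across a
#' reference age interval is `change / instrument_accuracy`, and the
#' achievable accuracy of the corresponding partial biological age is
#' `interval / units_resolved` years. For display the accuracy is truncated
#' (not rounded) to one decimal place; screening always uses full precision.
#'
#' For example, a biomarker changing by 40 units over a 50-year interval,
#' measured with an instrument accuracy of 5 units, resolves 8 units and
#' dates a subject to 50/8 = 6.25 years, displayed as 6.2.
#'
#' @param change biomarker change over the reference interval, in the
#'   biomarker's units (> 0).
#' @param interval length of the reference age interval in years (> 0).
#' @param instrument_accuracy measurement accuracy in the biomarker's units
#'   (> 0).
#' @return List with `units_resolved`, `accuracy_years` (full precision) and
#'   `display` (truncated to one decimal).
#' @export
accuracy_in_years <- function(change, interval, instrument_accuracy) {
  if (any(!is.finite(c(change, interval, instrument_accuracy))) ||
      change <= 0 || interval <= 0 || instrument_accuracy <= 0) {
    stop("change, interval and instrument_accuracy must all be positive")
  }
  units_resolved <- change / instrument_accuracy
  accuracy_years <- interval / units_resolved
  list(units_resolved = units_resolved,
       accuracy_years = accuracy_years,
       display = trunc1(accuracy_years))
}

#' Empirical biomarker change over an age window
#'
#' When metadata gives no reference change, the change is estimated from a
#' fitted age regression as the absolute difference between the predicted
#' biomarker value at the window end and at the window start. The window
#' defaults to the CA range observed in the fit.
#'
#' @param model an [fit_age_regression()] object.
#' @param window optional numeric length-2 age window (years); defaults to
#'   the model's observed CA range.
#' @return List with `change` (biomarker units) and `interval` (years).
#' @export
empirical_change <- function(model, window = NULL) {
  if (!inherits(model, "age_regression")) {
    stop("no regression available: supply reference_change metadata or a fitted model")
  }
  window <- window %||% model$ca_range
  stopifnot(length(window) == 2, window[2] > window[1])
  pred <- predict(model, ca = window)
  list(change = abs(pred[2] - pred[1]), interval = diff(window))
}

#' Accuracy report for a set of biomarkers
#'
#' Resolves each biomarker's accuracy-in-years from metadata
#' (`reference_change` / `reference_interval` / `instrument_accuracy`) when
#' complete, else empirically from a fitted regression combined with the
#' metadata instrument accuracy. Biomarkers without instrument accuracy, or
#' with zero empirical change, get an undefined accuracy and are flagged.
#'
#' @param members character vector of biomarker names.
#' @param specs optional [biomarker_spec()] table.
#' @param models optional named list of [fit_age_regression()] objects used
#'   for empirical change estimation.
#' @param window optional age window passed to [empirical_change()].
#' @return Object of class `accuracy_report`: a data frame with columns
#'   `biomarker`, `change`, `interval`, `instrument_accuracy`,
#'   `units_resolved`, `accuracy_years`, `display`, `source`.
#' @export
accuracy_report <- function(members, specs = NULL, models = NULL,
                            window = NULL) {
  rows <- lapply(members, function(bm) {
    row <- data.frame(biomarker = bm, change = NA_real_, interval = NA_real_,
                      instrument_accuracy = NA_real_,
                      units_resolved = NA_real_, accuracy_years = NA_real_,
                      display = NA_real_, source = NA_character_,
                      stringsAsFactors = FALSE)
    sp <- if (!is.null(specs) && bm %in% specs$name) {
      specs[match(bm, specs$name), ]
    } else NULL
    ia <- if (!is.null(sp)) sp$instrument_accuracy else NA_real_
    if (!is.na(ia)) {
      if (!is.null(sp) && !is.na(sp$reference_change) &&
          !is.na(sp$reference_interval)) {
        row$change <- sp$reference_change
        row$interval <- sp$reference_interval
        row$source <- "metadata"
      } else if (!is.null(models) && bm %in% names(models) &&
                 inherits(models[[bm]], "age_regression")) {
        ch <- empirical_change(models[[bm]], window)
        row$change <- ch$change
        row$interval <- ch$interval
        row$source <- "empirical"
      }
      row$instrument_accuracy <- ia
      if (!is.na(row$change) && row$change > 0) {
        acc <- accuracy_in_years(row$change, row$interval, ia)
        row$units_resolved <- acc$units_resolved
        row$accuracy_years <- acc$accuracy_years
        row$display <- acc$display
      } else if (!is.na(row$change)) {
        bp_log("accuracy: %s has zero change over the window; accuracy undefined", bm)
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Screen biomarkers by achievable accuracy
#'
#' Rejects biomarkers whose accuracy-in-years exceeds `max_years` (strict
#' inequality: a biomarker exactly at the limit is retained). Undefined
#' accuracies pass with a warning since metadata is optional.
#'
#' @param report an [accuracy_report()].
#' @param max_years largest acceptable accuracy in years (> 0). Defaults are
#'   task-dependent: 10 for cross-sectional studies, 5 for longitudinal
#'   follow-up of individuals.
#' @return List with `retained` and `rejected` (data frame of biomarker and
#'   accuracy_years).
#' @export
screen_by_accuracy <- function(report, max_years = 10) {
  stopifnot(max_years > 0)
  acc <- report$accuracy_years
  reject <- !is.na(acc) & acc > max_years
  undef <- is.na(acc)
  if (any(undef)) {
    bp_log("accuracy screen: %d biomarker(s) without defined accuracy pass unchecked (%s)",
           sum(undef), paste(report$biomarker[undef], collapse = ", "))
  }
  for (i in which(reject)) {
    bp_log("accuracy screen: rejected %s (accuracy %.2f y > %.2f y)",
           report$biomarker[i], acc[i], max_years)
  }
  list(retained = report$biomarker[!reject],
       rejected = data.frame(biomarker = report$biomarker[reject],
                             accuracy_years = acc[reject],
                             stringsAsFactors = FALSE))
}

#' Export an accuracy report as CSV
#' @param report an [accuracy_report()].
#' @param path output CSV path.
#' @param max_years the screening limit used to annotate the decision column.
#' @return Invisibly, `path`.
#' @export
write_accuracy_report <- function(report, path, max_years = 10) {
  df <- as.data.frame(report)
  df$decision <- ifelse(is.na(df$accuracy_years), "unchecked",
                        ifelse(df$accuracy_years > max_years,
                               "rejected", "retained"))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
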