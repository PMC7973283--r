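#' Pipeline configuration
#'
#' Mirrors the dialog parameters of the interactive panel constructor: all
#' thresholds may be fixed up front (automatic mode) or entered step by step
#' (interactive mode).
#'
#' @param ca_correlation_threshold biomarkers with `|r| < threshold` against
#'   CA are rejected at step 1 (`[0, 1]`).
#' @param cross_correlation_threshold pairs with `|r| >=` this value are
#'   pruned for redundancy at step 2 (`(0, 1]`).
#' @param max_accuracy_years accuracy screen limit at step 3 (years). When
#'   `NULL`, defaults by task: 10 for `cross_sectional`, 5 for
#'   `longitudinal`.
#' @param task `"cross_sectional"` (population studies; interindividual
#'   dispersion matters) or `"longitudinal"` (follow-up of individuals;
#'   stricter default accuracy limit).
#' @param sigma_policy an [outlier_policy()]: per-decade sigma rule and BA
#'   trim count.
#' @param coefficient_decimals decimal places of the published regression
#'   coefficients.
#' @param ba_ca_sigma_limit largest acceptable sigma of BA - CA (years);
#'   panels exceeding it are flagged rejected at step 5.
#' @param ba_ca_r_limits length-2 acceptable range for the BA/CA correlation.
#' @param improvement_threshold r2 gain a non-linear family must offer to
#'   displace the linear fit.
#' @param divisor_convention `"count"` or `"weight_sum"`; see [panel_model()].
#' @param min_availability minimum fraction of panel members a subject must
#'   have measured for a defined BA.
#' @param weights optional named numeric vector of user weight factors in
#'   `(0, 1]`, overriding the default `|r|`-derived weights.
#' @param user_criterion optional [user_criterion()] applied at step 6.
#' @param mode `"automatic"` or `"interactive"`.
#' @param group_stratify fit each stratum of the group column separately.
#' @param seed integer recorded for provenance and used by any randomized
#'   step.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(ca_correlation_threshold = 0.3,
                            cross_correlation_threshold = 0.7,
                            max_accuracy_years = NULL,
                            task = c("cross_sectional", "longitudinal"),
                            sigma_policy = outlier_policy(),
                            coefficient_decimals = 4L,
                            ba_ca_sigma_limit = 10,
                            ba_ca_r_limits = c(0.5, 1),
                            improvement_threshold = 0.02,
                            divisor_convention = c("count", "weight_sum"),
                            min_availability = 0.5,
                            weights = NULL,
                            user_criterion = NULL,
                            mode = c("automatic", "interactive"),
                            group_stratify = FALSE,
                            seed = 1L) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  divisor_convention <- match.arg(divisor_convention)
  if (is.null(max_accuracy_years)) {
    max_accuracy_years <- if (task == "longitudinal") 5 else 10
  }
  stopifnot(ca_correlation_threshold >= 0, ca_correlation_threshold <= 1,
            cross_correlation_threshold > 0, cross_correlation_threshold <= 1,
            max_accuracy_years > 0, coefficient_decimals >= 0,
            ba_ca_sigma_limit > 0, length(ba_ca_r_limits) == 2,
            ba_ca_r_limits[1] <= ba_ca_r_limits[2],
            min_availability >= 0, min_availability <= 1)
  structure(
    list(ca_correlation_threshold = ca_correlation_threshold,
         cross_correlation_threshold = cross_correlation_threshold,
         max_accuracy_years = max_accuracy_years, task = task,
         sigma_policy = sigma_policy,
         coefficient_decimals = as.integer(coefficient_decimals),
         ba_ca_sigma_limit = ba_ca_sigma_limit,
         ba_ca_r_limits = ba_ca_r_limits,
         improvement_threshold = improvement_threshold,
         divisor_convention = divisor_convention,
         min_availability = min_availability, weights = weights,
         user_criterion = user_criterion, mode = mode,
         group_stratify = group_stratify, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Additional researcher criterion for step 6
#'
#' Wraps a predicate over (biomarker, evidence) applied to the biomarkers
#' retained after the statistical screens, with an optional per-biomarker
#' threshold table. The evidence passed to the predicate is a list with the
#' biomarker's `r` with CA, its `accuracy_years`, its observed
#' interindividual `range` (max - min), and its fitted `model`.
#'
#' @param name short label recorded in the step log.
#' @param predicate `function(biomarker, evidence, threshold)` returning
#'   `TRUE` to keep the biomarker. `threshold` is the entry of `thresholds`
#'   for that biomarker, or `NA` when absent.
#' @param thresholds optional named numeric vector.
#' @return Object of class `user_criterion`.
#' @export
user_criterion <- function(name, predicate, thresholds = NULL) {
  stopifnot(is.function(predicate))
  structure(list(name = name, predicate = predicate, thresholds = thresholds),
            class = "user_criterion")
}

#' Interindividual-range criterion
#'
#' The classic example of a step-6 researcher criterion: a biomarker whose
#' observed interindividual range exceeds its limit is unusable for
#' individual cross-sectional assessment (body weight, spanning 45-135 kg in
#' a typical adult cohort, is the canonical exclusion) even when it passes
#' the statistical screens. Biomarkers without a limit always pass.
#'
#' @param limits named numeric vector: largest acceptable observed range
#'   (max - min) per biomarker, in the biomarker's units.
#' @return A [user_criterion()].
#' @export
criterion_max_range <- function(limits) {
  user_criterion(
    name = "interindividual range limit",
    predicate = function(biomarker, evidence, threshold) {
      is.na(threshold) || evidence$range <= threshold
    },
    thresholds = limits
  )
}

#' Apply a researcher criterion to the retained biomarker set
#'
#' @param retained character vector of biomarker names.
#' @param criterion a [user_criterion()].
#' @param evidence named list of per-biomarker evidence lists (see
#'   [user_criterion()]).
#' @return List with `retained` and `rejected` (data frame of biomarker,
#'   criterion, threshold).
#' @export
apply_user_criterion <- function(retained, criterion, evidence) {
  stopifnot(inherits(criterion, "user_criterion"))
  keep <- vapply(retained, function(bm) {
    thr <- if (!is.null(criterion$thresholds) &&
               bm %in% names(criterion$thresholds)) {
      criterion$thresholds[[bm]]
    } else NA_real_
    isTRUE(criterion$predicate(bm, evidence[[bm]], thr))
  }, logical(1))
  rejected <- data.frame(
    biomarker = retained[!keep],
    criterion = rep(criterion$name, sum(!keep)),
    threshold = vapply(retained[!keep], function(bm) {
      if (!is.null(criterion$thresholds) &&
          bm %in% names(criterion$thresholds)) {
        criterion$thresholds[[bm]]
      } else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  for (bm in rejected$biomarker) {
    bp_log("user criterion '%s': rejected %s", criterion$name, bm)
  }
  list(retained = retained[keep], rejected = rejected)
}

# ---------------------------------------------------------------------------
# interactive mode: a terminal prompt sequence exposing the dialog parameters;
# every session resolves to a replayable automatic config

prompt_config <- function(config, answers = NULL) {
  i <- 0L
  ask <- function(label, default) {
    i <<- i + 1L
    ans <- if (!is.null(answers)) {
      if (i <= length(answers)) answers[[i]] else ""
    } else {
      cat(sprintf("%s [%s]: ", label, format(default)))
      readLines(con = "stdin", n = 1L)
    }
    if (is.null(ans) || !nzchar(trimws(as.character(ans)))) {
      default
    } else {
      as.numeric(ans)
    }
  }
  config$ca_correlation_threshold <-
    ask("rejection threshold for low CA correlation", config$ca_correlation_threshold)
  config$cross_correlation_threshold <-
    ask("cross-correlation threshold", config$cross_correlation_threshold)
  config$max_accuracy_years <-
    ask("max accuracy in years", config$max_accuracy_years)
  config$sigma_policy$k <-
    ask("sigmas per 10-year age period", config$sigma_policy$k)
  config$sigma_policy$n_trim_ba <-
    as.integer(ask("number of max/min BA values to reject", config$sigma_policy$n_trim_ba))
  config$coefficient_decimals <-
    as.integer(ask("coefficient decimal places", config$coefficient_decimals))
  config$ba_ca_sigma_limit <-
    ask("sigma limit for BA-CA", config$ba_ca_sigma_limit)
  config$ba_ca_r_limits[1] <-
    ask("minimum BA/CA correlation", config$ba_ca_r_limits[1])
  config$ba_ca_r_limits[2] <-
    ask("maximum BA/CA correlation", config$ba_ca_r_limits[2])
  config$mode <- "interactive"
  config
}

# ---------------------------------------------------------------------------

#' Fit an optimized biological-age panel
#'
#' Runs the seven-step panel optimization on a cohort table:
#' \enumerate{
#'   \item correlation screen: biomarkers with `|r|` against CA below the
#'     rejection threshold (or undefined) are removed;
#'   \item redundancy pruning: of each biomarker pair cross-correlated above
#'     the threshold, the member with worse accuracy (or weaker age
#'     correlation) is dropped;
#'   \item accuracy screen: biomarkers whose achievable accuracy in years
#'     exceeds the limit are removed (biomarkers without metadata pass with a
#'     warning);
#'   \item regression: per-decade sigma-rule outlier masking, then linear /
#'     exponential / quadratic fits with coefficient rounding and family
#'     selection; biomarkers without an invertible (strictly monotone) fit
#'     are removed;
#'   \item biological age: partial biological ages from the inverse formulas,
#'     weighted aggregation, trimming of extreme BA values, and the
#'     sigma / correlation quality gate;
#'   \item researcher criterion: an optional predicate over the retained
#'     biomarkers (e.g. an interindividual-range limit);
#'   \item panel assembly: final weights, formula rendering and cohort
#'     statistics.
#' }
#' Every removal is logged in the step log with its numeric evidence, so each
#' input biomarker is either in the final panel or attributed to a rejection
#' step.
#'
#' @param data a [cohort_table()], a data frame, or a path to a cohort CSV.
#' @param ca_column name of the chronological-age column (for data frame /
#'   CSV input).
#' @param group_column optional stratum column (for data frame / CSV input).
#' @param specs optional [biomarker_spec()] metadata table.
#' @param config a [pipeline_config()].
#' @param answers optional character vector of scripted interactive answers
#'   (one per prompt, `""` keeps the default); only used in interactive mode.
#' @return Object of class `ba_panel` with elements `panel`
#'   ([panel_model()] or `NULL` when every biomarker was rejected), `result`
#'   ([compute_ba()] result), `stats` (cohort statistics), `step_log`,
#'   `rejections`, `correlations`, `accuracy`, `models`, `table` (the masked
#'   cohort), `config`, `accepted`, `status`, `formula`.
#'   With `group_stratify = TRUE` and a group column present, a
#'   `ba_panel_strata` list of per-stratum fits is returned instead.
#' @examples
#' cohort <- generate_cohort(soviet_panel_preset(seed = 1))
#' fit <- ba_panel(cohort$table,
#'                 config = pipeline_config(
#'                   user_criterion = criterion_max_range(c(BW = 80))))
#' print(fit)
#' summary(fit)
#' @export
ba_panel <- function(data, ca_column = "CA", group_column = NULL,
                     specs = NULL, config = pipeline_config(),
                     answers = NULL) {
  table <- if (inherits(data, "cohort_table")) {
    data
  } else if (is.character(data)) {
    read_cohort(data, ca_column = ca_column, group_column = group_column)
  } else {
    as_cohort_table(data, ca_column = ca_column, group_column = group_column)
  }
  if (config$mode == "interactive") {
    config <- prompt_config(config, answers)
  }
  if (isTRUE(config$group_stratify) && !is.null(table$group)) {
    fits <- lapply(split(seq_along(table$ca), table$group), function(idx) {
      ba_panel_run(subset_subjects(table, idx), specs, config)
    })
    return(structure(fits, class = "ba_panel_strata"))
  }
  ba_panel_run(table, specs, config)
}

# core single-stratum run
ba_panel_run <- function(table, specs, config) {
  cl <- match.call()
  log <- data.frame(step = integer(0), action = character(0),
                    target = character(0), value = numeric(0),
                    threshold = numeric(0), note = character(0),
                    stringsAsFactors = FALSE)
  add <- function(step, action, target, value = NA_real_,
                  threshold = NA_real_, note = "") {
    log <<- rbind(log, data.frame(step = step, action = action,
                                  target = target, value = value,
                                  threshold = threshold, note = note,
                                  stringsAsFactors = FALSE))
  }
  all_bms <- biomarkers(table)
  empty_result <- function(status) {
    bp_log("pipeline halted: %s", status)
    structure(
      list(panel = NULL, result = NULL, stats = NULL, step_log = log,
           rejections = log[log$action == "reject", ],
           correlations = corr, accuracy = NULL, models = list(),
           table = table, config = config, accepted = FALSE,
           status = status, formula = NULL, n_input = length(all_bms),
           call = cl),
      class = "ba_panel")
  }

  # step 1: CA-correlation screen
  corr <- correlation_report(table)
  s1 <- reject_low_correlation(corr, config$ca_correlation_threshold)
  for (i in seq_len(nrow(s1$rejected))) {
    add(1L, "reject", s1$rejected$biomarker[i], s1$rejected$r[i],
        config$ca_correlation_threshold, "low correlation with CA")
  }
  retained <- s1$retained
  if (!length(retained)) return(empty_result("no_panel"))

  # provisional linear fits feed the accuracy model (tie-breaks at step 2,
  # screen at step 3) before the definitive step-4 fits
  prov <- lapply(stats::setNames(retained, retained), function(bm) {
    tryCatch(fit_age_regression(table, bm, "linear",
                                config$coefficient_decimals),
             error = function(e) NULL)
  })
  acc <- accuracy_report(retained, specs = specs, models = prov)
  acc_map <- stats::setNames(acc$accuracy_years, acc$biomarker)

  # step 2: redundancy pruning
  s2 <- prune_redundant(corr, retained, config$cross_correlation_threshold,
                        accuracy = acc_map)
  for (i in seq_len(nrow(s2$rejected))) {
    add(2L, "reject", s2$rejected$dropped[i], s2$rejected$r[i],
        config$cross_correlation_threshold,
        sprintf("redundant with %s", s2$rejected$kept[i]))
  }
  retained <- s2$retained
  if (!length(retained)) return(empty_result("no_panel"))

  # step 3: accuracy screen
  s3 <- screen_by_accuracy(acc[acc$biomarker %in% retained, ],
                           config$max_accuracy_years)
  for (i in seq_len(nrow(s3$rejected))) {
    add(3L, "reject", s3$rejected$biomarker[i],
        s3$rejected$accuracy_years[i], config$max_accuracy_years,
        "accuracy in years above limit")
  }
  retained <- s3$retained
  if (!length(retained)) return(empty_result("no_panel"))

  # step 4: outlier masking, regression fits, invertibility
  masked <- reject_bm_outliers(table, config$sigma_policy, members = retained)
  n_masked <- nrow(attr(masked, "mask_report"))
  add(4L, "mask", "(cells)", n_masked, config$sigma_policy$k,
      "per-bin sigma rule")
  models <- list()
  for (bm in retained) {
    m <- tryCatch(fit_best_regression(masked, bm, config$coefficient_decimals,
                                      config$improvement_threshold),
                  error = function(e) NULL)
    if (is.null(m) || !isTRUE(m$monotone)) {
      add(4L, "reject", bm, NA_real_, NA_real_,
          "no invertible (monotone) regression")
    } else {
      models[[bm]] <- m
      add(4L, "fit", bm, m$r2, NA_real_, sprintf("family %s", m$family))
    }
  }
  retained <- names(models)
  if (!length(retained)) return(empty_result("no_panel"))

  weights_for <- function(members) {
    if (!is.null(config$weights)) {
      missing_w <- setdiff(members, names(config$weights))
      if (length(missing_w)) {
        stop("user weights missing for: ", paste(missing_w, collapse = ", "))
      }
      config$weights[members]
    } else {
      default_weights(corr, members)
    }
  }
  evaluate_panel <- function(members) {
    panel <- panel_model(members, models, weights_for(members),
                         config$divisor_convention)
    result <- compute_ba(masked, panel, config$min_availability)
    stats <- cohort_statistics(result, config$sigma_policy,
                               config$ba_ca_sigma_limit,
                               config$ba_ca_r_limits)
    list(panel = panel, result = result, stats = stats)
  }

  # step 5: biological age and the sigma / correlation quality gate
  ev5 <- evaluate_panel(retained)
  add(5L, "statistics", "(panel)", ev5$stats$sigma,
      config$ba_ca_sigma_limit,
      sprintf("mean %.3f, sigma %.3f, r %.3f, n %d -> %s",
              ev5$stats$mean, ev5$stats$sigma, ev5$stats$r_ba_ca,
              ev5$stats$n, if (ev5$stats$accepted) "pass" else "fail"))
  if (!ev5$stats$accepted) {
    bp_log("step 5: panel flagged rejected (sigma %.2f vs limit %.2f, r %.3f vs [%.2f, %.2f])",
           ev5$stats$sigma, config$ba_ca_sigma_limit, ev5$stats$r_ba_ca,
           config$ba_ca_r_limits[1], config$ba_ca_r_limits[2])
  }

  # step 6: researcher criterion
  if (!is.null(config$user_criterion)) {
    evidence <- lapply(stats::setNames(retained, retained), function(bm) {
      v <- masked$values[, bm]
      list(r = corr$r_with_ca[[bm]], accuracy_years = acc_map[[bm]],
           range = if (all(is.na(v))) NA_real_ else
             diff(range(v, na.rm = TRUE)),
           model = models[[bm]])
    })
    s6 <- apply_user_criterion(retained, config$user_criterion, evidence)
    for (i in seq_len(nrow(s6$rejected))) {
      add(6L, "reject", s6$rejected$biomarker[i],
          evidence[[s6$rejected$biomarker[i]]]$range,
          s6$rejected$threshold[i], s6$rejected$criterion[i])
    }
    retained <- s6$retained
    if (!length(retained)) return(empty_result("no_panel"))
  }

  # step 7: final assembly (re-evaluated when step 6 changed the set)
  final <- if (identical(retained, ev5$panel$members)) ev5 else
    evaluate_panel(retained)
  formula_text <- render_formula(final$panel)
  add(7L, "assemble", "(panel)", length(retained), NA_real_, formula_text)

  structure(
    list(panel = final$panel, result = final$result, stats = final$stats,
         step_log = log, rejections = log[log$action == "reject", ],
         correlations = corr, accuracy = acc, models = models,
         table = masked, config = config,
         accepted = final$stats$accepted,
         status = if (final$stats$accepted) "accepted" else "rejected_step5",
         formula = formula_text, n_input = length(all_bms), call = cl),
    class = "ba_panel"
  )
}

# ---------------------------------------------------------------------------
# methods

#' @export
print.ba_panel <- function(x, ...) {
  cat("Optimized biological-age panel\n")
  if (is.null(x$panel)) {
    cat("  status: no panel (every biomarker rejected)\n")
    cat(sprintf("  rejections logged: %d\n", nrow(x$rejections)))
    return(invisible(x))
  }
  cat(sprintf("  members (%d of %d biomarkers): %s\n",
              length(x$panel$members), x$n_input,
              paste(x$panel$members, collapse = ", ")))
  cat("  ", x$formula, "\n", sep = "")
  cat(sprintf("  BA-CA: mean %.2f, sigma %.2f years; r(BA, CA) = %.3f (n = %d)\n",
              x$stats$mean, x$stats$sigma, x$stats$r_ba_ca, x$stats$n))
  cat(sprintf("  status: %s\n", x$status))
  invisible(x)
}

#' @export
summary.ba_panel <- function(object, ...) {
  structure(list(fit = object), class = "summary.ba_panel")
}

#' @export
print.summary.ba_panel <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$panel)) {
    cat("\nPer-member detail:\n")
    df <- data.frame(
      biomarker = fit$panel$members,
      weight = unname(fit$panel$weights),
      r_with_ca = unname(fit$correlations$r_with_ca[fit$panel$members]),
      family = vapply(fit$panel$inverses, `[[`, character(1), "family"),
      r2 = vapply(fit$panel$inverses, `[[`, numeric(1), "r2"),
      row.names = NULL)
    print(df, digits = 3)
  }
  cat("\nStep log:\n")
  print(fit$step_log, digits = 4)
  invisible(x)
}

#' @export
coef.ba_panel <- function(object, ...) {
  if (is.null(object$panel)) return(NULL)
  members <- object$panel$members
  out <- t(vapply(members, function(bm) {
    m <- object$panel$inverses[[bm]]
    if (m$family == "linear") {
      c(intercept = m$inverse[["a"]], slope = m$inverse[["b"]],
        weight = object$panel$weights[[bm]])
    } else {
      c(intercept = NA_real_, slope = NA_real_,
        weight = object$panel$weights[[bm]])
    }
  }, numeric(3)))
  rownames(out) <- members
  out
}

#' @export
residuals.ba_panel <- function(object, ...) {
  if (is.null(object$result)) return(NULL)
  stats::setNames(object$result$ba_minus_ca, object$result$subject_id)
}

#' @export
fitted.ba_panel <- function(object, ...) {
  if (is.null(object$result)) return(NULL)
  stats::setNames(object$result$ba, object$result$subject_id)
}

#' Predict biological age for new subjects
#'
#' Applies the fitted panel's inverse formulas and aggregation convention to
#' a new cohort table (which must contain the panel members and a CA column).
#'
#' @param object a fitted `ba_panel`.
#' @param newdata a [cohort_table()], data frame or CSV path.
#' @param ca_column CA column name for data frame / CSV input.
#' @param ... unused.
#' @return Data frame with `subject_id`, `CA`, `BA`, `BA_minus_CA`,
#'   `n_available`.
#' @export
predict.ba_panel <- function(object, newdata, ca_column = "CA", ...) {
  if (is.null(object$panel)) stop("no panel was accepted; nothing to predict")
  table <- if (inherits(newdata, "cohort_table")) newdata else
    if (is.character(newdata)) read_cohort(newdata, ca_column = ca_column) else
      as_cohort_table(newdata, ca_column = ca_column)
  res <- compute_ba(table, object$panel, object$config$min_availability)
  data.frame(subject_id = res$subject_id, CA = res$ca, BA = res$ba,
             BA_minus_CA = res$ba_minus_ca, n_available = res$n_available,
             stringsAsFactors = FALSE)
}

#' Plot biological age against chronological age
#'
#' The classic quality display: per-subject BA against CA with the identity
#' diagonal; a good panel scatters tightly around the diagonal.
#'
#' @param x a fitted `ba_panel`.
#' @param ... passed to [plot()].
#' @export
plot.ba_panel <- function(x, ...) {
  if (is.null(x$result)) stop("no panel was accepted; nothing to plot")
  ok <- !is.na(x$result$ba)
  plot(x$result$ca[ok], x$result$ba[ok],
       xlab = "Chronological age (years)", ylab = "Biological age (years)",
       main = sprintf("BA vs CA (sigma = %.2f y, r = %.3f)",
                      x$stats$sigma, x$stats$r_ba_ca), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
print.ba_panel_strata <- function(x, ...) {
  cat(sprintf("Stratified biological-age panels (%d strata)\n\n", length(x)))
  for (g in names(x)) {
    cat(sprintf("== stratum %s ==\n", g))
    print(x[[g]])
    cat("\n")
  }
  invisible(x)
}
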