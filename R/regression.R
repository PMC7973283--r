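#' Fit a biomarker-on-age regression
#'
#' Fits the biomarker as a function of chronological age by least squares in
#' one of three families:
#' \itemize{
#'   \item `linear`: `BM = a + b*CA`
#'   \item `exponential`: `BM = a*exp(b*CA)`, fitted by least squares on the
#'     log-transformed biomarker; requires all values of one sign
#'   \item `polynomial2`: `BM = a + b*CA + c*CA^2`
#' }
#' Coefficients are stored both raw and rounded to `decimals` places. For the
#' linear family the inverse-form coefficients `a' = -a/b`, `b' = 1/b`
#' (so that `BAp = a' + b'*BM`) are computed from the rounded fit and rounded
#' to the same precision; [invert_regression()] applies these published-style
#' rounded inverse formulas. The fitted curve is invertible only where it is
#' strictly monotone over the observed CA range.
#'
#' @param table a [cohort_table()].
#' @param biomarker name of the biomarker column to fit.
#' @param family one of `"linear"`, `"exponential"`, `"polynomial2"`.
#' @param decimals number of decimal places for the published coefficients.
#' @return Object of class `age_regression` with elements `family`,
#'   `coefficients` (raw), `rounded` , `inverse` (linear only), `r2`,
#'   `residual_se`, `ca_range`, `n`, `monotone`, `biomarker`, `decimals`.
#' @export
fit_age_regression <- function(table, biomarker,
                               family = c("linear", "exponential",
                                          "polynomial2"),
                               decimals = 4L) {
  family <- match.arg(family)
  stopifnot(inherits(table, "cohort_table"),
            biomarker %in% biomarkers(table))
  y <- table$values[, biomarker]
  ok <- !is.na(y) & !is.na(table$ca)
  y <- y[ok]; ca <- table$ca[ok]
  n_min <- if (family == "polynomial2") 4L else 3L
  if (length(y) < n_min) {
    stop(sprintf("%s: need >= %d complete (BM, CA) pairs for family '%s'",
                 biomarker, n_min, family))
  }
  if (stats::sd(ca) == 0) stop(biomarker, ": degenerate design (all CA equal)")

  if (family == "linear") {
    fit <- stats::lm(y ~ ca)
    coefs <- c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
    fitted <- stats::fitted(fit)
  } else if (family == "exponential") {
    s <- unique(sign(y[y != 0]))
    if (any(y == 0) || length(s) != 1) {
      stop(biomarker, ": exponential family unavailable (values not of one sign)")
    }
    fit <- stats::lm(log(s * y) ~ ca)
    coefs <- c(a = s * exp(unname(stats::coef(fit)[1])),
               b = unname(stats::coef(fit)[2]))
    fitted <- coefs["a"] * exp(coefs["b"] * ca)
  } else {
    ca2 <- ca^2
    fit <- stats::lm(y ~ ca + ca2)
    coefs <- c(a = unname(stats::coef(fit)[1]),
               b = unname(stats::coef(fit)[2]),
               c = unname(stats::coef(fit)[3]))
    fitted <- stats::fitted(fit)
  }
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - fitted)^2)
  r2 <- if (ss_tot == 0) NA_real_ else max(0, 1 - ss_res / ss_tot)
  p <- length(coefs)
  residual_se <- sqrt(ss_res / max(1, length(y) - p))
  rounded <- round(coefs, decimals)
  ca_range <- range(ca)

  model <- structure(
    list(family = family, coefficients = coefs, rounded = rounded,
         inverse = NULL, r2 = r2, residual_se = residual_se,
         ca_range = ca_range, n = length(y), biomarker = biomarker,
         decimals = as.integer(decimals)),
    class = "age_regression"
  )
  model$monotone <- is_monotone(model)
  if (family == "linear" && rounded[["b"]] != 0) {
    model$inverse <- c(a = round(-rounded[["a"]] / rounded[["b"]], decimals),
                       b = round(1 / rounded[["b"]], decimals))
  }
  model
}

# strict monotonicity of the rounded fit over the observed CA range
is_monotone <- function(model) {
  co <- model$rounded
  switch(model$family,
    linear = co[["b"]] != 0,
    exponential = co[["b"]] != 0 && co[["a"]] != 0,
    polynomial2 = {
      if (co[["c"]] == 0) {
        co[["b"]] != 0
      } else {
        vertex <- -co[["b"]] / (2 * co[["c"]])
        vertex <= model$ca_range[1] || vertex >= model$ca_range[2]
      }
    }
  )
}

#' Construct an inverse age formula from published coefficients
#'
#' Builds an invertible linear `age_regression` object directly from the
#' inverse-form coefficients of a published partial-biological-age formula,
#' `BAp = intercept + slope * BM`, so that published panels can be applied to
#' new cohorts without refitting.
#'
#' @param biomarker biomarker name.
#' @param intercept inverse-form intercept `a'` in years.
#' @param slope inverse-form slope `b'` in years per biomarker unit
#'   (non-zero).
#' @param ca_range age range (years) over which the formula is considered
#'   calibrated; values inverted outside it are flagged as extrapolations.
#' @param decimals coefficient precision used when rendering.
#' @return An `age_regression` object usable in [panel_model()].
#' @export
manual_inverse <- function(biomarker, intercept, slope,
                           ca_range = c(20, 90), decimals = 4L) {
  stopifnot(is.finite(intercept), is.finite(slope), slope != 0)
  a <- -intercept / slope
  b <- 1 / slope
  structure(
    list(family = "linear",
         coefficients = c(a = a, b = b),
         rounded = c(a = a, b = b),
         inverse = c(a = intercept, b = slope),
         r2 = NA_real_, residual_se = NA_real_,
         ca_range = ca_range, n = NA_integer_, biomarker = biomarker,
         decimals = as.integer(decimals), monotone = TRUE),
    class = "age_regression"
  )
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf("Age regression for %s (%s)\n", x$biomarker, x$family))
  cat("  ", format_forward(x), "\n", sep = "")
  if (!is.na(x$r2)) {
    cat(sprintf("  r2 = %.4f, residual SE = %.4g, n = %d, CA %g-%g\n",
                x$r2, x$residual_se, x$n, x$ca_range[1], x$ca_range[2]))
  }
  if (x$monotone) {
    cat("  inverse: ", format_inverse(x), "\n", sep = "")
  } else {
    cat("  not monotone on the observed CA range; inversion refused\n")
  }
  invisible(x)
}

format_forward <- function(model) {
  co <- model$rounded
  d <- model$decimals
  nm <- model$biomarker
  switch(model$family,
    linear = sprintf("%s = %s %s %s * CA", nm, fmt_coef(co[["a"]], d),
                     if (co[["b"]] < 0) "-" else "+",
                     fmt_coef(abs(co[["b"]]), d)),
    exponential = sprintf("%s = %s * exp(%s * CA)", nm,
                          fmt_coef(co[["a"]], d), fmt_coef(co[["b"]], d)),
    polynomial2 = sprintf("%s = %s %s %s * CA %s %s * CA^2", nm,
                          fmt_coef(co[["a"]], d),
                          if (co[["b"]] < 0) "-" else "+",
                          fmt_coef(abs(co[["b"]]), d),
                          if (co[["c"]] < 0) "-" else "+",
                          fmt_coef(abs(co[["c"]]), d))
  )
}

# textual inverse formula in the published style "BAp = a' + b' * NAME"
format_inverse <- function(model) {
  d <- model$decimals
  nm <- model$biomarker
  if (model$family == "linear") {
    inv <- model$inverse
    sprintf("BAp = %s %s %s * %s", fmt_coef(inv[["a"]], d),
            if (inv[["b"]] < 0) "-" else "+", fmt_coef(abs(inv[["b"]]), d), nm)
  } else if (model$family == "exponential") {
    co <- model$rounded
    sprintf("BAp = ln(%s / %s) / %s", nm, fmt_coef(co[["a"]], d),
            fmt_coef(co[["b"]], d))
  } else {
    co <- model$rounded
    sprintf("BAp = root of %s * x^2 %s %s * x + (%s - %s) in the CA range",
            fmt_coef(co[["c"]], d), if (co[["b"]] < 0) "-" else "+",
            fmt_coef(abs(co[["b"]]), d), fmt_coef(co[["a"]], d), nm)
  }
}

#' Predict biomarker values from a fitted age regression
#' @param object an `age_regression`.
#' @param ca numeric vector of chronological ages (years).
#' @param rounded use the rounded (published) coefficients instead of the raw
#'   fit.
#' @param ... unused.
#' @return Numeric vector of predicted biomarker values.
#' @export
predict.age_regression <- function(object, ca, rounded = FALSE, ...) {
  co <- if (rounded) object$rounded else object$coefficients
  switch(object$family,
    linear = co[["a"]] + co[["b"]] * ca,
    exponential = co[["a"]] * exp(co[["b"]] * ca),
    polynomial2 = co[["a"]] + co[["b"]] * ca + co[["c"]] * ca^2
  )
}

#' Select a regression family
#'
#' The linear family is retained unless a competing family improves r2 by
#' more than `improvement_threshold`. With no linear candidate the best r2
#' wins. Non-invertible candidates are never selected when an invertible one
#' exists.
#'
#' @param models list of `age_regression` candidates (NULL entries allowed
#'   for unavailable families).
#' @param improvement_threshold minimum r2 gain over linear required to
#'   displace it.
#' @return The selected `age_regression`, with attribute `"selection"`
#'   recording the candidate r2 values.
#' @export
select_family <- function(models, improvement_threshold = 0.02) {
  models <- Filter(function(m) inherits(m, "age_regression"), models)
  if (!length(models)) stop("no fitted candidates")
  mono <- vapply(models, `[[`, logical(1), "monotone")
  if (any(mono)) models <- models[mono]
  fams <- vapply(models, `[[`, character(1), "family")
  r2 <- vapply(models, `[[`, numeric(1), "r2")
  pick <- if ("linear" %in% fams) {
    base <- r2[match("linear", fams)]
    better <- which(r2 > base + improvement_threshold)
    if (length(better)) better[which.max(r2[better])] else match("linear", fams)
  } else {
    which.max(r2)
  }
  sel <- models[[pick]]
  attr(sel, "selection") <- stats::setNames(r2, fams)
  bp_log("family selection for %s: chose %s (r2 = %.4f; candidates: %s)",
         sel$biomarker, sel$family, sel$r2,
         paste(sprintf("%s=%.4f", fams, r2), collapse = ", "))
  sel
}

#' Invert an age regression: biomarker value to partial biological age
#'
#' Applies the rounded (published-style) inverse formula:
#' \itemize{
#'   \item linear: `BAp = a' + b'*BM` with the rounded inverse-form
#'     coefficients
#'   \item exponential: `BAp = ln(BM/a)/b`
#'   \item polynomial2: the root of the quadratic lying in (or nearest to)
#'     the observed CA range
#' }
#' The result is not clamped to the calibrated CA range; values falling
#' outside it are flagged in the `"extrapolated"` attribute.
#'
#' @param model a monotone `age_regression`.
#' @param bm_value numeric vector of biomarker values.
#' @return Numeric vector of partial biological ages (years), with a logical
#'   attribute `"extrapolated"`. Values that cannot be inverted (e.g.
#'   `BM/a <= 0` for the exponential family) are `NA`.
#' @export
invert_regression <- function(model, bm_value) {
  stopifnot(inherits(model, "age_regression"))
  if (!model$monotone) {
    stop(model$biomarker,
         ": fitted curve is not monotone on the CA range; inversion refused")
  }
  co <- model$rounded
  bap <- switch(model$family,
    linear = {
      if (co[["b"]] == 0) stop(model$biomarker, ": zero slope; inversion refused")
      model$inverse[["a"]] + model$inverse[["b"]] * bm_value
    },
    exponential = {
      ratio <- bm_value / co[["a"]]
      out <- rep(NA_real_, length(bm_value))
      pos <- !is.na(ratio) & ratio > 0
      if (any(!pos & !is.na(ratio))) {
        bp_log("%s: %d value(s) outside the exponential range (BM/a <= 0) set to NA",
               model$biomarker, sum(!pos & !is.na(ratio)))
      }
      out[pos] <- log(ratio[pos]) / co[["b"]]
      out
    },
    polynomial2 = invert_quadratic(co, bm_value, model$ca_range)
  )
  attr(bap, "extrapolated") <- !is.na(bap) &
    (bap < model$ca_range[1] | bap > model$ca_range[2])
  bap
}

# root of c x^2 + b x + (a - v) lying in, or nearest to, the CA range
invert_quadratic <- function(co, v, ca_range) {
  a <- co[["a"]]; b <- co[["b"]]; cc <- co[["c"]]
  if (cc == 0) return((v - a) / b)
  vapply(v, function(vi) {
    if (is.na(vi)) return(NA_real_)
    disc <- b^2 - 4 * cc * (a - vi)
    if (disc < 0) return(NA_real_)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * cc)
    inside <- roots >= ca_range[1] & roots <= ca_range[2]
    if (any(inside)) return(roots[inside][1])
    mid <- mean(ca_range)
    roots[which.min(abs(roots - mid))]
  }, numeric(1))
}

#' Fit all candidate families and select one
#'
#' Convenience wrapper used by the pipeline: fits linear, exponential and
#' quadratic candidates (families that fail, e.g. the exponential on
#' sign-mixed data, are logged and skipped) and applies [select_family()].
#'
#' @inheritParams fit_age_regression
#' @inheritParams select_family
#' @return The selected `age_regression`.
#' @export
fit_best_regression <- function(table, biomarker, decimals = 4L,
                                improvement_threshold = 0.02) {
  cands <- lapply(c("linear", "exponential", "polynomial2"), function(fam) {
    tryCatch(fit_age_regression(table, biomarker, fam, decimals),
             error = function(e) {
               bp_log("fit %s/%s unavailable: %s", biomarker, fam,
                      conditionMessage(e))
               NULL
             })
  })
  select_family(cands, improvement_threshold)
}
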