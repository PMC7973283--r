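#' Biomarker panel model
#'
#' A panel couples a set of biomarkers with their weight factors
#' `w` in `(0, 1]` and their invertible age regressions. The biological age
#' of a subject is the weighted mean of the partial biological ages (BAp)
#' obtained by inverting each member's regression at the subject's measured
#' value.
#'
#' Two aggregation conventions are supported for the difference BA - CA over
#' the members available for a subject:
#' \itemize{
#'   \item `count` (default): `sum(w_i * (BAp_i - CA)) / n_available`, the
#'     convention of published panel formulas that divide by the member count
#'   \item `weight_sum`: divide by the sum of the available weights instead
#'     (the statistically conventional weighted mean)
#' }
#'
#' @param members ordered character vector of biomarker names (non-empty).
#' @param inverses named list of monotone [fit_age_regression()] /
#'   [manual_inverse()] objects, one per member.
#' @param weights named numeric vector of weights in `(0, 1]`; defaults to 1
#'   for every member.
#' @param divisor_convention `"count"` or `"weight_sum"`.
#' @return Object of class `panel_model`.
#' @export
panel_model <- function(members, inverses, weights = NULL,
                        divisor_convention = c("count", "weight_sum")) {
  divisor_convention <- match.arg(divisor_convention)
  if (!length(members)) stop("panel must contain at least one biomarker")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(members)), members)
  stopifnot(all(members %in% names(inverses)),
            all(members %in% names(weights)))
  weights <- weights[members]
  if (any(weights <= 0 | weights > 1)) stop("weights must lie in (0, 1]")
  for (bm in members) {
    m <- inverses[[bm]]
    if (!inherits(m, "age_regression") || !isTRUE(m$monotone)) {
      stop("member ", bm, " has no monotone inverse")
    }
  }
  structure(
    list(members = members, weights = weights, inverses = inverses[members],
         divisor_convention = divisor_convention),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("Biomarker panel (%d members, divisor = %s)\n",
              length(x$members), x$divisor_convention))
  cat(render_formula(x), "\n")
  invisible(x)
}

#' Default weight factors from age correlations
#'
#' `w_i = |r_i|` rounded to 2 decimals and floored at 0.01. User-supplied
#' weights override these.
#'
#' @param report a [correlation_report()].
#' @param members biomarker names; every member must have a defined
#'   correlation with CA.
#' @return Named numeric vector of weights.
#' @export
default_weights <- function(report, members) {
  r <- report$r_with_ca[members]
  if (anyNA(r)) {
    stop("undefined CA correlation for: ",
         paste(members[is.na(r)], collapse = ", "))
  }
  stats::setNames(pmax(round(abs(r), 2), 0.01), members)
}

#' Compute biological age for every subject
#'
#' Inverts each panel member's regression at the subject's biomarker value to
#' obtain the partial biological ages BAp, then aggregates
#' `BA - CA = sum(w_i * (BAp_i - CA)) / divisor` over the members available
#' for that subject. Subjects whose available-member fraction falls below
#' `min_availability` (or with no members at all) get an undefined BA and are
#' excluded from cohort statistics with a logged count.
#'
#' @param table a [cohort_table()] (typically after outlier masking).
#' @param panel a [panel_model()].
#' @param min_availability minimum fraction of panel members that must be
#'   non-missing for a subject's BA to be defined.
#' @return Object of class `ba_result`: list with `bap` (subjects x members
#'   matrix, years), `ba`, `ba_minus_ca`, `ca`, `subject_id`, `n_available`,
#'   `panel`.
#' @export
compute_ba <- function(table, panel, min_availability = 0.5) {
  stopifnot(inherits(table, "cohort_table"), inherits(panel, "panel_model"))
  missing_members <- setdiff(panel$members, biomarkers(table))
  if (length(missing_members)) {
    stop("cohort lacks panel member(s): ",
         paste(missing_members, collapse = ", "))
  }
  n <- nrow(table$values)
  m <- length(panel$members)
  bap <- matrix(NA_real_, n, m,
                dimnames = list(table$subject_id, panel$members))
  for (bm in panel$members) {
    v <- table$values[, bm]
    ok <- !is.na(v)
    if (any(ok)) {
      bap[ok, bm] <- invert_regression(panel$inverses[[bm]], v[ok])
    }
  }
  w <- panel$weights
  avail <- !is.na(bap)
  n_avail <- rowSums(avail)
  dev <- sweep(bap - table$ca, 2, w, `*`)
  num <- rowSums(dev, na.rm = TRUE)
  divisor <- if (panel$divisor_convention == "count") {
    n_avail
  } else {
    avail %*% w
  }
  ba_minus_ca <- ifelse(n_avail > 0, num / as.numeric(divisor), NA_real_)
  low <- n_avail / m < min_availability
  if (any(low & n_avail > 0)) {
    bp_log("compute_ba: %d subject(s) below the availability floor (%.0f%% of members); BA undefined",
           sum(low & n_avail > 0), 100 * min_availability)
  }
  ba_minus_ca[low] <- NA_real_
  structure(
    list(bap = bap, ba = table$ca + ba_minus_ca, ba_minus_ca = ba_minus_ca,
         ca = table$ca, subject_id = table$subject_id,
         n_available = n_avail, panel = panel),
    class = "ba_result"
  )
}

#' @export
print.ba_result <- function(x, ...) {
  ok <- !is.na(x$ba)
  cat(sprintf("BA result: %d of %d subjects with defined BA\n",
              sum(ok), length(x$ba)))
  if (any(ok)) {
    cat(sprintf("  BA - CA: mean %.2f, sd %.2f years\n",
                mean(x$ba_minus_ca[ok]), stats::sd(x$ba_minus_ca[ok])))
  }
  invisible(x)
}

#' Cohort-level quality statistics
#'
#' Mean and sample standard deviation of BA - CA and the Pearson correlation
#' of BA with CA, computed after trimming the `n_trim_ba` largest and
#' smallest BA values. The panel passes when sigma is below `sigma_limit`
#' and the correlation lies within `r_limits`.
#'
#' @param result a [compute_ba()] result.
#' @param policy an [outlier_policy()] supplying `n_trim_ba`.
#' @param sigma_limit largest acceptable sigma of BA - CA in years.
#' @param r_limits length-2 numeric: acceptable range for the BA/CA
#'   correlation.
#' @return List with `mean`, `sigma`, `r_ba_ca`, `n`, `n_trimmed`,
#'   `sigma_ok`, `r_ok`, `accepted`.
#' @export
cohort_statistics <- function(result, policy = outlier_policy(),
                              sigma_limit = 10, r_limits = c(0.5, 1)) {
  stopifnot(inherits(result, "ba_result"))
  keep <- trim_extreme_ba(result$ba, policy$n_trim_ba)
  n <- sum(keep)
  if (n < 3L) stop("fewer than 3 subjects with defined BA after trimming")
  d <- result$ba_minus_ca[keep]
  r <- pairwise_pearson(result$ba[keep], result$ca[keep])$r
  sigma <- stats::sd(d)
  out <- list(
    mean = mean(d), sigma = sigma, r_ba_ca = r, n = n,
    n_trimmed = sum(!is.na(result$ba)) - n,
    sigma_ok = sigma < sigma_limit,
    r_ok = !is.na(r) && r >= r_limits[1] && r <= r_limits[2]
  )
  out$accepted <- out$sigma_ok && out$r_ok
  out
}

#' Render a panel formula in the published textual style
#'
#' Produces e.g.
#' `BA-CA = (0.83 * [-44.384 + 0.1235 * PWVe - CA] + ...)/5`
#' with one bracketed term per member and the divisor given by the panel's
#' convention (member count, or `sum w` for `weight_sum`).
#'
#' @param panel a [panel_model()].
#' @return A single character string.
#' @export
render_formula <- function(panel) {
  terms <- vapply(panel$members, function(bm) {
    m <- panel$inverses[[bm]]
    d <- m$decimals
    inner <- if (m$family == "linear") {
      inv <- m$inverse
      sprintf("%s %s %s * %s", fmt_coef(inv[["a"]], d),
              if (inv[["b"]] < 0) "-" else "+",
              fmt_coef(abs(inv[["b"]]), d), bm)
    } else if (m$family == "exponential") {
      co <- m$rounded
      sprintf("ln(%s / %s) / %s", bm, fmt_coef(co[["a"]], d),
              fmt_coef(co[["b"]], d))
    } else {
      sprintf("inv2(%s)", bm)
    }
    sprintf("%.2f * [%s - CA]", panel$weights[[bm]], inner)
  }, character(1))
  divisor <- if (panel$divisor_convention == "count") {
    as.character(length(panel$members))
  } else {
    sprintf("%.2f", sum(panel$weights))
  }
  sprintf("BA-CA = (%s)/%s", paste(terms, collapse = " + "), divisor)
}

#' Parse a rendered linear panel formula
#'
#' Inverse of [render_formula()] for panels whose members all use the linear
#' family: recovers weights, inverse-form coefficients and the divisor, and
#' returns an evaluator.
#'
#' @param text a formula string produced by [render_formula()].
#' @return List with `weights`, `terms` (data frame of biomarker, intercept,
#'   slope), `divisor`, and `evaluate(values, ca)` where `values` is a named
#'   list/vector of biomarker values.
#' @export
parse_ba_formula <- function(text) {
  divisor <- as.numeric(sub("^.*\\)/([0-9.]+)$", "\\1", text))
  rx <- "([0-9.]+) \\* \\[(-?[0-9.]+) ([+-]) ([0-9.]+) \\* ([^ ]+) - CA\\]"
  term_strs <- regmatches(text, gregexpr(rx, text))[[1]]
  if (!length(term_strs)) stop("unparseable formula: ", text)
  terms <- lapply(term_strs, function(ts) {
    m <- regmatches(ts, regexec(paste0("^", rx, "$"), ts))[[1]]
    if (!length(m)) stop("unparseable term: ", ts)
    slope <- as.numeric(m[5]) * if (m[4] == "-") -1 else 1
    data.frame(biomarker = m[6], w = as.numeric(m[2]),
               intercept = as.numeric(m[3]), slope = slope,
               stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, terms)
  list(
    weights = stats::setNames(terms$w, terms$biomarker),
    terms = terms, divisor = divisor,
    evaluate = function(values, ca) {
      tot <- 0
      for (i in seq_len(nrow(terms))) {
        bm <- terms$biomarker[i]
        bap <- terms$intercept[i] + terms$slope[i] * values[[bm]]
        tot <- tot + terms$w[i] * (bap - ca)
      }
      tot / divisor
    }
  )
}

#' Export per-subject results as CSV
#'
#' Writes one row per subject: id, CA, BAp per member, number of available
#' members, BA and BA - CA.
#'
#' @param result a [compute_ba()] result.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ba_results <- function(result, path) {
  df <- data.frame(subject_id = result$subject_id, CA = result$ca,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (bm in colnames(result$bap)) df[[paste0("BAp_", bm)]] <- result$bap[, bm]
  df$n_available <- result$n_available
  df$BA <- result$ba
  df$BA_minus_CA <- result$ba_minus_ca
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
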