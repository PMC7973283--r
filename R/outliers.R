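#' Outlier-rejection policy
#'
#' Controls the per-decade sigma rule for unrepresentative biomarker values
#' and the trimming of extreme biological-age values from cohort statistics.
#' Age bins are the 10-year half-open intervals `[lo, lo + 10)` anchored at
#' multiples of 10 years.
#'
#' @param k default number of standard deviations tolerated within each
#'   10-year age bin (> 0).
#' @param per_bin optional named numeric vector overriding `k` for specific
#'   bins; names are bin lower edges (e.g. `c("40" = 2.5)`).
#' @param n_trim_ba non-negative count of maximum and of minimum BA values
#'   excluded from cohort statistics.
#' @return Object of class `outlier_policy`.
#' @export
outlier_policy <- function(k = 3, per_bin = NULL, n_trim_ba = 0L) {
  stopifnot(k > 0, n_trim_ba >= 0)
  if (!is.null(per_bin)) {
    stopifnot(!is.null(names(per_bin)), all(per_bin > 0))
  }
  structure(list(k = k, per_bin = per_bin, n_trim_ba = as.integer(n_trim_ba)),
            class = "outlier_policy")
}

# sigma multiplier for the bin whose lower edge is `lo`
bin_k <- function(policy, lo) {
  key <- as.character(lo)
  if (!is.null(policy$per_bin) && key %in% names(policy$per_bin)) {
    policy$per_bin[[key]]
  } else {
    policy$k
  }
}

#' Reject unrepresentative biomarker values per 10-year age bin
#'
#' Within each 10-year age bin, biomarker cells farther than `k` sample
#' standard deviations from the bin mean are masked (set missing for all
#' downstream computation). Bin statistics are computed on the non-missing
#' cells of that bin; bins with fewer than 3 values are never filtered.
#' Exactly one pass is applied: bin statistics are not recomputed after
#' masking. Chronological age is never masked.
#'
#' @param table a [cohort_table()].
#' @param policy an [outlier_policy()].
#' @param members biomarkers to filter; defaults to all.
#' @return The masked `cohort_table`, with attribute `"mask_report"`: a data
#'   frame (subject, biomarker, value, bin, bin_mean, bin_sd, k).
#' @export
reject_bm_outliers <- function(table, policy = outlier_policy(),
                               members = biomarkers(table)) {
  stopifnot(inherits(table, "cohort_table"), inherits(policy, "outlier_policy"))
  lo <- floor(table$ca / 10) * 10
  report <- data.frame(subject = character(0), biomarker = character(0),
                       value = numeric(0), bin = numeric(0),
                       bin_mean = numeric(0), bin_sd = numeric(0),
                       k = numeric(0), stringsAsFactors = FALSE)
  values <- table$values
  for (bm in members) {
    v <- values[, bm]
    for (edge in sort(unique(lo))) {
      idx <- which(lo == edge & !is.na(v))
      if (length(idx) < 3L) next
      m <- mean(v[idx])
      s <- stats::sd(v[idx])
      if (!is.finite(s) || s == 0) next
      k <- bin_k(policy, edge)
      bad <- idx[abs(v[idx] - m) > k * s]
      if (length(bad)) {
        report <- rbind(report, data.frame(
          subject = table$subject_id[bad], biomarker = bm, value = v[bad],
          bin = edge, bin_mean = m, bin_sd = s, k = k,
          stringsAsFactors = FALSE))
        values[bad, bm] <- NA_real_
      }
    }
  }
  if (nrow(report)) {
    bp_log("outlier filter: masked %d cell(s) beyond the per-bin sigma rule",
           nrow(report))
  }
  out <- table
  out$values <- values
  attr(out, "mask_report") <- report
  out
}

#' Trim extreme biological-age values
#'
#' Removes the `n_trim` largest and `n_trim` smallest BA values from cohort
#' statistics (individual reports are unaffected). Ties are broken by subject
#' order: among equal values, earlier subjects are trimmed first.
#'
#' @param ba numeric vector of per-subject biological ages (NA allowed; NA
#'   entries are never part of the trim and are always excluded from
#'   statistics).
#' @param n_trim non-negative trim count; `2 * n_trim` must be smaller than
#'   the number of defined BA values.
#' @return Logical vector, `TRUE` for entries retained in cohort statistics.
#' @export
trim_extreme_ba <- function(ba, n_trim = 0L) {
  stopifnot(n_trim >= 0)
  keep <- !is.na(ba)
  n <- sum(keep)
  if (n_trim == 0L) return(keep)
  if (2L * n_trim >= n) {
    stop("2 * n_trim must be smaller than the number of defined BA values")
  }
  idx <- which(keep)
  o_low <- idx[order(ba[idx], idx)]          # stable: ties by subject order
  low <- o_low[seq_len(n_trim)]
  rest <- setdiff(idx, low)
  o_high <- rest[order(-ba[rest], rest)]
  keep[low] <- FALSE
  keep[o_high[seq_len(n_trim)]] <- FALSE
  keep
}

#' Export the mask report as CSV
#' @param table a masked [cohort_table()] returned by [reject_bm_outliers()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_mask_report <- function(table, path) {
  rep <- attr(table, "mask_report")
  if (is.null(rep)) stop("table carries no mask report")
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(path)
}
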