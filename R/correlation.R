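#' Biomarker correlation report
#'
#' Computes, on pairwise-complete observations, the Pearson correlation of
#' every biomarker with chronological age and the full biomarker x biomarker
#' cross-correlation matrix, recording the number of complete pairs behind
#' each estimate. Correlations based on fewer than 2 complete pairs, or on a
#' zero-variance column, are reported as undefined (`NA`), never as 0.
#'
#' @param table a [cohort_table()].
#' @return An object of class `correlation_report` with elements
#'   `r_with_ca` (named vector), `n_with_ca` (named integer vector),
#'   `pair_r` (symmetric matrix), `n_pairs` (symmetric integer matrix).
#' @export
correlation_report <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  bms <- biomarkers(table)
  m <- length(bms)
  r_ca <- stats::setNames(rep(NA_real_, m), bms)
  n_ca <- stats::setNames(rep(0L, m), bms)
  for (bm in bms) {
    pc <- pairwise_pearson(table$values[, bm], table$ca)
    r_ca[bm] <- pc$r
    n_ca[bm] <- pc$n
  }
  pair_r <- matrix(NA_real_, m, m, dimnames = list(bms, bms))
  n_pairs <- matrix(0L, m, m, dimnames = list(bms, bms))
  for (i in seq_len(m)) {
    pair_r[i, i] <- 1
    n_pairs[i, i] <- sum(!is.na(table$values[, i]))
    for (j in seq_len(m)[-seq_len(i)]) {
      pc <- pairwise_pearson(table$values[, i], table$values[, j])
      pair_r[i, j] <- pair_r[j, i] <- pc$r
      n_pairs[i, j] <- n_pairs[j, i] <- pc$n
    }
  }
  structure(
    list(r_with_ca = r_ca, n_with_ca = n_ca, pair_r = pair_r,
         n_pairs = n_pairs),
    class = "correlation_report"
  )
}

# Pearson r over pairwise-complete observations; NA when n < 2 or a side is
# constant (zero variance).
pairwise_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2L) return(list(r = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(list(r = NA_real_, n = n))
  list(r = stats::cor(x, y), n = n)
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Correlation report\n  r with CA:\n")
  ord <- order(-abs(x$r_with_ca))
  for (bm in names(x$r_with_ca)[ord]) {
    cat(sprintf("    %-8s r = %7s  (n = %d)\n", bm,
                ifelse(is.na(x$r_with_ca[bm]), "NA",
                       sprintf("%+.3f", x$r_with_ca[bm])),
                x$n_with_ca[bm]))
  }
  invisible(x)
}

#' Correlate each biomarker with chronological age
#'
#' @param table a [cohort_table()].
#' @return Data frame with columns `biomarker`, `r`, `n`; `r` is `NA`
#'   (undefined) for biomarkers with fewer than 2 complete pairs or zero
#'   variance.
#' @export
correlate_with_ca <- function(table) {
  rep <- correlation_report(table)
  data.frame(biomarker = names(rep$r_with_ca),
             r = unname(rep$r_with_ca),
             n = unname(rep$n_with_ca),
             stringsAsFactors = FALSE)
}

#' Reject biomarkers with low correlation with age
#'
#' Screens on the magnitude `|r|`, so biomarkers that decrease with age are
#' retained alongside increasing ones. Undefined correlations are rejected.
#'
#' @param report a [correlation_report()].
#' @param threshold rejection threshold in `[0, 1]`; biomarkers with
#'   `|r| < threshold` are removed.
#' @return List with `retained` (character vector) and `rejected` (data frame
#'   of biomarker and r).
#' @export
reject_low_correlation <- function(report, threshold = 0.3) {
  stopifnot(threshold >= 0, threshold <= 1)
  r <- report$r_with_ca
  keep <- !is.na(r) & abs(r) >= threshold
  rejected <- data.frame(biomarker = names(r)[!keep], r = unname(r[!keep]),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rejected))) {
    bp_log("correlation screen: rejected %s (r = %s, threshold %.3g)",
           rejected$biomarker[i],
           ifelse(is.na(rejected$r[i]), "undefined",
                  sprintf("%.3f", rejected$r[i])), threshold)
  }
  list(retained = names(r)[keep], rejected = rejected)
}

#' Prune redundant biomarkers by cross-correlation
#'
#' Pairs with `|r| >= cross_threshold` are processed in descending `|r|`;
#' from each pair exactly one member is dropped: the one with the worse
#' (larger) accuracy-in-years when accuracies are available for both,
#' otherwise the one with the smaller `|r|` with CA; remaining ties are
#' broken lexicographically by name. A pair with an already-dropped member
#' is skipped.
#'
#' @param report a [correlation_report()].
#' @param retained character vector of candidate biomarkers.
#' @param cross_threshold redundancy threshold in `(0, 1]`.
#' @param accuracy optional named numeric vector of accuracy-in-years per
#'   biomarker (smaller is better), used to choose which member to drop.
#' @return List with `retained` and `rejected` (data frame of dropped, kept,
#'   r).
#' @export
prune_redundant <- function(report, retained, cross_threshold = 0.7,
                            accuracy = NULL) {
  stopifnot(cross_threshold > 0, cross_threshold <= 1)
  bms <- intersect(rownames(report$pair_r), retained)
  pairs <- which(upper.tri(report$pair_r), arr.ind = TRUE)
  recs <- data.frame(
    a = rownames(report$pair_r)[pairs[, 1]],
    b = colnames(report$pair_r)[pairs[, 2]],
    r = report$pair_r[pairs], stringsAsFactors = FALSE
  )
  recs <- recs[recs$a %in% bms & recs$b %in% bms & !is.na(recs$r) &
                 abs(recs$r) >= cross_threshold, , drop = FALSE]
  recs <- recs[order(-abs(recs$r), recs$a, recs$b), , drop = FALSE]
  dropped <- character(0)
  out <- data.frame(dropped = character(0), kept = character(0),
                    r = numeric(0), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(recs))) {
    a <- recs$a[k]; b <- recs$b[k]
    if (a %in% dropped || b %in% dropped) next
    loser <- pick_redundant_loser(a, b, report$r_with_ca, accuracy)
    winner <- setdiff(c(a, b), loser)
    dropped <- c(dropped, loser)
    out <- rbind(out, data.frame(dropped = loser, kept = winner,
                                 r = recs$r[k], stringsAsFactors = FALSE))
    bp_log("redundancy prune: dropped %s (kept %s, cross r = %.3f)",
           loser, winner, recs$r[k])
  }
  list(retained = setdiff(retained, dropped), rejected = out)
}

# decide which member of a redundant pair to drop
pick_redundant_loser <- function(a, b, r_with_ca, accuracy) {
  if (!is.null(accuracy)) {
    aa <- accuracy[[a]] %||% NA_real_
    ab <- accuracy[[b]] %||% NA_real_
    if (!is.na(aa) && !is.na(ab) && aa != ab) {
      return(if (aa > ab) a else b)  # worse (larger) accuracy loses
    }
  }
  ra <- abs(r_with_ca[[a]]); rb <- abs(r_with_ca[[b]])
  if (!is.na(ra) && !is.na(rb) && ra != rb) {
    return(if (ra < rb) a else b)    # weaker age correlation loses
  }
  if (is.na(ra) && !is.na(rb)) return(a)
  if (is.na(rb) && !is.na(ra)) return(b)
  max(a, b)                          # lexicographic tie-break: later name loses
}

#' Export the cross-correlation matrix as CSV
#'
#' @param report a [correlation_report()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_correlations <- function(report, path) {
  utils::write.csv(report$pair_r, path, row.names = TRUE)
  invisible(path)
}
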