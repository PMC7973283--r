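# brute-force oracles, independent of the package's implementation paths

# textbook Pearson formula
bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# closed-form simple least squares via the normal equations
bf_lsq <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- mean(y) - b * mean(x)
  c(a = a, b = b)
}

# sort-and-slice trimming oracle: indices retained after dropping the n_trim
# smallest and n_trim largest values (ties by original position)
bf_trim <- function(ba, n_trim) {
  idx <- which(!is.na(ba))
  ord <- idx[order(ba[idx], idx)]
  keep <- ord
  if (n_trim > 0) keep <- ord[seq(n_trim + 1, length(ord) - n_trim)]
  sort(keep)
}

# small deterministic cohort: one subject per row
toy_cohort <- function(ca, ..., group = NULL) {
  vals <- cbind(...)
  cohort_table(vals, ca, group = group)
}

# write a CSV fixture and return its path
write_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# a correlation_report built directly from given r values (for screening
# rules that only consume the report)
fake_corr_report <- function(r_with_ca, pair_r = NULL, n = 50L) {
  bms <- names(r_with_ca)
  if (is.null(pair_r)) {
    pair_r <- diag(length(bms))
    dimnames(pair_r) <- list(bms, bms)
  }
  structure(
    list(r_with_ca = r_with_ca,
         n_with_ca = stats::setNames(rep(n, length(bms)), bms),
         pair_r = pair_r,
         n_pairs = matrix(n, length(bms), length(bms),
                          dimnames = list(bms, bms))),
    class = "correlation_report")
}
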