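test_that("CA-correlation handles identity, degeneracy and missingness", {
  ca <- c(20, 30, 40, 50, 60)
  tab <- toy_cohort(ca, clone = ca, flat = rep(7, 5),
                    gap = c(1, NA, 2, NA, 3))
  df <- correlate_with_ca(tab)
  expect_equal(df$r[df$biomarker == "clone"], 1)
  expect_equal(df$n[df$biomarker == "clone"], 5L)
  # zero variance is undefined, not zero
  expect_true(is.na(df$r[df$biomarker == "flat"]))
  # pairwise-complete n is recorded per biomarker
  expect_equal(df$n[df$biomarker == "gap"], 3L)
})

test_that("Pearson matches the textbook formula on a 5-point fixture", {
  ca <- c(20, 30, 40, 50, 60)
  bm <- c(1, 3, 2, 5, 4)
  tab <- toy_cohort(ca, bm = bm)
  rep <- correlation_report(tab)
  expect_equal(unname(rep$r_with_ca["bm"]), bf_pearson(ca, bm),
               tolerance = 1e-12)
})

test_that("correlations are invariant to subject order", {
  g <- generate_cohort(synthetic_spec(
    n_subjects = 40,
    biomarkers = list(X = list(a = 0, b = 1, r = 0.7),
                      Y = list(a = 50, b = -2, r = 0.5)),
    missing_fraction = 0.1, seed = 5))
  tab <- g$table
  perm <- sample(seq_along(tab$ca))
  tab2 <- cohort_table(tab$values[perm, ], tab$ca[perm], tab$subject_id[perm])
  r1 <- correlation_report(tab)
  r2 <- correlation_report(tab2)
  expect_equal(r1$r_with_ca, r2$r_with_ca, tolerance = 1e-12)
  expect_equal(r1$pair_r, r2$pair_r, tolerance = 1e-12)
  # symmetry
  expect_equal(r1$pair_r, t(r1$pair_r))
})

test_that("low-correlation screening rejects below |r| threshold", {
  rep <- fake_corr_report(c(A = -0.047, B = 0.232, C = 0.82))
  s <- suppressMessages(reject_low_correlation(rep, 0.3))
  expect_equal(s$retained, "C")
  expect_setequal(s$rejected$biomarker, c("A", "B"))
  # threshold 0: every defined r passes
  expect_equal(suppressMessages(reject_low_correlation(rep, 0))$retained,
               c("A", "B", "C"))
  # threshold 1: only |r| = 1 survives
  rep2 <- fake_corr_report(c(A = 1, B = -1, C = 0.999))
  expect_setequal(suppressMessages(reject_low_correlation(rep2, 1))$retained,
                  c("A", "B"))
  # undefined r is always rejected, with the rejection logged
  rep3 <- fake_corr_report(c(A = NA_real_, B = 0.5))
  s3 <- suppressMessages(reject_low_correlation(rep3, 0))
  expect_equal(s3$retained, "B")
})

test_that("redundancy pruning follows the greedy descending-|r| procedure", {
  bms <- c("A", "B", "C")
  pr <- matrix(c(1, 0.9, 0.8,
                 0.9, 1, 0.85,
                 0.8, 0.85, 1), 3, 3, dimnames = list(bms, bms))
  rep <- fake_corr_report(c(A = 0.6, B = 0.6, C = 0.6), pair_r = pr)
  # hand trace: pairs sorted by |r| are AB(.9), BC(.85), AC(.8); equal CA
  # correlations and no accuracies, so lexicographic tie-break drops the later
  # name: AB drops B; BC skipped (B gone); AC drops C; survivor {A}
  s <- suppressMessages(prune_redundant(rep, bms, 0.7))
  expect_equal(s$retained, "A")
  expect_equal(s$rejected$dropped, c("B", "C"))
  expect_equal(s$rejected$kept, c("A", "A"))

  # no pair above threshold: unchanged
  expect_equal(suppressMessages(prune_redundant(rep, bms, 0.95))$retained, bms)

  # exactly one member of an offending pair is dropped
  pr2 <- matrix(c(1, 0.986, 0.986, 1), 2, 2,
                dimnames = list(c("PWVe", "PWVm"), c("PWVe", "PWVm")))
  rep2 <- fake_corr_report(c(PWVe = 0.82, PWVm = 0.80), pair_r = pr2)
  s2 <- suppressMessages(prune_redundant(rep2, c("PWVe", "PWVm"), 0.7))
  expect_equal(length(s2$retained), 1L)
  # the weaker age correlation loses without accuracies
  expect_equal(s2$retained, "PWVe")
  # with accuracies, the worse (larger) accuracy-in-years loses instead
  s3 <- suppressMessages(prune_redundant(rep2, c("PWVe", "PWVm"), 0.7,
                                         accuracy = c(PWVe = 0.7, PWVm = 5)))
  expect_equal(s3$retained, "PWVe")
  s4 <- suppressMessages(prune_redundant(rep2, c("PWVe", "PWVm"), 0.7,
                                         accuracy = c(PWVe = 5, PWVm = 0.7)))
  expect_equal(s4$retained, "PWVm")
})

test_that("no retained pair exceeds the cross-correlation threshold", {
  for (seed in 1:5) {
    g <- generate_cohort(synthetic_spec(
      n_subjects = 80,
      biomarkers = list(X = list(a = 0, b = 1, r = 0.8),
                        Y = list(a = 10, b = 2, r = 0.7),
                        Z = list(a = 5, b = -1, r = 0.6)),
      links = list(list(source = "X", target = "X2", r_link = 0.9,
                        mean = 0, sd = 1),
                   list(source = "Y", target = "Y2", r_link = 0.85,
                        mean = 0, sd = 1)),
      seed = seed))
    rep <- correlation_report(g$table)
    s <- suppressMessages(prune_redundant(rep, biomarkers(g$table), 0.7))
    kept <- s$retained
    sub <- abs(rep$pair_r[kept, kept, drop = FALSE])
    diag(sub) <- 0
    expect_lt(max(sub, na.rm = TRUE), 0.7)
  }
})

test_that("a near-copy biomarker is detected as redundant", {
  g <- generate_cohort(synthetic_spec(
    n_subjects = 500,
    biomarkers = list(BM1 = list(a = 0, b = 1, r = 0.8)),
    links = list(list(source = "BM1", target = "BM2", r_link = 0.99,
                      mean = 0, sd = 1)),
    seed = 2))
  rep <- correlation_report(g$table)
  expect_gt(abs(rep$pair_r["BM1", "BM2"]), 0.95)
  s <- suppressMessages(prune_redundant(rep, c("BM1", "BM2"), 0.95))
  expect_equal(length(s$retained), 1L)
})

test_that("the correlation matrix exports as a square labelled CSV", {
  tab <- toy_cohort(c(20, 30, 40, 50), X = c(1, 2, 3, 4), Y = c(4, 3, 2, 1))
  rep <- correlation_report(tab)
  path <- tempfile(fileext = ".csv")
  write_correlations(rep, path)
  back <- as.matrix(utils::read.csv(path, row.names = 1))
  expect_equal(unname(back), unname(rep$pair_r), tolerance = 1e-12)
})
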