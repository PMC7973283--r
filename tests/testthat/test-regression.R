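test_that("a noiseless line is recovered exactly", {
  ca <- seq(20, 70, by = 5)
  tab <- toy_cohort(ca, X = 10 + 2 * ca)
  m <- fit_age_regression(tab, "X", "linear")
  expect_equal(unname(m$coefficients), c(10, 2), tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_true(m$monotone)
  expect_equal(m$ca_range, c(20, 70))
})

test_that("linear coefficients match the normal-equations oracle on 5 points", {
  ca <- c(20, 30, 40, 50, 60)
  bm <- c(1, 3, 2, 5, 4)
  tab <- toy_cohort(ca, bm = bm)
  m <- fit_age_regression(tab, "bm", "linear")
  oracle <- bf_lsq(ca, bm)
  expect_equal(unname(m$coefficients["a"]), unname(oracle["a"]),
               tolerance = 1e-9)
  expect_equal(unname(m$coefficients["b"]), unname(oracle["b"]),
               tolerance = 1e-9)
})

test_that("an exponential trend is recovered within 10% under 1% noise", {
  g <- generate_cohort(synthetic_spec(
    n_subjects = 200, ca_range = c(20, 70),
    biomarkers = list(X = list(family = "exponential", a = 50, b = 0.02,
                               noise_sd = 0.01)),
    seed = 4))
  m <- fit_age_regression(g$table, "X", "exponential")
  expect_equal(unname(m$coefficients["b"]), 0.02, tolerance = 0.1)
  expect_equal(unname(m$coefficients["a"]), 50, tolerance = 0.1 * 50)
})

test_that("fit preconditions are enforced", {
  tab <- toy_cohort(c(30, 30, 30), X = c(1, 2, 3))
  expect_error(fit_age_regression(tab, "X", "linear"), "degenerate")
  tab2 <- toy_cohort(c(20, 30), X = c(1, 2))
  expect_error(fit_age_regression(tab2, "X", "linear"), "pairs")
  tab3 <- toy_cohort(c(20, 30, 40, 50), X = c(-1, 2, 3, 4))
  expect_error(fit_age_regression(tab3, "X", "exponential"), "one sign")
})

test_that("family selection keeps linear unless clearly beaten", {
  ca <- seq(20, 70, length.out = 30)
  tab <- toy_cohort(ca, X = 10 + 2 * ca)
  lin <- fit_age_regression(tab, "X", "linear")
  # singleton
  expect_equal(suppressMessages(select_family(list(lin)))$family, "linear")
  # a marginal r2 gain does not displace linear
  lo <- lin; lo$r2 <- 0.50
  hi <- fit_age_regression(tab, "X", "polynomial2"); hi$r2 <- 0.51
  expect_equal(suppressMessages(select_family(list(lo, hi), 0.02))$family,
               "linear")
  # a clear gain does
  ex <- fit_age_regression(toy_cohort(ca, X = 50 * exp(0.02 * ca)), "X",
                           "exponential")
  ex$r2 <- 0.60
  expect_equal(suppressMessages(select_family(list(lo, ex), 0.02))$family,
               "exponential")
})

test_that("published inverse formulas evaluate exactly as printed", {
  m <- manual_inverse("PWVe", intercept = -44.384, slope = 0.1235)
  bap <- invert_regression(m, 600)
  expect_equal(as.numeric(bap), -44.384 + 0.1235 * 600, tolerance = 1e-12)
  expect_equal(as.numeric(bap), 29.716, tolerance = 1e-12)
})

test_that("inversion round-trips a noiseless monotone fit", {
  ca <- seq(20, 70, length.out = 30)
  tab <- toy_cohort(ca, X = 10 + 2 * ca)
  m <- fit_age_regression(tab, "X", "linear")
  bap <- invert_regression(m, 10 + 2 * 40)
  expect_equal(as.numeric(bap), 40, tolerance = 1e-3)
  expect_false(attr(bap, "extrapolated"))
  # outside the calibrated range the value is returned but flagged
  bap2 <- invert_regression(m, 10 + 2 * 90)
  expect_equal(as.numeric(bap2), 90, tolerance = 1e-2)
  expect_true(attr(bap2, "extrapolated"))
})

test_that("coefficient rounding perturbs inversion by under half a year", {
  # fixtures with magnitudes typical of the classic panel
  fixtures <- list(c(a = 359.4, b = 8.0972), c(a = 89.4, b = 0.753),
                   c(a = 3427, b = -15.106), c(a = 71.7, b = -0.35))
  ca <- seq(20, 70, length.out = 41)
  for (co in fixtures) {
    tab <- toy_cohort(ca, X = co["a"] + co["b"] * ca)
    m <- fit_age_regression(tab, "X", "linear", decimals = 4L)
    bap <- invert_regression(m, co["a"] + co["b"] * ca)
    expect_lt(max(abs(bap - ca)), 0.5)
  }
})

test_that("non-monotone and zero-slope fits refuse inversion", {
  ca <- seq(20, 70, length.out = 30)
  # parabola with vertex at CA 45, well inside the range
  tab <- toy_cohort(ca, X = (ca - 45)^2)
  m <- fit_age_regression(tab, "X", "polynomial2")
  expect_false(m$monotone)
  expect_error(invert_regression(m, 100), "monotone")
  # flat biomarker: zero slope
  tabf <- toy_cohort(ca, X = rep(3, 30))
  mf <- fit_age_regression(tabf, "X", "linear")
  expect_false(mf$monotone)
  expect_error(invert_regression(mf, 3), "monotone")
})

test_that("a monotone quadratic inverts to the in-range root", {
  ca <- seq(20, 70, length.out = 30)
  f <- function(x) 100 + 3 * x + 0.05 * x^2   # vertex at -30, monotone here
  tab <- toy_cohort(ca, X = f(ca))
  m <- fit_age_regression(tab, "X", "polynomial2")
  expect_true(m$monotone)
  bap <- invert_regression(m, f(c(25, 45, 65)))
  expect_equal(as.numeric(bap), c(25, 45, 65), tolerance = 0.2)
})

test_that("exponential inversion respects its domain", {
  ca <- seq(20, 70, length.out = 30)
  tab <- toy_cohort(ca, X = 50 * exp(0.02 * ca))
  m <- fit_age_regression(tab, "X", "exponential")
  bap <- invert_regression(m, 50 * exp(0.02 * 40))
  expect_equal(as.numeric(bap), 40, tolerance = 0.2)
  # values outside the exponential's range are NA, not an error
  bad <- suppressMessages(invert_regression(m, c(-5, 50 * exp(0.02 * 30))))
  expect_true(is.na(bad[1]))
  expect_equal(unname(bad[2]), 30, tolerance = 0.2)
})
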