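# panels built from published-style inverse formulas for exactly controlled
# arithmetic
identity_panel <- function(names, weights = NULL,
                           divisor = c("count", "weight_sum")) {
  inv <- lapply(stats::setNames(names, names), function(nm)
    manual_inverse(nm, intercept = 0, slope = 1))
  panel_model(names, inv, weights, match.arg(divisor))
}

test_that("a subject whose every BAp equals CA has BA - CA = 0 under both conventions", {
  ca <- c(30, 45, 60)
  tab <- toy_cohort(ca, X = ca, Y = ca)
  w <- c(X = 0.8, Y = 0.4)
  for (conv in c("count", "weight_sum")) {
    res <- compute_ba(tab, identity_panel(c("X", "Y"), w, conv))
    expect_equal(unname(res$ba_minus_ca), c(0, 0, 0), tolerance = 1e-12)
    expect_equal(unname(res$ba), ca, tolerance = 1e-12)
  }
})

test_that("the published five-biomarker formula evaluates to the hand-computed value", {
  inv <- list(
    PWVe = manual_inverse("PWVe", -44.384, 0.1235),
    A    = manual_inverse("A",    -7.0318, 0.333),
    APs  = manual_inverse("APs",  -118.760, 1.328),
    WT   = manual_inverse("WT",   204.880, -2.8573),
    LC   = manual_inverse("LC",   226.860, -0.0662))
  w <- c(PWVe = 0.83, A = 0.65, APs = 0.58, WT = 0.54, LC = 0.54)
  panel <- panel_model(names(inv), inv, w, "count")
  tab <- toy_cohort(c(50, 50), PWVe = c(800, 800), A = c(150, 150),
                    APs = c(120, 120), WT = c(50, 50), LC = c(2500, 2500))
  res <- compute_ba(tab, panel)
  # independent hand evaluation of the printed expression
  hand <- (0.83 * (-44.384 + 0.1235 * 800 - 50) +
           0.65 * (-7.0318 + 0.333 * 150 - 50) +
           0.58 * (-118.760 + 1.328 * 120 - 50) +
           0.54 * (204.880 - 2.8573 * 50 - 50) +
           0.54 * (226.860 - 0.0662 * 2500 - 50)) / 5
  expect_equal(unname(res$ba_minus_ca[1]), hand, tolerance = 1e-12)
  expect_equal(hand, 1.246522, tolerance = 1e-6)
})

test_that("unit weights under the count divisor reduce to the plain BAp mean", {
  set.seed(12)
  ca <- runif(20, 25, 65)
  tab <- toy_cohort(ca, X = 2 * ca + rnorm(20), Y = 100 - ca + rnorm(20))
  inv <- list(X = manual_inverse("X", 0, 0.5), Y = manual_inverse("Y", 100, -1))
  panel <- panel_model(c("X", "Y"), inv, divisor_convention = "count")
  res <- compute_ba(tab, panel)
  expect_equal(unname(res$ba), unname(rowMeans(res$bap)), tolerance = 1e-12)
})

test_that("default weights are |r| rounded to 2 decimals with a floor", {
  rep <- fake_corr_report(c(A = 0.823, B = -0.53, C = 0.001, D = NA))
  w <- default_weights(rep, c("A", "B", "C"))
  expect_equal(unname(w), c(0.82, 0.53, 0.01))
  expect_error(default_weights(rep, c("A", "D")), "undefined")
})

test_that("missing members use the availability-adjusted divisor", {
  ca <- c(40, 40)
  tab <- toy_cohort(ca, X = c(50, 50), Y = c(60, NA))
  inv <- list(X = manual_inverse("X", 0, 1), Y = manual_inverse("Y", 0, 1))
  w <- c(X = 0.5, Y = 1)
  panel <- panel_model(c("X", "Y"), inv, w, "count")
  res <- compute_ba(tab, panel, min_availability = 0.5)
  # subject 1: (0.5*(50-40) + 1*(60-40))/2 ; subject 2: (0.5*10)/1
  expect_equal(unname(res$ba_minus_ca), c(12.5, 5), tolerance = 1e-12)
  panel2 <- panel_model(c("X", "Y"), inv, w, "weight_sum")
  res2 <- compute_ba(tab, panel2, min_availability = 0.5)
  # subject 2 has only X available: divisor is its weight 0.5
  expect_equal(unname(res2$ba_minus_ca), c(25 / 1.5, 10), tolerance = 1e-12)
  # below the availability floor the BA is undefined
  res3 <- compute_ba(tab, panel, min_availability = 0.9)
  expect_true(is.na(res3$ba[2]))
  expect_equal(res3$n_available[[2]], 1)
})

test_that("cohort statistics behave on exact and shifted clocks", {
  ca <- seq(30, 60, length.out = 12)
  tab <- toy_cohort(ca, X = ca)
  panel <- identity_panel("X")
  res <- compute_ba(tab, panel)
  st <- cohort_statistics(res)
  expect_equal(st$mean, 0, tolerance = 1e-12)
  expect_equal(st$sigma, 0, tolerance = 1e-12)
  expect_equal(st$r_ba_ca, 1, tolerance = 1e-12)
  expect_true(st$accepted)
  # constant shift: mean c, sigma 0, r still 1
  inv_c <- list(X = manual_inverse("X", 7, 1))
  res2 <- compute_ba(tab, panel_model("X", inv_c))
  st2 <- cohort_statistics(res2)
  expect_equal(st2$mean, 7, tolerance = 1e-12)
  expect_equal(st2$sigma, 0, tolerance = 1e-12)
  expect_equal(st2$r_ba_ca, 1, tolerance = 1e-12)
})

test_that("statistics honour BA trimming and the quality gates", {
  ca <- seq(30, 60, length.out = 10)
  tab <- toy_cohort(ca, X = ca)
  res <- compute_ba(tab, identity_panel("X"))
  res$ba[3] <- res$ba[3] + 100   # manufacture one wild BA
  res$ba_minus_ca[3] <- res$ba_minus_ca[3] + 100
  st_raw <- cohort_statistics(res, outlier_policy(n_trim_ba = 0),
                              sigma_limit = 10)
  expect_false(st_raw$sigma_ok)
  st_trim <- cohort_statistics(res, outlier_policy(n_trim_ba = 1),
                               sigma_limit = 10)
  expect_true(st_trim$sigma_ok)
  expect_equal(st_trim$n, 8L)
  expect_error(cohort_statistics(compute_ba(toy_cohort(c(30, 40), X = c(30, 40)),
                                            identity_panel("X"))),
               "fewer than 3")
})

test_that("sigma propagates from member noise as the closed form predicts", {
  # BAp_i = CA + e_i with known noise in years; under the count divisor
  # sd(BA - CA) = sqrt(sum(w_i^2 tau_i^2)) / m
  tau <- c(X = 6, Y = 10, Z = 14)
  w <- c(X = 0.9, Y = 0.6, Z = 0.4)
  b <- c(X = 2, Y = -0.5, Z = 10)
  g <- generate_cohort(synthetic_spec(
    n_subjects = 500, ca_range = c(20, 70),
    biomarkers = list(X = list(a = 10, b = 2, noise_sd = tau[["X"]] * 2),
                      Y = list(a = 80, b = -0.5, noise_sd = tau[["Y"]] * 0.5),
                      Z = list(a = 0, b = 10, noise_sd = tau[["Z"]] * 10)),
    seed = 21))
  models <- lapply(stats::setNames(names(b), names(b)), function(nm)
    fit_age_regression(g$table, nm, "linear"))
  panel <- panel_model(names(b), models, w, "count")
  res <- compute_ba(g$table, panel)
  st <- cohort_statistics(res, sigma_limit = 100, r_limits = c(0, 1))
  predicted <- sqrt(sum(w^2 * tau^2)) / 3
  expect_equal(st$sigma, predicted, tolerance = 0.15)
})

test_that("r(BA, CA) is invariant to adding a constant to every BA", {
  set.seed(4)
  ca <- runif(30, 20, 70)
  tab <- toy_cohort(ca, X = 3 * ca + rnorm(30, 0, 20))
  m <- fit_age_regression(tab, "X", "linear")
  res <- compute_ba(tab, panel_model("X", list(X = m)))
  st <- cohort_statistics(res, sigma_limit = 100, r_limits = c(0, 1))
  res_shift <- res
  res_shift$ba <- res$ba + 11
  res_shift$ba_minus_ca <- res$ba_minus_ca + 11
  st_shift <- cohort_statistics(res_shift, sigma_limit = 100,
                                r_limits = c(0, 1))
  expect_equal(st$r_ba_ca, st_shift$r_ba_ca, tolerance = 1e-12)
})

test_that("formula rendering matches the published layout", {
  inv <- list(X = manual_inverse("X", -44.384, 0.1235))
  p1 <- panel_model("X", inv, c(X = 1))
  expect_equal(render_formula(p1),
               "BA-CA = (1.00 * [-44.384 + 0.1235 * X - CA])/1")
  inv5 <- lapply(stats::setNames(paste0("B", 1:5), paste0("B", 1:5)),
                 function(nm) manual_inverse(nm, 10, 2))
  p5 <- panel_model(names(inv5), inv5)
  txt <- render_formula(p5)
  expect_equal(lengths(regmatches(txt, gregexpr("\\[", txt))), 5L)
  expect_match(txt, "\\)/5$")
  # weight_sum convention renders the weight total as divisor
  p5w <- panel_model(names(inv5), inv5,
                     stats::setNames(rep(0.5, 5), names(inv5)), "weight_sum")
  expect_match(render_formula(p5w), "\\)/2.50$")
})

test_that("a rendered formula parses back and reproduces compute_ba", {
  inv <- list(
    PWVe = manual_inverse("PWVe", -44.384, 0.1235),
    LC   = manual_inverse("LC", 226.860, -0.0662))
  w <- c(PWVe = 0.83, LC = 0.54)
  panel <- panel_model(names(inv), inv, w, "count")
  parsed <- parse_ba_formula(render_formula(panel))
  expect_equal(parsed$weights, w)
  expect_equal(parsed$divisor, 2)
  tab <- toy_cohort(c(50, 55), PWVe = c(800, 760), LC = c(2500, 2600))
  res <- compute_ba(tab, panel)
  for (i in 1:2) {
    expect_equal(parsed$evaluate(as.list(tab$values[i, ]), tab$ca[i]),
                 unname(res$ba_minus_ca[i]), tolerance = 1e-12)
  }
})
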