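#' Specification of a synthetic cohort
#'
#' Describes a cohort generator with the statistical structure the panel
#' optimizer assumes: chronological age drawn uniformly over `ca_range`, each
#' base biomarker following a linear or exponential age trend plus Gaussian
#' noise, optional redundancy links that construct one biomarker from another
#' (inducing a controlled cross-correlation), random missingness, and planted
#' per-bin outliers.
#'
#' Base biomarkers are given as a named list; each entry is a list with
#' `family` (`"linear"` or `"exponential"`), coefficients `a`, `b`, and
#' either `noise_sd` (biomarker units; log-scale for the exponential family)
#' or `r` (target Pearson correlation with CA, from which the noise sd is
#' derived analytically: `noise_sd = |b| * sd(CA) * sqrt(1/r^2 - 1)` for the
#' linear family, with `sd(CA)` the analytic uniform sd).
#'
#' Links are lists with `source`, `target`, `r_link` (target cross-correlation
#' with the source), optional `r_ca` (target correlation with CA; by default
#' the target inherits age signal only through the source), and `mean`, `sd`
#' on the target's own scale.
#'
#' @param n_subjects number of subjects.
#' @param ca_range length-2 numeric, CA range in years.
#' @param biomarkers named list of base biomarker definitions (see Details).
#' @param links list of redundancy-link definitions (see Details).
#' @param missing_fraction probability in `[0, 1)` that any biomarker cell is
#'   missing.
#' @param outliers list of planted-outlier plans: each a list with
#'   `biomarker`, `bin` (lower edge of a 10-year bin), `offset_sigma`
#'   (displacement in bin-sd units) and `count`.
#' @param groups optional named integer vector of per-stratum subject counts;
#'   overrides `n_subjects` with their sum.
#' @param column_order optional character vector fixing the column order of
#'   the generated table.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects, ca_range = c(20, 70),
                           biomarkers = list(), links = list(),
                           missing_fraction = 0, outliers = list(),
                           groups = NULL, column_order = NULL, seed = 1L) {
  stopifnot(length(ca_range) == 2, ca_range[2] > ca_range[1], ca_range[1] > 0,
            missing_fraction >= 0, missing_fraction < 1,
            length(biomarkers) > 0, !is.null(names(biomarkers)))
  if (!is.null(groups)) {
    stopifnot(!is.null(names(groups)), all(groups >= 1))
    n_subjects <- sum(groups)
  }
  for (nm in names(biomarkers)) {
    b <- biomarkers[[nm]]
    if (is.null(b$family)) biomarkers[[nm]]$family <- "linear"
    if (!is.null(b$noise_sd) && b$noise_sd < 0) stop("noise_sd must be >= 0")
    if (is.null(b$noise_sd) && is.null(b$r)) biomarkers[[nm]]$noise_sd <- 0
  }
  structure(
    list(n_subjects = as.integer(n_subjects), ca_range = ca_range,
         biomarkers = biomarkers, links = links,
         missing_fraction = missing_fraction, outliers = outliers,
         groups = groups, column_order = column_order,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# analytic sd of CA ~ Uniform(ca_range)
uniform_sd <- function(ca_range) diff(ca_range) / sqrt(12)

# noise sd achieving a target |r| with CA for a linear biomarker
noise_for_r <- function(b, r, ca_range) {
  stopifnot(abs(r) > 0, abs(r) <= 1)
  abs(b) * uniform_sd(ca_range) * sqrt(1 / r^2 - 1)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws CA uniformly over the spec's range, builds each base biomarker from
#' its age trend plus Gaussian noise, constructs link targets with the
#' requested cross-correlations, then applies missingness and planted
#' outliers. Deterministic given the spec (the session RNG state is
#' restored afterwards).
#'
#' @param spec a [synthetic_spec()].
#' @return List with `table` (a [cohort_table()]) and `truth`: per-biomarker
#'   true coefficients, noise sds and analytic target correlations, plus the
#'   link definitions.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    # jittered lattice: marginally uniform over the range, with systematic
    # age coverage (stable moments) as in stratified cohort recruitment
    ca <- spec$ca_range[1] +
      (sample(n) - stats::runif(n)) * diff(spec$ca_range) / n
    sd_ca <- uniform_sd(spec$ca_range)
    mean_ca <- mean(spec$ca_range)

    truth_bm <- list()
    cols <- list()
    for (nm in names(spec$biomarkers)) {
      b <- spec$biomarkers[[nm]]
      noise_sd <- b$noise_sd %||% noise_for_r(b$b, b$r, spec$ca_range)
      if (b$family == "linear") {
        v <- b$a + b$b * ca + stats::rnorm(n, 0, noise_sd)
        sd_v <- sqrt(b$b^2 * sd_ca^2 + noise_sd^2)
        r_an <- if (sd_v == 0) NA_real_ else b$b * sd_ca / sd_v
        mean_v <- b$a + b$b * mean_ca
      } else {
        v <- b$a * exp(b$b * ca + stats::rnorm(n, 0, noise_sd))
        sd_v <- NA_real_; r_an <- NA_real_; mean_v <- NA_real_
      }
      cols[[nm]] <- v
      truth_bm[[nm]] <- list(family = b$family, a = b$a, b = b$b,
                             noise_sd = noise_sd, r_analytic = r_an,
                             mean_analytic = mean_v, sd_analytic = sd_v)
    }

    for (lk in spec$links) {
      src <- lk$source
      stopifnot(src %in% names(cols))
      tb <- truth_bm[[src]]
      if (is.na(tb$sd_analytic) || tb$sd_analytic == 0) {
        stop("link source must be a linear biomarker with positive variance")
      }
      s_std <- (cols[[src]] - tb$mean_analytic) / tb$sd_analytic
      ca_std <- (ca - mean_ca) / sd_ca
      r_s <- tb$r_analytic
      if (is.null(lk$r_ca)) {
        p <- lk$r_link; q <- 0
      } else {
        p <- (lk$r_link - lk$r_ca * r_s) / (1 - r_s^2)
        q <- (lk$r_ca - lk$r_link * r_s) / (1 - r_s^2)
      }
      res_var <- 1 - p^2 - q^2 - 2 * p * q * r_s
      if (res_var < 0) stop("infeasible link targets for ", lk$target)
      t_std <- p * s_std + q * ca_std + stats::rnorm(n, 0, sqrt(res_var))
      cols[[lk$target]] <- lk$mean + lk$sd * t_std
      truth_bm[[lk$target]] <- list(
        family = "link", source = src, r_link = lk$r_link,
        r_analytic = p * r_s + q, mean_analytic = lk$mean,
        sd_analytic = lk$sd)
    }

    values <- do.call(cbind, cols)
    colnames(values) <- names(cols)
    if (!is.null(spec$column_order)) {
      stopifnot(setequal(spec$column_order, colnames(values)))
      values <- values[, spec$column_order, drop = FALSE]
    }

    if (spec$missing_fraction > 0) {
      mask <- matrix(stats::runif(length(values)) < spec$missing_fraction,
                     nrow(values), ncol(values))
      values[mask] <- NA_real_
    }

    planted <- data.frame(subject = integer(0), biomarker = character(0),
                          value = numeric(0), stringsAsFactors = FALSE)
    for (pl in spec$outliers) {
      bm <- pl$biomarker
      in_bin <- which(ca >= pl$bin & ca < pl$bin + 10 & !is.na(values[, bm]))
      if (length(in_bin) < 3L) next
      m <- mean(values[in_bin, bm]); s <- stats::sd(values[in_bin, bm])
      pickn <- min(pl$count, length(in_bin))
      idx <- sample(in_bin, pickn)
      values[idx, bm] <- m + pl$offset_sigma * s
      planted <- rbind(planted, data.frame(subject = idx, biomarker = bm,
                                           value = values[idx, bm],
                                           stringsAsFactors = FALSE))
    }

    group <- if (!is.null(spec$groups)) {
      rep(names(spec$groups), times = spec$groups)
    } else NULL

    table <- cohort_table(values, ca, group = group)
    list(table = table,
         truth = list(biomarkers = truth_bm, links = spec$links,
                      planted_outliers = planted,
                      missing_fraction = spec$missing_fraction,
                      seed = spec$seed))
  })
}

#' Preset emulating the classic Soviet 15-row biomarker spreadsheet
#'
#' A 13-biomarker cohort spec carrying the labels of the USSR-approved
#' biological-age panel (systolic/diastolic/pulse arterial pressure, elastic-
#' and muscular-artery pulse wave velocity, lung capacity, breath-hold time,
#' eye accommodation, hearing acuity, static balancing, body weight,
#' self-assessed health, Wechsler test), with the structural features the
#' optimizer is designed to detect planted in:
#' \itemize{
#'   \item two near-zero-slope biomarkers (BHT, SAH) that fail the default
#'     age-correlation screen,
#'   \item redundancy links mirroring the classically reported
#'     cross-correlated pairs APs/APd, APs/APp, PWVe/PWVm (above the default
#'     prune threshold) and LC/BW (below it),
#'   \item one high-dispersion biomarker (BW, body weight spanning roughly
#'     45-135 kg) meant to be excluded by a user range criterion rather than
#'     by the statistical screens,
#'   \item 5\% random missingness and three planted per-bin outliers.
#' }
#'
#' @param n_subjects cohort size; the classic female reference group had 160
#'   subjects.
#' @param seed integer seed.
#' @return A [synthetic_spec()]. Its `truth` (after [generate_cohort()])
#'   includes the planted structure; the ground-truth panel that a default-
#'   configured run should recover is stored in the
#'   `"expected_panel"` attribute of the returned spec, along with
#'   `"range_limits"` giving the step-6 interindividual-range criterion that
#'   excludes BW.
#' @export
soviet_panel_preset <- function(n_subjects = 160L, seed = 1L) {
  bms <- list(
    APs  = list(family = "linear", a = 89.4,  b = 0.7530,  r = 0.60),
    PWVe = list(family = "linear", a = 359.4, b = 8.0972,  r = 0.823),
    A    = list(family = "linear", a = 21.1,  b = 3.0030,  r = 0.58),
    LC   = list(family = "linear", a = 3427,  b = -15.106, r = -0.54),
    WT   = list(family = "linear", a = 71.7,  b = -0.3500, r = -0.54),
    SB   = list(family = "linear", a = 75.0,  b = -0.9000, r = -0.50),
    HA   = list(family = "linear", a = -4.0,  b = 0.5000,  r = 0.50),
    BHT  = list(family = "linear", a = 35.0,  b = -0.0200, r = -0.047),
    SAH  = list(family = "linear", a = 30.0,  b = 0.0300,  r = 0.06)
  )
  links <- list(
    list(source = "APs",  target = "APd",  r_link = 0.795, r_ca = 0.50,
         mean = 80,  sd = 12),
    list(source = "APs",  target = "APp",  r_link = 0.85, r_ca = 0.48,
         mean = 45,  sd = 10),
    list(source = "PWVe", target = "PWVm", r_link = 0.986,
         mean = 850, sd = 150),
    list(source = "LC",   target = "BW",   r_link = 0.60, r_ca = -0.52,
         mean = 90,  sd = 22)
  )
  spec <- synthetic_spec(
    n_subjects = n_subjects, ca_range = c(20, 70), biomarkers = bms,
    links = links, missing_fraction = 0.05,
    outliers = list(
      list(biomarker = "PWVe", bin = 40, offset_sigma = 6,  count = 1),
      list(biomarker = "PWVe", bin = 60, offset_sigma = -6, count = 1),
      list(biomarker = "LC",   bin = 30, offset_sigma = 6,  count = 1)
    ),
    column_order = c("APs", "APd", "APp", "PWVe", "PWVm", "LC", "BHT",
                     "A", "HA", "SB", "BW", "SAH", "WT"),
    seed = seed
  )
  attr(spec, "expected_panel") <- c("APs", "PWVe", "LC", "A", "HA", "SB", "WT")
  attr(spec, "expected_rejections") <- list(
    low_correlation = c("BHT", "SAH"),
    redundant = c(APd = "APs", APp = "APs", PWVm = "PWVe"),
    high_dispersion = "BW"
  )
  attr(spec, "range_limits") <- c(BW = 80)
  spec
}

#' Measurement metadata accompanying the classic panel preset
#'
#' Instrument-accuracy metadata for the arterial-pressure and pulse-wave-
#' velocity biomarkers of [soviet_panel_preset()], built from the classic
#' worked examples: systolic pressure changing 40 mmHg over the 20-70-year
#' interval with 5 mmHg instrument accuracy (accuracy 6.25 years), pulse
#' pressure changing 20 mmHg with the same instrument (12.5 years),
#' elastic-artery pulse wave velocity changing 700 m/s with 10 m/s accuracy
#' (0.71 years). Diastolic pressure (a synthetic but physiologically
#' plausible 15 mmHg change with the same instrument, 16.7 years) and the
#' muscular-artery velocity (a synthetic, plausibly coarser instrument
#' accuracy of 20 m/s) are included so that redundancy pruning resolves the
#' pressure and pulse-wave pairs on accuracy, as a practitioner would. The
#' remaining biomarkers carry no metadata and pass the accuracy screen
#' unchecked.
#'
#' @return A [biomarker_spec()] table.
#' @export
soviet_panel_specs <- function() {
  rbind(
    biomarker_spec("APs", "mmHg", instrument_accuracy = 5,
                   reference_change = 40, reference_interval = 50),
    biomarker_spec("APd", "mmHg", instrument_accuracy = 5,
                   reference_change = 15, reference_interval = 50),
    biomarker_spec("APp", "mmHg", instrument_accuracy = 5,
                   reference_change = 20, reference_interval = 50),
    biomarker_spec("PWVe", "m/s", instrument_accuracy = 10,
                   reference_change = 700, reference_interval = 50),
    biomarker_spec("PWVm", "m/s", instrument_accuracy = 20,
                   reference_change = 700, reference_interval = 50)
  )
}
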