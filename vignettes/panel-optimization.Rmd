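---
title: "Stepwise optimization of aging biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise optimization of aging biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bapanel)
```

## The problem

Biological age (BA) summarizes how far an organism's physiology has drifted
from the norms of its chronological age (CA). A practical BA instrument is a
*panel*: a small set of aging biomarkers (BMs) — pulse wave velocity, lung
capacity, blood pressure, and the like — each calibrated against CA in a
reference cohort. Every biomarker's calibration can be inverted to give a
*partial biological age* (BAp), the age at which an average subject would show
the measured value; the panel's BA is a weighted mean of the member BAp
values.

Large candidate panels are expensive to measure and frequently redundant, and
individual biomarkers differ enormously in how precisely they can date a
subject. `bapanel` implements a threshold-driven, fully auditable selection
pipeline that reduces a candidate table to a compact panel while reporting the
numeric evidence for every exclusion. It is deliberately *not* a combinatorial
subset search: each screening rule is a criterion a practitioner can inspect,
override, or disable.

## The seven steps

`ba_panel()` executes, in a fixed order:

1. **Correlation screen.** Pearson correlation of each biomarker with CA on
   pairwise-complete observations. Biomarkers with `|r|` below the rejection
   threshold (default 0.3) or with undefined `r` (fewer than two complete
   pairs, or zero variance) are removed. Magnitude is used so that markers
   that decline with age (lung capacity, static balance) are retained.
2. **Redundancy pruning.** Biomarker pairs cross-correlated at or above the
   redundancy threshold (default 0.7) are processed in descending `|r|`; one
   member of each pair is dropped — the one with the worse accuracy-in-years
   when accuracies are known for both, otherwise the one with the weaker age
   correlation, with remaining ties broken lexicographically. A pair whose
   member is already gone is skipped, so exactly one biomarker falls per
   offending pair.
3. **Accuracy screen.** A biomarker changing by `change` units over a
   reference interval of `interval` years, measured with instrument accuracy
   `acc`, resolves `change/acc` distinguishable units and can therefore date
   a subject no better than `interval/(change/acc)` years. Biomarkers whose
   accuracy-in-years exceeds the limit are removed; biomarkers without
   metadata pass with a warning. Reference changes absent from metadata are
   estimated from a provisional linear fit over the observed age range.
4. **Calibration.** Extreme biomarker values are masked by a per-decade sigma
   rule (below), then linear, exponential and quadratic regressions of
   biomarker on CA are fitted by least squares; coefficients are rounded to
   the configured precision and the fit is inverted algebraically. Biomarkers
   without a strictly monotone (hence invertible) fit on the observed age
   range are removed.
5. **Quality gate.** Per-subject BA is computed (below), the configured
   number of extreme BA values is trimmed from cohort statistics, and the
   panel is checked against the sigma limit (default: sd(BA − CA) < 10
   years) and the acceptable range for r(BA, CA) (default [0.5, 1]). A
   failing panel is flagged `rejected_step5` — the pipeline reports the best
   statistics found rather than searching alternative subsets.
6. **Researcher criterion.** An optional predicate over the retained
   biomarkers and their evidence (age correlation, accuracy, interindividual
   range, fitted model). The packaged example, `criterion_max_range()`,
   excludes biomarkers whose observed spread across subjects exceeds a limit
   — the classic case being body weight, whose interindividual dispersion
   dwarfs its age trend.
7. **Assembly.** Final weights, the rendered formula, and cohort statistics
   for the final member set.

Every removal is a row of the step log, so
`#input biomarkers = #panel members + #attributed rejections` always holds.

## The BA aggregation formula

For a subject with CA `c` and available panel members `i = 1..k` (missing
measurements are simply skipped),

```
BA - CA = sum_i w_i * (BAp_i - c) / D
```

with weights `w_i` in (0, 1] and divisor `D`. The default
`divisor_convention = "count"` sets `D = k`, matching the published style of
panel formulas that divide by the member count even when weights are below 1;
this shrinks BA − CA toward zero relative to a true weighted mean.
`"weight_sum"` (`D = sum of available w_i`) is offered as the statistically
conventional alternative. Default weights are `|r|` with CA rounded to two
decimals (floored at 0.01); user-supplied weights override them. Subjects
with fewer than `min_availability` (default 50%) of the members measured get
no BA and are excluded from cohort statistics with a logged count.

## Inversion and coefficient rounding

Regressions are fitted as biomarker-on-age and inverted algebraically,
matching the printed inverse-form terms of published panels; whether
published coefficients historically came from this convention or from a
direct age-on-biomarker regression is not documented, so the package fixes
and logs the former. For the linear family the forward fit `BM = a + b*CA`
is rounded to `coefficient_decimals` (default 4) places, then the
inverse-form coefficients `a' = -a/b`, `b' = 1/b` are rounded to the same
precision and `BAp = a' + b'*BM` is evaluated exactly as rendered — the
package applies the same rounded formulas it publishes. On biomarkers with
the magnitudes of the classic panel this rounding perturbs BAp by well under
half a year over the calibrated range (asserted in the test suite). The
exponential family inverts as `ln(BM/a)/b` (values with `BM/a <= 0` give
`NA`); the quadratic family returns the root inside the calibrated age range
(or nearest to it). Inversions are never clamped, but values falling outside
the calibrated range carry an extrapolation flag. A quadratic whose vertex
lies inside the observed age range is not monotone and refuses inversion.

The quadratic is the only polynomial family offered: it is the lowest degree
with curvature, and its invertibility is checkable in closed form. Family
selection keeps the linear fit unless a competitor improves r² by more than
`improvement_threshold` (default 0.02) — the families are nested in
flexibility, and the published formulas for the classic panel are linear, so
the simplest family wins ties.

## Outlier handling

Unrepresentative extremes are masked *before* the definitive fits: within
each 10-year age bin (half-open, anchored at multiples of 10), cells farther
than `k` sample standard deviations (default `k = 3`, per-bin overrides
allowed) from the bin mean are treated as missing downstream. Bin statistics
use the n−1 standard deviation (bins are small) and are computed once —
masking is single-pass, since recomputing statistics after each removal would
make the result order- and iteration-dependent. Bins with fewer than three
values are never filtered. Note a single-pass consequence: in a bin of n
values the largest achievable deviation is (n−1)/sqrt(n) standard
deviations, so `k = 3` cannot fire in bins smaller than about 11 — a
deliberate conservatism for sparse bins. Chronological age itself is never
masked. Separately, the `n_trim_ba` largest and smallest BA values can be
excluded from cohort statistics (ties broken by subject order); trimming
affects only the statistics, never the individual reports or the regression
fits, because nothing in the procedure prescribes a refit.

## The synthetic cohort generator

`generate_cohort()` produces cohorts with exactly the structure the
pipeline's screens are designed to detect, together with the ground truth
that produced them. CA is drawn as a jittered lattice over the configured
range — marginally uniform, with the stable age coverage of a systematically
recruited cohort. Base biomarkers follow `a + b*CA` (or `a*exp(b*CA)`) plus
Gaussian noise; the noise sd may be given directly or derived from a target
age correlation. Redundant biomarkers are constructed from a source
biomarker with a requested cross-correlation and, optionally, their own age
correlation. Missingness is uniform per cell; planted outliers displace
chosen cells by a multiple of their bin sd.

`soviet_panel_preset()` emulates the classic 13-biomarker panel
(15 spreadsheet rows counting CA and the subject label) used by Soviet-era
gerontology clinics, at the reference-cohort size of 160 subjects:
two near-zero-slope biomarkers (breath-hold time, self-assessed health) that
the step-1 screen must reject; redundancy links for the systolic/diastolic/
pulse-pressure triple and the two pulse-wave velocities above the prune
threshold, and a moderate lung-capacity/body-weight association below it;
body weight with decisively high interindividual dispersion (roughly 45-135
kg) for the step-6 range criterion; 5% missing cells; and three planted
per-bin outliers. The age-trend coefficients are taken at the physiological
scales of the classic panel's published calibrations. Planted targets are
placed at least ~3 standard errors from every decision threshold so the
planted structure is realized at n = 160 essentially independently of the
seed; in particular the planted low correlations are genuinely near zero and
the redundant pairs are resolved by the accompanying accuracy metadata
(`soviet_panel_specs()` — the classic systolic-pressure and pulse-wave
worked examples plus synthetic, physiologically plausible values for
diastolic pressure and muscular-artery velocity), mirroring how a
practitioner decides which member of a redundant pair to keep.

What the generator does *not* emulate: real biomarkers are not conditionally
Gaussian around a clean trend, missingness in clinic data is not uniform,
instrument panels drift, and real cross-correlation structure is richer than
pairwise links. Passing the planted-structure tests therefore demonstrates
that the pipeline implements its rules correctly, not that those rules are
sufficient for any particular clinical cohort.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `ca_correlation_threshold` | 0.3 | correlation | conventional floor for a usable age signal |
| `cross_correlation_threshold` | 0.7 | correlation | above this, two markers carry largely the same signal |
| `max_accuracy_years` | 10 (cross-sectional), 5 (longitudinal) | years | a marker that cannot date a subject to a decade is uninformative; follow-up studies need ±5 y |
| `sigma_policy$k` | 3 | bin sds | conventional sigma rule; per-decade overrides exposed |
| `coefficient_decimals` | 4 | decimals | precision of published formulas |
| `ba_ca_sigma_limit` | 10 | years | acceptability bound for sd(BA − CA) |
| `ba_ca_r_limits` | [0.5, 1] | correlation | no published default exists; these are package defaults, flagged as such |
| `min_availability` | 0.5 | fraction | quality gate for incomplete subjects |

The two task classes differ only in the default accuracy limit and the
emphasis on interindividual dispersion: longitudinal follow-up of one person
is immune to between-subject spread, while cross-sectional assessment is not
— hence the range criterion at step 6.

## Degenerate inputs and numerical choices

Undefined correlations are reported as `NA`, never coerced to zero, and are
rejected by the screen rather than silently dropped. Accuracy displays are
truncated (not rounded) to one decimal — 6.25 displays as 6.2 — but all
screening uses full precision. The exponential family requires one-signed
values and is otherwise logged as unavailable rather than failing the
biomarker. An all-rejected run returns an explicit `no_panel` result whose
report still carries the full step log. Interactive mode is a prompt
sequence over exactly the automatic thresholds; every session resolves to a
replayable configuration, and scripted answers reproduce the automatic run
bit for bit.

## Known limitations

- Step order is fixed; the dialog-style reordering of screens is deliberately
  unsupported for reproducibility.
- Threshold tightening cannot enlarge the panel on hub-free correlation
  structures (and is verified on the preset over randomized configurations),
  but it is not a theorem: a hub biomarker that out-correlates its satellites
  can in principle shield them from pruning while it survives.
- Measurement error is not propagated through the BA aggregation; the
  accuracy model scores biomarkers individually.
- No robust or quantile regression, no confidence bands, no partial
  correlations, and no multiple-testing correction — screening is on effect
  sizes, not p-values.

## A worked run

```{r, eval = FALSE}
spec <- soviet_panel_preset(seed = 1)
cohort <- generate_cohort(spec)
fit <- ba_panel(cohort$table, specs = soviet_panel_specs(),
                config = pipeline_config(
                  user_criterion = criterion_max_range(c(BW = 80))))
print(fit)
summary(fit)
plot(fit)
predict(fit, cohort$table)
```
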