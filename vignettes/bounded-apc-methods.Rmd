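---
title: "Bounded APC analysis: model, identification, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded APC analysis: model, identification, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcbound)
```

## The model

For person-day diary records indexed by five-year age group, five-year
period, and the implied birth-cohort diagonal, the package fits

y = b0 + theta1·A_L + theta2·C_L + a_NL'·A + p_NL'·P + c_NL'·C + b_NL'·x + e

by weighted least squares, where `A_L` and `C_L` are the weighted-centered
age and cohort group indices, `A`, `P`, `C` are the nonlinear weighted
orthogonal polynomial contrasts for the three factors (orders 2–5 for age
and cohort, 2–3 for the four periods; higher orders are set to zero to
smooth the estimates), and `x` holds day-of-week and holiday covariates.
The full three-trend model is inestimable because the centered period
index equals the sum of the centered age and cohort indices exactly on a
Lexis surface; dropping the period linear column leaves a full-rank model
whose two linear coefficients are the estimable combinations
`theta1 = alpha_L + pi_L` and `theta2 = gamma_L + pi_L`.

Assumptions worth keeping in view: effects are additive on the minutes
scale; survey weights enter as weighted least squares (no replicate-weight
variance estimation); nonlinear structure beyond polynomial order 5 is
attributed to noise; and records are treated as independent across diary
days.

### Why *weighted* orthogonal contrasts

With unequal cell sizes, ordinary orthogonal polynomials are no longer
orthogonal in the sample, so linear and nonlinear coefficient estimates
would contaminate each other and `theta1`/`theta2` would lose their clean
interpretation. The package therefore orthogonalizes the monomials in the
group index under the inner product weighted by per-group survey-weight
totals (a `contrast_weights = "counts"` option uses record counts
instead, for comparison). The linear vector is kept on the raw index
scale — exactly `index - weighted mean index` — so linear coefficients
read as minutes per five-year group step; nonlinear vectors are scaled to
unit weighted root-mean-square norm. Any fixed normalization gives
identical fitted values; coefficients are always reported together with
their basis.

A `linear_scale = "year"` switch divides the linear columns by the group
width so slopes read per calendar year. The default is per group step:
the bounded-region algebra and all reported linear effects are on that
scale, and the reference ranges the test suite reproduces are consistent
with per-group coding.

## Identification, the canonical line, and the constraint

The estimable pair (theta1, theta2) defines the canonical solution line
`(alpha_L, pi_L, gamma_L) = (theta1 - p, p, theta2 - p)`. Substantive
knowledge — time spent alone is lowest for people in their mid-30s —
selects the segment of that line for which the **net total age curve**
(chosen linear age effect plus estimated age nonlinearities) attains its
minimum in the age group containing 35. `grid_search_age_bounds()` scans
candidate linear age effects over a grid and returns the accepted
extremes; because each pairwise comparison between groups is affine in
the candidate, the accepted set is an interval, and the midpoint triple
is always itself accepted (up to grid resolution).

Tunable constraint parameters: `target_min_age` (years; default 35, i.e.
group 35–39), grid `[-20, 20]` in steps of `0.01` minutes per group step
(wide enough to bracket any plausible slope for a minutes outcome;
refining the step moves bounds by at most one step), and a `tie_policy`.
The default policy accepts a candidate when the target group attains the
minimum within a relative tolerance of 1e-9 — a 13-point discrete curve
can tie at machine precision, and a strict-argmin policy
(`unique_argmin`) is available when ties should disqualify.

Bounds propagate along the line with slope one:
`pi in [theta1 - alpha_hi, theta1 - alpha_lo]`,
`gamma in [theta2 - theta1 + alpha_lo, theta2 - theta1 + alpha_hi]`, so
all three ranges share one width. Net-effect bands evaluate each
dimension's curve at its range endpoints (curves are affine in the linear
value, so the envelope is attained there) and at the midpoint triple. The
curves include the intercept and set covariates and the other two
dimensions to their weighted-effect zero — "average day, average
composition" — so values read as mean minutes. Ties in a curve's argmin
resolve to the lowest group index.

## The synthetic generator

`simulate_microdata()` emulates the structural features the estimator
must cope with: a Lexis surface with `cohort = year - age` exact, ages
15–79 by years 2003–2022 (13 × 4 groups, 16 cohort diagonals), unequal
cell sizes (an `age_skewed` density over-samples middle ages; the default
is uniform), positive lognormal survey weights (sdlog 0.5, a moderate
spread; `constant` for didactic tests), additive linear + nonlinear APC
effects, day-of-week effects summing to zero, a holiday offset (−30
minutes at rate 0.03), and Gaussian noise (default sd 60 minutes).

Default effect sizes: grand mean 300 minutes; linear triple
(2.8, 1.4, −1.0) minutes per group step, so the identifiable truth is
theta1 = 4.2, theta2 = 0.4; a U-shaped age nonlinearity (quadratic 8.687
on the unit-RMS basis — about 0.7 minutes per squared group step — plus
small cubic 0.5 and quartic 0.3) calibrated so the net age minimum falls
in the 35–39 group at the generating linear age effect, with the accepted
linear-age interval approximately [2.1, 3.3] under equal weights; mild
period (1.0, 0.8) and cohort (6, −2, 1, 0) nonlinearities. These choices
keep the net curves qualitatively like observed time-alone profiles (a
mid-30s minimum, rising period trend, U-shaped cohort profile) at a
conservative overall amplitude.

Two deliberate departures from realism:

* **No censoring by default.** Real diary outcomes live in [0, 1440] and
  with sd-60 noise a small fraction of simulated outcomes falls below
  zero. Clamping (`clamp_outcome = TRUE`) restores realism but biases
  recovery of the generating effects, so recovery tests run unclamped and
  the clamped mode is documented as biased.
* **Nonlinear truth on the realized basis.** Ground-truth nonlinear
  coefficients are defined on the weighted contrast basis of the realized
  sample (the very basis the design stage rebuilds from the same table),
  so with zero noise the fit recovers every coefficient to numerical
  precision rather than approximately. The linear part is computed from
  the weighted-centered indices, which coincide with the basis linear
  vectors.

What passing tests on these data do **not** show about real surveys:
weights here are independent of cells and outcomes (real weights are
not), noise is Gaussian and homoskedastic (diary minutes are heavy-tailed
and heaped at 5-minute units), every cell is occupied, and outcomes are
uncensored. The generator validates the estimator's algebra and sampling
behavior, not the substantive realism of any particular dataset.

### A numerical note on the null direction

The APC identification problem means triples shifted by `(+d, -d, +d)`
describe the same data distribution. The generator honors this *bitwise*:
it depends on the triple only through `theta1` and `theta2`, snapped to a
`2^-32` grid (a perturbation below 1.2e-10 minutes per group step,
orders of magnitude under every tolerance used anywhere). Without the
snap, floating-point rounding of e.g. `(2.8 + 17) + (1.4 - 17)` versus
`2.8 + 1.4` would break exact equality for large shifts even though the
mathematics is an identity.

## Numerical choices

* WLS is solved by QR on the weight-scaled design (`lm.wfit`); an
  independent normal-equations solver exists purely as a cross-check and
  the two agree to 1e-8 in the tests. The condition number of the
  weight-scaled design is reported; on default-scheme data it is ~30,
  dominated by the near-collinearity of the age and cohort linear
  contrasts on a short (four-period) Lexis surface.
* Contrast construction uses modified Gram–Schmidt with a second
  orthogonalization pass; off-diagonal weighted Gram entries stay below
  1e-10 across random weight draws for all group counts used here.
* Degenerate inputs fail loudly: empty groups are named in errors (both
  at contrast construction and as rank-deficiency diagnostics), an
  infeasible constraint reports the argmin group at the grid ends, empty
  filter results warn while downstream stages raise.
* `noise_sd = 0` is accepted by the generator so exact-recovery
  invariants can be tested; user-facing validation still rejects
  out-of-range outcomes when data re-enter through `read_microdata()`.

## Design choices that were genuinely open

* **Per-group linear scale** as default (vs per-year): the bounded-region
  algebra on reference values is consistent with per-group coding, and it
  makes the grid span interpretable; both scales are supported.
* **Contrast weights from survey-weight totals** rather than counts,
  matching the principle that weights apply to all models; counts are an
  option for sensitivity.
* **Weighted-effect coding for covariates** (reference Sunday /
  non-holiday), so the intercept stays on the weighted grand mean and net
  curves need no post-hoc covariate adjustment.
* **Cohort labels** are printed as the realized birth-year span of each
  diagonal (9 calendar years for interior diagonals, e.g. "1924-1932");
  the span is labeling only and plays no role in estimation.
* **Gender strata are fully separate models**, each with its own contrast
  weights — there is no pooled interaction model, mirroring stratified
  practice.
* **Missing outcome or weight drops the row** (itemized in the validation
  report) rather than imputing; diary extracts are effectively complete
  for these fields and silent imputation would be worse than a counted
  rejection.

## Problem sizes in the test suite

Structural tests simulate 20–60 thousand records; the parameter-recovery
study uses 20 replicate surveys of 50,000 records at noise sd 60, and the
acceptance script's single full run uses 100,000 records. At 50,000
records the sampling standard error of each estimated theta is roughly
0.25–0.28 minutes per group step — the age-cohort collinearity inflates
it by a factor of ~3.5 over an orthogonal design — which is the right
yardstick for any recovery comparison at these sizes.

## Known limitations

* No sampling-uncertainty bands: the reported bands quantify
  identification uncertainty only.
* Single-year (ungrouped) designs, unequal group widths, and alternative
  constraint families (monotonicity, sign restrictions) are out of scope.
* No replicate-weight or design-based variance estimation.
* The generator's Gaussian noise understates the tails of real diary
  outcomes; heavier-tailed options are unimplemented.
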