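# apcbound

Bounded age-period-cohort (APC) analysis of survey-weighted time-diary
microdata.

## The problem

Any outcome indexed by age, calendar time, and birth cohort faces the APC
identification problem: because Age = Period − Cohort, the three linear
trends cannot all be estimated from a single dataset. What *is* estimable
is (i) every nonlinear deviation from the linear trends and (ii) two
linear combinations of the linear effects,

    theta1 = alpha_L + pi_L        theta2 = gamma_L + pi_L

where `alpha_L`, `pi_L`, `gamma_L` are the linear age, period, and cohort
effects (here in minutes of the outcome per five-year group step). The
triples consistent with the data form the **canonical solution line**

    (alpha_L, pi_L, gamma_L) = (theta1 - pi_L, pi_L, theta2 - pi_L).

`apcbound` implements this partial-identification workflow for
person-day diary data (the motivating outcome is minutes spent alone in
nonwork activities, ages 15–79, diary years 2003–2022):

1. **Design** — 13 five-year age groups, 4 five-year periods, and the 16
   implied cohort diagonals; *weighted* orthogonal polynomial contrasts
   (weights = per-group survey-weight totals) keep linear and nonlinear
   coefficients independent despite unequal cell sizes; nonlinear orders
   beyond 5 are set to zero to smooth the estimates.
2. **Fit** — weighted least squares of the estimable reparameterized
   model: intercept, age and cohort linear contrasts (carrying `theta1`
   and `theta2`), all nonlinear contrasts, and weighted-effect-coded
   day-of-week and holiday covariates (20 columns for the defaults).
3. **Bound** — a grid search accepts the linear age effects for which the
   net total age curve (linear + nonlinear parts) attains its minimum in
   the group containing age 35, the well-documented low point of time
   spent alone over the life course; the accepted extremes propagate
   along the line to period and cohort ranges with the same width.
4. **Net effects** — per-dimension net total curves in minutes, a `mid`
   curve at the region midpoint and a `min`/`max` identification band
   over the bounded region, with summaries (argmin/argmax groups,
   min-max gap).

A synthetic generator (`sim_config()` / `simulate_microdata()`) produces
survey-weighted Lexis-structured microdata with known ground truth, so
the whole pipeline is testable end to end without any survey download.

## Worked example

```r
library(apcbound)

cfg <- sim_config(seed = 42, n_records = 80000)   # truth: theta1 = 4.2, theta2 = 0.4
tab <- simulate_microdata(cfg)
fit <- fit_apc_model(build_design_matrix(assign_groups(filter_records(tab))))
fit
#> <apc_fit> weighted least squares, n = 80000
#>   beta0  (weighted grand mean): 299.1726
#>   theta1 (alpha_L + pi_L):      4.1142
#>   theta2 (gamma_L + pi_L):      0.2855
#>   residual sd 59.7488, condition number 30.8

region <- bounds_to_ranges(fit$theta1, fit$theta2, grid_search_age_bounds(fit))
region
#> <apc_region> bounded segment of the canonical solution line
#>   linear age     [1.730, 2.780]
#>   linear period  [1.334, 2.384]
#>   linear cohort  [-2.099, -1.049]
#>   midpoint (2.255, 1.859, -1.574)

bands <- net_effect_bands(fit, region)
summarize_curve(bands$age)[c("argmin_label", "argmax_label", "gap")]
#> $argmin_label [1] "35-39"   $argmax_label [1] "75-79"   $gap [1] 39.5
head(bands$age)
#>   group label      mid      min      max
#> 1     0 15-19 297.8422 294.6872 300.9973
#> 2     1 20-24 294.2855 291.6554 296.9156
#> 3     2 25-29 291.5346 289.4295 293.6397
#> 4     3 30-34 289.8634 288.2833 291.4435
#> 5     4 35-39 289.3284 288.2733 290.3835
#> 6     5 40-44 289.8544 289.3243 290.3845
```

Reading the output: the fit recovers the estimable combinations (truth
4.2 and 0.4) to within sampling noise at this size; the constraint bounds
the linear age effect to [1.73, 2.78] minutes per five-year step, which
pins the linear period and cohort effects to intervals of the same width
on the canonical line; and the net total age curve bottoms out in the
35–39 group by construction of the constraint, with an identification
band that pinches to zero where the centered linear contrast vanishes.

For a one-call version, `run_pipeline(run_config(input = tab, out_dir =
"results/"))` fits each gender stratum separately (each with its own
contrast weights) and writes `estimates.json`, `bounded_region.json`,
`canonical_line.csv`, `net_effects.csv`, `summaries.json`,
`descriptives.csv`, and a run `manifest.json`. Weekday/weekend and
pre-pandemic (2003–2019) sensitivity analyses are pure configuration:
`filter_spec(day_subset = c("Sat", "Sun"))`,
`filter_spec(year_range = c(2003, 2019))`.

Real survey extracts are consumed from a flat delimited file with header
columns `age, year, cohort_year (optional), gender, minutes_alone,
weight, day_of_week, holiday`; `read_microdata()` validates every row
(cohort identity `cohort_year = year - age`, outcome within a diary day,
positive weights) and reports all rejections.

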