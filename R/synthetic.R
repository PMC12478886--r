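#' Simulation configuration
#'
#' Ground-truth configuration for the synthetic time-diary generator. The
#' defaults emulate the study conditions of the analysis this package
#' supports: a Lexis surface of ages 15-79 by diary years 2003-2022 with
#' the cohort identity holding exactly, survey-like lognormal weights, an
#' outcome around 300 minutes per day with a linear effect triple at the
#' men's midpoint (2.8, 1.4, -1.0) minutes per five-year group step, a
#' U-shaped age nonlinearity whose net minimum (at the default linear age
#' effect) falls in the 35-39 group, day-of-week and holiday effects, and
#' Gaussian noise.
#'
#' Nonlinear coefficients are expressed on the unit weighted-RMS contrast
#' basis of the realized sample, so model recovery is exact as noise goes
#' to zero. The default quadratic age coefficient 8.687 corresponds to a
#' curvature of about 0.7 minutes per squared group step on 13
#' equal-weight groups.
#'
#' @param seed Integer RNG seed.
#' @param n_records Number of person-day rows.
#' @param age_range,year_range Closed integer intervals; widths must be
#'   multiples of 5 so the default five-year grouping tiles them.
#' @param gender_mix Proportion female in \[0, 1\].
#' @param grand_mean Baseline outcome, minutes per diary day.
#' @param linear_triple `c(alpha_L, pi_L, gamma_L)`, minutes per group
#'   step. Only `alpha_L + pi_L` and `gamma_L + pi_L` are recoverable.
#' @param age_nl,period_nl,cohort_nl Nonlinear coefficients for orders
#'   2..5, 2..3, 2..5 (lengths at most `G - 1` per factor).
#' @param dow_effects Seven minutes-scale offsets (Mon..Sun) summing to
#'   zero (days are drawn uniformly, so this is the weighted-mean-zero
#'   condition).
#' @param holiday_effect Minutes offset on holidays.
#' @param holiday_rate Probability a diary day is a holiday.
#' @param noise_sd Gaussian noise standard deviation, minutes (0 allowed
#'   for exact-recovery checks).
#' @param weight_law `"constant"` or `"lognormal"`.
#' @param weight_meanlog,weight_sdlog Lognormal weight parameters.
#' @param cell_density `"uniform"` or `"age_skewed"` (middle-aged
#'   respondents over-represented, emulating unequal survey cell sizes).
#' @param clamp_outcome Clamp outcomes into \[0, 1440\]? Default `FALSE`;
#'   clamping makes the data look like real diaries but biases recovery of
#'   the generating effects.
#' @return An object of class `apc_sim_config`.
#' @seealso [simulate_microdata()], [true_identifiable_params()],
#'   [expected_group_means()]
#' @export
sim_config <- function(seed = 1L,
                       n_records = 50000L,
                       age_range = c(15L, 79L),
                       year_range = c(2003L, 2022L),
                       gender_mix = 0.5,
                       grand_mean = 300,
                       linear_triple = c(2.8, 1.4, -1.0),
                       age_nl = c(8.687, 0.5, 0.3, 0),
                       period_nl = c(1.0, 0.8),
                       cohort_nl = c(6.0, -2.0, 1.0, 0),
                       dow_effects = c(10, 12, 12, 10, 5, -25, -14) -
                         mean(c(10, 12, 12, 10, 5, -25, -14)),
                       holiday_effect = -30,
                       holiday_rate = 0.03,
                       noise_sd = 60,
                       weight_law = c("lognormal", "constant"),
                       weight_meanlog = 0,
                       weight_sdlog = 0.5,
                       cell_density = c("uniform", "age_skewed"),
                       clamp_outcome = FALSE) {
  stopifnot(n_records > 0, noise_sd >= 0,
            gender_mix >= 0, gender_mix <= 1,
            holiday_rate >= 0, holiday_rate <= 1,
            length(linear_triple) == 3, length(dow_effects) == 7)
  if (abs(sum(dow_effects)) > 1e-8) {
    stop("dow_effects must sum to zero (days are drawn uniformly)")
  }
  scheme <- scheme_for_ranges(age_range, year_range)
  check_orders <- function(nl, G, what) {
    # orders run 2..min(5, G - 1), so at most min(4, G - 2) coefficients
    if (length(nl) > min(4L, G - 2L)) {
      stop(what, " nonlinear coefficients exceed available orders (max ",
           min(4L, G - 2L), " values for ", G, " groups)")
    }
  }
  check_orders(age_nl, scheme$n_age, "age")
  check_orders(period_nl, scheme$n_period, "period")
  check_orders(cohort_nl, scheme$n_cohort, "cohort")
  structure(list(seed = as.integer(seed), n_records = as.integer(n_records),
                 age_range = as.integer(age_range),
                 year_range = as.integer(year_range),
                 gender_mix = gender_mix, grand_mean = grand_mean,
                 linear_triple = linear_triple,
                 age_nl = age_nl, period_nl = period_nl,
                 cohort_nl = cohort_nl, dow_effects = dow_effects,
                 holiday_effect = holiday_effect,
                 holiday_rate = holiday_rate, noise_sd = noise_sd,
                 weight_law = match.arg(weight_law),
                 weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog,
                 cell_density = match.arg(cell_density),
                 clamp_outcome = clamp_outcome, scheme = scheme),
            class = "apc_sim_config")
}

scheme_for_ranges <- function(age_range, year_range, width = 5L) {
  n_age <- (age_range[2] - age_range[1] + 1L) / width
  n_period <- (year_range[2] - year_range[1] + 1L) / width
  if (n_age != round(n_age) || n_period != round(n_period)) {
    stop("age_range and year_range widths must be multiples of ", width)
  }
  grouping_scheme(age_start = age_range[1], age_width = width,
                  n_age = as.integer(n_age), period_start = year_range[1],
                  period_width = width, n_period = as.integer(n_period))
}

age_density <- function(config) {
  ages <- config$age_range[1]:config$age_range[2]
  if (config$cell_density == "uniform") {
    p <- rep(1, length(ages))
  } else {
    p <- stats::dnorm(ages, mean = 47, sd = 16)
  }
  list(ages = ages, p = p / sum(p))
}

# Sum of the configured nonlinear contributions for one factor, as a
# per-group vector on the given contrast basis.
nl_curve_from_config <- function(nl_coefs, basis) {
  out <- rep(0, basis$n_groups)
  if (length(nl_coefs) == 0) return(out)
  for (j in seq_along(nl_coefs)) {
    out <- out + nl_coefs[j] * basis$nonlinear[[paste0("nl", j + 1L)]]
  }
  out
}

#' Simulate survey-weighted Lexis microdata with known APC truth
#'
#' Draws `n_records` person-day rows: age and year from the configured
#' cell density (cohort year is `year - age` by construction), gender,
#' day of week (uniform), holiday flag, survey weight, and Gaussian noise;
#' then assembles the outcome as
#' `grand_mean + linear APC part + nonlinear APC part + day/holiday
#' effects + noise`. The linear part uses the weighted-centered group
#' indices of the realized sample and the nonlinear part uses the weighted
#' orthogonal contrast bases the design stage would build from this very
#' table, so a weighted least-squares fit recovers `theta1`, `theta2`, and
#' all nonlinear coefficients exactly as `noise_sd -> 0`.
#'
#' Identical seed and config give a bit-identical table, and shifting the
#' linear triple along the null direction `(+d, -d, +d)` leaves every
#' outcome unchanged — the generator exhibits the APC identification
#' problem by construction.
#'
#' @param config An `apc_sim_config`.
#' @return An `apc_microdata` table with attributes `scheme`, `truth`
#'   (the config plus the implied `theta1`/`theta2`).
#' @export
simulate_microdata <- function(config) {
  stopifnot(inherits(config, "apc_sim_config"))
  n <- config$n_records
  scheme <- config$scheme
  set.seed(config$seed)
  dens <- age_density(config)
  age <- sample(dens$ages, n, replace = TRUE, prob = dens$p)
  year <- sample(config$year_range[1]:config$year_range[2], n,
                 replace = TRUE)
  gender <- ifelse(stats::runif(n) < config$gender_mix, "female", "male")
  dow <- sample(DAY_LEVELS, n, replace = TRUE)
  holiday <- stats::runif(n) < config$holiday_rate
  weight <- if (config$weight_law == "constant") rep(1, n) else
    stats::rlnorm(n, config$weight_meanlog, config$weight_sdlog)
  noise <- stats::rnorm(n, 0, config$noise_sd)

  age_idx <- (age - scheme$age_start) %/% scheme$age_width
  period_idx <- (year - scheme$period_start) %/% scheme$period_width
  cohort_idx <- period_idx - age_idx + scheme$n_age - 1L

  # The outcome distribution depends on the linear triple only through the
  # identifiable combinations theta1 = alpha_L + pi_L and theta2 = gamma_L
  # + pi_L (the centered period index equals the sum of the centered age
  # and cohort indices on the Lexis surface). Computing the linear part
  # from those combinations — snapped to a 2^-32 grid to absorb the last
  # ulps of the sums — makes the null-direction invariance exact in
  # floating point: triples shifted by (+d, -d, +d) give bit-identical
  # outcomes.
  wm <- function(v) sum(weight * v) / sum(weight)
  th <- round(true_identifiable_params(config) * 2^32) / 2^32
  linear <- th[["theta1"]] * (age_idx - wm(age_idx)) +
    th[["theta2"]] * (cohort_idx - wm(cohort_idx))

  nl <- rep(0, n)
  specs <- list(age = list(config$age_nl, age_idx, scheme$n_age),
                period = list(config$period_nl, period_idx,
                              scheme$n_period),
                cohort = list(config$cohort_nl, cohort_idx,
                              scheme$n_cohort))
  for (f in names(specs)) {
    coefs <- specs[[f]][[1]]
    if (length(coefs) == 0 || all(coefs == 0)) next
    idx <- specs[[f]][[2]]
    G <- specs[[f]][[3]]
    wsum <- vapply(0:(G - 1), function(k) sum(weight[idx == k]), numeric(1))
    if (any(wsum <= 0)) {
      stop("simulate_microdata: empty ", f, " group(s) in the draw; ",
           "increase n_records or drop the ", f, " nonlinearity")
    }
    basis <- weighted_orthogonal_contrasts(wsum, length(coefs) + 1L, f)
    nl <- nl + nl_curve_from_config(coefs, basis)[idx + 1L]
  }

  y <- config$grand_mean + linear + nl +
    config$dow_effects[match(dow, DAY_LEVELS)] +
    ifelse(holiday, config$holiday_effect, 0) + noise
  if (config$clamp_outcome) y <- pmin(pmax(y, 0), 1440)

  tab <- as_apc_microdata(data.frame(
    age = as.integer(age), year = as.integer(year),
    cohort_year = as.integer(year - age), gender = gender,
    minutes_alone = y, weight = weight, day_of_week = dow,
    holiday = holiday, stringsAsFactors = FALSE))
  attr(tab, "scheme") <- scheme
  attr(tab, "truth") <- c(list(config = config),
                          as.list(true_identifiable_params(config)))
  tab
}

#' Ground-truth identifiable parameters
#'
#' The only linear quantities a fit can recover from data generated by a
#' config: `theta1 = alpha_L + pi_L` and `theta2 = gamma_L + pi_L`.
#'
#' @param config An `apc_sim_config`.
#' @return Named numeric `c(theta1 = ..., theta2 = ...)`.
#' @export
true_identifiable_params <- function(config) {
  t <- config$linear_triple
  c(theta1 = t[1] + t[2], theta2 = t[3] + t[2])
}

#' Closed-form expected group means under a simulation config
#'
#' The noise-free population mean surface implied by a config, evaluated
#' by exhaustive enumeration of all (age, year) cells under the configured
#' cell density and marginalized to each of the three dimensions
#' (population-level contrast bases; survey weights are drawn
#' independently of cells, so they do not shift the expectation). Day
#' effects average to zero by the sum-to-zero constraint; the holiday
#' contribution enters as `holiday_rate * holiday_effect`. Serves as the
#' recovery target for fitted net-effect curves.
#'
#' @param config An `apc_sim_config`.
#' @return Named list of three data.frames (`age`, `period`, `cohort`)
#'   with columns `group`, `label`, `mean`.
#' @export
expected_group_means <- function(config) {
  stopifnot(inherits(config, "apc_sim_config"))
  scheme <- config$scheme
  dens <- age_density(config)
  years <- config$year_range[1]:config$year_range[2]
  cells <- expand.grid(age = dens$ages, year = years)
  cells$p <- dens$p[match(cells$age, dens$ages)] / length(years)
  a_idx <- (cells$age - scheme$age_start) %/% scheme$age_width
  p_idx <- (cells$year - scheme$period_start) %/% scheme$period_width
  c_idx <- p_idx - a_idx + scheme$n_age - 1L

  wsum <- function(idx, G) vapply(0:(G - 1),
                                  function(k) sum(cells$p[idx == k]),
                                  numeric(1))
  wm <- function(idx) sum(cells$p * idx)
  mean_cell <- config$grand_mean +
    config$linear_triple[1] * (a_idx - wm(a_idx)) +
    config$linear_triple[2] * (p_idx - wm(p_idx)) +
    config$linear_triple[3] * (c_idx - wm(c_idx)) +
    config$holiday_rate * config$holiday_effect

  add_nl <- function(mean_cell, coefs, idx, G, f) {
    if (length(coefs) == 0 || all(coefs == 0)) return(mean_cell)
    basis <- weighted_orthogonal_contrasts(wsum(idx, G),
                                           length(coefs) + 1L, f)
    mean_cell + nl_curve_from_config(coefs, basis)[idx + 1L]
  }
  mean_cell <- add_nl(mean_cell, config$age_nl, a_idx, scheme$n_age, "age")
  mean_cell <- add_nl(mean_cell, config$period_nl, p_idx, scheme$n_period,
                      "period")
  mean_cell <- add_nl(mean_cell, config$cohort_nl, c_idx, scheme$n_cohort,
                      "cohort")

  marginal <- function(idx, G, labels) {
    m <- vapply(0:(G - 1), function(k) {
      sum(cells$p[idx == k] * mean_cell[idx == k]) / sum(cells$p[idx == k])
    }, numeric(1))
    data.frame(group = 0:(G - 1), label = labels, mean = m)
  }
  list(age = marginal(a_idx, scheme$n_age, scheme$age_labels),
       period = marginal(p_idx, scheme$n_period, scheme$period_labels),
       cohort = marginal(c_idx, scheme$n_cohort, scheme$cohort_labels))
}
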