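# A hand-built fit over a 4-group factor with equal weights, for
# closed-form curve checks.
flat_fit_4 <- function(beta0 = 300) {
  scheme <- grouping_scheme(age_start = 15, n_age = 4, period_start = 2003,
                            n_period = 4)
  mk <- function(f, G) weighted_orthogonal_contrasts(rep(1, G), 3, f)
  structure(list(beta0 = beta0, theta1 = 1, theta2 = 0,
                 age_nl = list(age_nl2 = 0, age_nl3 = 0),
                 period_nl = list(period_nl2 = 0, period_nl3 = 0),
                 cohort_nl = list(cohort_nl2 = 0, cohort_nl3 = 0),
                 bases = list(age = mk("age", 4), period = mk("period", 4),
                              cohort = mk("cohort", 7)),
                 scheme = scheme), class = "apc_fit")
}

test_that("a pure linear curve is the shifted centered index", {
  fit <- flat_fit_4()
  v <- net_total_curve(fit, "age", linear_value = 1,
                       include_intercept = TRUE)
  expect_equal(unname(v), c(298.5, 299.5, 300.5, 301.5))
  v0 <- net_total_curve(fit, "age", linear_value = 0)
  expect_equal(unname(v0), rep(300, 4))
})

test_that("curves carry group labels and honor include_intercept", {
  tab <- simulate_microdata(quick_config(n = 20000))
  fit <- fit_from_table(tab)
  v <- net_total_curve(fit, "cohort", 0, include_intercept = FALSE)
  expect_equal(names(v), fit$scheme$cohort_labels)
  expect_equal(net_total_curve(fit, "cohort", 0) - fit$beta0, v)
})

test_that("bands: mid within envelope, width follows the linear contrast", {
  tab <- simulate_microdata(quick_config(n = 30000))
  fit <- fit_from_table(tab)
  region <- bounds_to_ranges(fit$theta1, fit$theta2, c(2.2, 3.2))
  bands <- net_effect_bands(fit, region)
  for (dim in names(bands)) {
    b <- bands[[dim]]
    expect_true(all(b$min <= b$mid + 1e-12 & b$mid <= b$max + 1e-12))
    rng <- switch(dim, age = region$alpha_range, period = region$pi_range,
                  cohort = region$gamma_range)
    lin <- fit$bases[[dim]]$linear
    expect_equal(b$max - b$min, abs(lin) * diff(rng), tolerance = 1e-10)
  }
})

test_that("a degenerate region collapses every band to zero width", {
  tab <- simulate_microdata(quick_config(n = 20000))
  fit <- fit_from_table(tab)
  region <- bounds_to_ranges(fit$theta1, fit$theta2, c(2.8, 2.8))
  bands <- net_effect_bands(fit, region)
  for (b in bands) expect_equal(b$min, b$max, tolerance = 1e-10)
})

test_that("the period band is tighter than age and cohort bands", {
  # short period index span + narrow alpha range => tight period envelope
  tab <- simulate_microdata(quick_config(n = 30000))
  fit <- fit_from_table(tab)
  region <- bounds_to_ranges(fit$theta1, fit$theta2,
                             grid_search_age_bounds(fit))
  bands <- net_effect_bands(fit, region)
  spread <- vapply(bands, function(b) max(b$max - b$min), numeric(1))
  expect_lt(spread[["period"]], spread[["age"]])
  expect_lt(spread[["period"]], spread[["cohort"]])
})

test_that("summaries scan the mid curve with lowest-index tie rule", {
  fit <- flat_fit_4()
  region <- bounds_to_ranges(0, 0, c(0, 0))
  flat <- net_effect_bands(fit, region)$period  # linear value 0 everywhere
  s_flat <- summarize_curve(flat)
  expect_equal(s_flat$gap, 0)
  expect_equal(s_flat$argmin_label, s_flat$argmax_label)
  expect_equal(s_flat$argmin_label, flat$label[1])

  curve <- flat
  curve$mid <- c(300, 280, 290, 310)
  s <- summarize_curve(curve)
  expect_equal(s$argmin_label, curve$label[2])
  expect_equal(s$gap, 30)
  expect_equal(s$first, 300)
  expect_equal(s$last, 310)
})

test_that("summary equals a brute-force scan on a fitted curve", {
  tab <- simulate_microdata(quick_config(n = 25000))
  fit <- fit_from_table(tab)
  region <- bounds_to_ranges(fit$theta1, fit$theta2,
                             grid_search_age_bounds(fit))
  b <- net_effect_bands(fit, region)$age
  s <- summarize_curve(b)
  expect_equal(s$min, min(b$mid))
  expect_equal(s$gap, max(b$mid) - min(b$mid))
  expect_equal(s$argmin_label, b$label[which.min(b$mid)])
})

test_that("adding a constant to outcomes shifts curves, not bands or argmins", {
  tab <- simulate_microdata(quick_config(n = 25000))
  fit1 <- fit_from_table(tab)
  tab2 <- tab
  tab2$minutes_alone <- tab2$minutes_alone + 50
  fit2 <- fit_from_table(tab2)
  r1 <- bounds_to_ranges(fit1$theta1, fit1$theta2,
                         grid_search_age_bounds(fit1))
  r2 <- bounds_to_ranges(fit2$theta1, fit2$theta2,
                         grid_search_age_bounds(fit2))
  expect_equal(r2$alpha_range, r1$alpha_range, tolerance = 1e-8)
  b1 <- net_effect_bands(fit1, r1)
  b2 <- net_effect_bands(fit2, r2)
  for (dim in names(b1)) {
    expect_equal(b2[[dim]]$mid, b1[[dim]]$mid + 50, tolerance = 1e-6)
    expect_equal(b2[[dim]]$max - b2[[dim]]$min,
                 b1[[dim]]$max - b1[[dim]]$min, tolerance = 1e-6)
  }
  expect_equal(summarize_curve(b2$age)$argmin_label,
               summarize_curve(b1$age)$argmin_label)
})

test_that("noise-free mid curves reproduce the generating curve exactly", {
  cfg <- quick_config(n = 30000, noise_sd = 0)
  tab <- simulate_microdata(cfg)
  g <- assign_groups(tab)
  fit <- fit_from_table(tab)
  # generating net age curve on the realized basis at the generating alpha
  basis <- contrast_bases(g)$age
  gen <- 2.8 * basis$linear + 8.687 * basis$nonlinear$nl2 +
    0.5 * basis$nonlinear$nl3 + 0.3 * basis$nonlinear$nl4
  got <- net_total_curve(fit, "age", 2.8, include_intercept = FALSE)
  expect_equal(unname(got), gen, tolerance = 1e-7)
})
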