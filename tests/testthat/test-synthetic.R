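test_that("same seed and config give a bit-identical table", {
  cfg <- quick_config(n = 2000)
  a <- simulate_microdata(cfg)
  b <- simulate_microdata(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("degenerate config yields a constant outcome", {
  cfg <- sim_config(seed = 3, n_records = 500, grand_mean = 300,
                    linear_triple = c(0, 0, 0), age_nl = numeric(0),
                    period_nl = numeric(0), cohort_nl = numeric(0),
                    dow_effects = rep(0, 7), holiday_effect = 0,
                    noise_sd = 0)
  tab <- simulate_microdata(cfg)
  expect_equal(tab$minutes_alone, rep(300, 500))
})

test_that("cohort identity holds by construction and n_records is exact", {
  tab <- simulate_microdata(quick_config(n = 3000))
  expect_equal(nrow(tab), 3000)
  expect_equal(tab$cohort_year, tab$year - tab$age)
  expect_true(all(tab$weight > 0))
  expect_true(all(tab$age >= 15 & tab$age <= 79))
  expect_true(all(tab$year >= 2003 & tab$year <= 2022))
})

test_that("shifting the triple along the null direction leaves outcomes unchanged", {
  base <- c(2.8, 1.4, -1.0)
  a <- simulate_microdata(quick_config(n = 4000, linear_triple = base))
  for (delta in c(1, 5, 17)) {
    b <- simulate_microdata(quick_config(
      n = 4000, linear_triple = base + c(delta, -delta, delta)))
    expect_identical(b$minutes_alone, a$minutes_alone)
  }
})

test_that("true identifiable parameters are the theta sums", {
  expect_equal(
    true_identifiable_params(quick_config(linear_triple = c(2.8, 1.4, -1.0))),
    c(theta1 = 4.2, theta2 = 0.4))
  expect_equal(
    true_identifiable_params(quick_config(linear_triple = c(0, 0, 0))),
    c(theta1 = 0, theta2 = 0))
  expect_equal(
    true_identifiable_params(quick_config(linear_triple = c(5.15, 0, -0.03))),
    c(theta1 = 5.15, theta2 = -0.03))
})

test_that("nonlinear orders beyond the group count are a config error", {
  expect_error(sim_config(period_nl = c(1, 1, 1)), "nonlinear")
})

test_that("dow effects must sum to zero", {
  expect_error(sim_config(dow_effects = c(1, 0, 0, 0, 0, 0, 0)),
               "sum to zero")
})

test_that("expected group means: flat and pure-linear closed forms", {
  flat <- sim_config(seed = 1, n_records = 10, grand_mean = 250,
                     linear_triple = c(0, 0, 0), age_nl = numeric(0),
                     period_nl = numeric(0), cohort_nl = numeric(0),
                     dow_effects = rep(0, 7), holiday_effect = 0,
                     noise_sd = 1)
  m <- expected_group_means(flat)
  for (dim in c("age", "period", "cohort")) {
    expect_equal(m[[dim]]$mean, rep(250, nrow(m[[dim]])))
  }
  # pure linear age effect of 1 per group step, uniform cells:
  # age curve = grand_mean + centered group index
  lin <- sim_config(seed = 1, n_records = 10, grand_mean = 250,
                    linear_triple = c(1, 0, 0), age_nl = numeric(0),
                    period_nl = numeric(0), cohort_nl = numeric(0),
                    dow_effects = rep(0, 7), holiday_effect = 0,
                    noise_sd = 1)
  ml <- expected_group_means(lin)
  expect_equal(ml$age$mean, 250 + (0:12) - 6)
})

test_that("expected group means match an independent cell enumeration", {
  cfg <- quick_config(holiday_rate = 0.1)
  m <- expected_group_means(cfg)
  # brute-force oracle: rebuild the surface from scratch with plain loops
  ages <- 15:79; years <- 2003:2022
  grid <- expand.grid(age = ages, year = years)
  p <- rep(1 / nrow(grid), nrow(grid))
  ai <- (grid$age - 15) %/% 5; pi_ <- (grid$year - 2003) %/% 5
  ci <- pi_ - ai + 12
  cm <- rep(cfg$grand_mean + cfg$holiday_rate * cfg$holiday_effect,
            nrow(grid))
  cm <- cm + cfg$linear_triple[1] * (ai - sum(p * ai)) +
    cfg$linear_triple[2] * (pi_ - sum(p * pi_)) +
    cfg$linear_triple[3] * (ci - sum(p * ci))
  for (f in list(list(cfg$age_nl, ai, 13), list(cfg$period_nl, pi_, 4),
                 list(cfg$cohort_nl, ci, 16))) {
    W <- vapply(0:(f[[3]] - 1), function(k) sum(p[f[[2]] == k]),
                numeric(1))
    b <- weighted_orthogonal_contrasts(W, length(f[[1]]) + 1)
    curve <- rep(0, f[[3]])
    for (j in seq_along(f[[1]])) {
      curve <- curve + f[[1]][j] * b$nonlinear[[paste0("nl", j + 1)]]
    }
    cm <- cm + curve[f[[2]] + 1]
  }
  oracle_age <- vapply(0:12, function(k) {
    sum(p[ai == k] * cm[ai == k]) / sum(p[ai == k])
  }, numeric(1))
  expect_equal(m$age$mean, oracle_age, tolerance = 1e-12)
  oracle_cohort <- vapply(0:15, function(k) {
    sum(p[ci == k] * cm[ci == k]) / sum(p[ci == k])
  }, numeric(1))
  expect_equal(m$cohort$mean, oracle_cohort, tolerance = 1e-12)
})

test_that("simulated weighted group means track the closed-form surface", {
  # quadratic age effect only; compare realized weighted means per age
  # group with the population surface at n = 50,000 (3 SE slack)
  cfg <- sim_config(seed = 11, n_records = 50000,
                    linear_triple = c(0, 0, 0),
                    age_nl = c(8.687, 0, 0, 0), period_nl = numeric(0),
                    cohort_nl = numeric(0), dow_effects = rep(0, 7),
                    holiday_effect = 0, noise_sd = 60)
  tab <- simulate_microdata(cfg)
  g <- assign_groups(tab)
  m_exp <- expected_group_means(cfg)$age$mean
  for (k in 0:12) {
    rows <- g$age_idx == k
    m_obs <- sum(g$weight[rows] * g$minutes_alone[rows]) /
      sum(g$weight[rows])
    se <- 60 * sqrt(sum((g$weight[rows] / sum(g$weight[rows]))^2))
    expect_lt(abs(m_obs - m_exp[k + 1]), 3 * se + 1)
  }
})

test_that("clamped mode keeps outcomes inside the diary day", {
  cfg <- quick_config(n = 5000, noise_sd = 400, clamp_outcome = TRUE)
  tab <- simulate_microdata(cfg)
  expect_true(all(tab$minutes_alone >= 0 & tab$minutes_alone <= 1440))
})
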