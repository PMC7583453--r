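test_that("risk-score covariate relative risks multiply as published", {
  st <- blank_state(bmi = 28)
  expect_equal(thin_relative_risk(st), 1)  # reference profile

  st$stroke_history <- TRUE
  st$diabetes_diagnosed <- TRUE
  expect_equal(thin_relative_risk(st), 1.781 * 1.332)
  expect_equal(thin_relative_risk(st), 2.372, tolerance = 1e-3)

  st2 <- blank_state(bmi = 32)
  expect_equal(thin_relative_risk(st2),
               0.940^4 * 1.003^(32^2 - 28^2), tolerance = 1e-12)
  expect_equal(thin_relative_risk(st2), 1.602, tolerance = 1e-3)

  st3 <- blank_state(bmi = 28)
  st3$on_antihypertensives <- TRUE
  expect_equal(thin_relative_risk(st3), 0.876)
})

test_that("diagnosis probability is zero before 60 and hazard-based after", {
  p <- default_parameters()
  expect_equal(dementia_diagnosis_probability(blank_state(age = 55), p), 0)

  st <- blank_state(age = 72, bmi = 28)
  h0 <- 11 / 1000  # 70-74 band of the default table
  expect_equal(dementia_diagnosis_probability(st, p), 1 - exp(-h0))

  # extra relative risk multiplies the hazard
  expect_equal(dementia_diagnosis_probability(st, p, rr_extra = 0.5),
               1 - exp(-h0 * 0.5))

  # ages below the configured hazard table are a configuration error
  p2 <- p
  p2$dementia$incidence$baseline_hazard <-
    p$dementia$incidence$baseline_hazard[-1, ]
  expect_error(dementia_diagnosis_probability(blank_state(age = 61), p2),
               "baseline dementia hazard")
})

test_that("CAIDE relative risk responds only to threshold crossings", {
  prof <- list(bmi = 28, sbp = 130, total_chol = 5)
  expect_equal(caide_relative_risk(prof, prof, 1), 1)

  # control obese, treated non-obese: 1/OR
  expect_equal(
    caide_relative_risk(list(bmi = 31, sbp = 130, total_chol = 5),
                        list(bmi = 29.5, sbp = 130, total_chol = 5), 2),
    1 / 2.296)
  expect_equal(
    caide_relative_risk(list(bmi = 31, sbp = 130, total_chol = 5),
                        list(bmi = 29.5, sbp = 130, total_chol = 5), 2),
    0.4355, tolerance = 1e-3)

  # within-category changes do not alter the risk
  expect_equal(
    caide_relative_risk(list(bmi = 35, sbp = 150, total_chol = 7),
                        list(bmi = 33, sbp = 145, total_chol = 6.8), 1),
    1)

  # all three factors crossing compound
  expect_equal(
    caide_relative_risk(list(bmi = 31, sbp = 145, total_chol = 6.7),
                        list(bmi = 29, sbp = 138, total_chol = 6.4), 1),
    1 / (2.296 * 2.206 * 1.879))

  # beyond the 20-year horizon the effect is gone
  expect_equal(
    caide_relative_risk(list(bmi = 31, sbp = 145, total_chol = 6.7),
                        list(bmi = 29, sbp = 138, total_chol = 6.4), 21),
    1)
  expect_error(caide_relative_risk(prof, prof, 0), ">= 1")
})

test_that("CAIDE relative risk is at most 1 when treated values do not exceed control", {
  set.seed(5)
  for (i in 1:50) {
    control <- list(bmi = runif(1, 20, 40), sbp = runif(1, 110, 170),
                    total_chol = runif(1, 4, 8))
    red <- runif(3, 0, 3)
    treated <- list(bmi = control$bmi - red[1], sbp = control$sbp - red[2],
                    total_chol = control$total_chol - red[3] / 10)
    expect_lte(caide_relative_risk(control, treated, sample(1:20, 1)), 1)
  }
})

test_that("MMSE at diagnosis is gamma-shifted, bounded, and centred near 21", {
  p <- default_parameters()
  set.seed(9)
  draws <- sample_mmse_at_diagnosis(1e5, p)
  expect_true(all(draws >= 0 & draws <= 30))
  mu <- 30 - p$dementia$onset_mmse$shape * p$dementia$onset_mmse$scale
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se)
  expect_equal(mu, 21, tolerance = 1e-12)

  # degenerate scale: no heterogeneity, MMSE -> 30
  p0 <- p
  p0$dementia$onset_mmse$scale <- 1e-12
  expect_equal(sample_mmse_at_diagnosis(5, p0), rep(30, 5),
               tolerance = 1e-6)

  # quantile path for common random numbers is monotone in u
  u <- c(0.1, 0.5, 0.9)
  expect_true(all(diff(sample_mmse_at_diagnosis(params = p, u = u)) < 0))
})

test_that("MMSE progression rate matches hand-evaluated spline cases", {
  expect_equal(annual_mmse_change(30, 75, 0), -2.0727, tolerance = 1e-4)
  expect_equal(annual_mmse_change(5, 80, -2), -1.4816, tolerance = 1e-4)
  # full linear predictor, written out
  expect_equal(annual_mmse_change(30, 75, 0),
               -5.4663 - 0.4299 * 9 - 0.0042 * 9 + 0.1415 * 12 +
                 0.0747 * 75, tolerance = 1e-12)

  p0 <- default_parameters()
  for (nm in c("intercept", "b_pm1", "b_pm2", "b_pm3", "b_age",
               "b_prev_rate"))
    p0$dementia$progression[[nm]] <- 0
  expect_equal(annual_mmse_change(17, 70, -1, p0), 0)

  expect_error(annual_mmse_change(31, 75, 0), "\\[0, 30\\]")
  expect_error(annual_mmse_change(-1, 75, 0), "\\[0, 30\\]")
})

test_that("clamped MMSE trajectories stay within [0, 30] for simulated lifetimes", {
  p <- default_parameters()
  set.seed(13)
  for (i in 1:25) {
    mmse <- runif(1, 0, 30)
    age_dx <- runif(1, 60, 95)
    rate <- 0
    for (y in 1:40) {
      rate <- annual_mmse_change(mmse, age_dx, rate, p)
      mmse <- min(max(mmse + rate, 0), 30)
      expect_true(mmse >= 0 && mmse <= 30)
    }
  }
})

test_that("severity bands follow the published MMSE ranges", {
  b <- severity_band(c(22, 20, 9, 26, 28, 14, 15))
  expect_equal(b$cost_band,
               c("mild", "moderate", "severe", "mild", "none",
                 "moderate", "moderate"))
  expect_equal(b$utility_band,
               c("21-25", "15-20", "0-9", "none", "none", "10-14",
                 "15-20"))
  expect_error(severity_band(31), "\\[0, 30\\]")

  # multiplier table, including the undecremented 26+ region
  expect_equal(mmse_utility_multiplier(c(27, 22, 18, 12, 7)),
               c(1, 0.93, 0.725, 0.710, 0.478), ignore_attr = TRUE)
})
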