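cohort_small <- sample_cohort(400, seed = 31)

test_that("arm runs are deterministic under a fixed seed", {
  a <- run_arm(cohort_small, "dementia_only", "dpp", seed = 32)
  b <- run_arm(cohort_small, "dementia_only", "dpp", seed = 32)
  expect_identical(a$summary, b$summary)
  expect_identical(a$per_person, b$per_person)
  c <- run_arm(cohort_small, "dementia_only", "dpp", seed = 33)
  expect_false(identical(a$summary, c$summary))
  expect_error(run_arm(cohort_small[0, ], "dementia_only", "dpp"),
               "empty")
})

test_that("scenario gating switches the dementia machinery on and off", {
  none <- run_arm(cohort_small, "no_dementia", "dpp", seed = 32)
  only <- run_arm(cohort_small, "dementia_only", "dpp", seed = 32)
  reduced <- run_arm(cohort_small, "reduced_dementia_risk", "dpp",
                     seed = 32)
  ctrl_red <- run_arm(cohort_small, "reduced_dementia_risk", "control",
                      seed = 32)

  # no dementia: risk score never evaluated, no dementia costs or cases
  expect_equal(none$counters[["thin_evaluations"]], 0)
  expect_equal(none$counters[["caide_applications"]], 0)
  expect_equal(none$summary$mean_dementia_cost, 0)
  expect_equal(none$summary$per_1000[["dementia_diagnoses"]], 0)

  # dementia only: risk score active, direct risk reduction never applied
  expect_gt(only$counters[["thin_evaluations"]], 0)
  expect_equal(only$counters[["caide_applications"]], 0)

  # reduced risk: both active in the intervention arm, CAIDE never in control
  expect_gt(reduced$counters[["caide_applications"]], 0)
  expect_equal(ctrl_red$counters[["caide_applications"]], 0)
})

test_that("a null intervention produces exactly zero incremental results", {
  p <- null_intervention_params()
  cmp <- compare_arms(cohort_small, "reduced_dementia_risk", p, seed = 35)
  inc <- cmp$incremental
  expect_equal(inc$cost, 0)
  expect_equal(inc$qalys, 0)
  expect_equal(inc$net_benefit, 0)
  expect_equal(unname(inc$per_1000), c(0, 0, 0))
  expect_equal(max(abs(inc$yearly_cumulative_cost)), 0)
})

test_that("a fee-only intervention costs exactly the undiscounted fee", {
  p <- fee_only_params()
  cmp <- compare_arms(cohort_small, "no_dementia", p, seed = 36)
  expect_equal(cmp$incremental$cost, 270)
  expect_equal(cmp$incremental$qalys, 0)
  expect_equal(cmp$incremental$net_benefit, -270)
})

test_that("net benefit identity holds exactly on stored values", {
  cmp <- compare_arms(cohort_small, "dementia_only", seed = 37)
  expect_identical(cmp$incremental$net_benefit,
                   20000 * cmp$incremental$qalys - cmp$incremental$cost)
})

test_that("QALYs never exceed (discounted) life years", {
  for (sc in c("no_dementia", "dementia_only")) {
    res <- run_arm(cohort_small, sc, "control", seed = 38)
    expect_true(all(res$per_person$qalys <=
                      res$per_person$disc_life_years + 1e-9))
    expect_lte(res$summary$mean_qalys, res$summary$mean_disc_life_years)
    expect_lte(res$summary$mean_disc_life_years,
               res$summary$mean_life_years)
  }
})

test_that("the cost ledger reconciles against a brute-force re-walk of histories", {
  co <- sample_cohort(100, seed = 41)
  for (arm in c("control", "dpp")) {
    res <- run_arm(co, "reduced_dementia_risk", arm, seed = 42,
                   keep_history = TRUE)
    h <- res$history
    comp_cols <- c("diabetes", "cvd", "cancer", "osteoarthritis",
                   "depression", "chf", "dementia_health",
                   "dementia_social", "intervention")
    # independent re-walk: discount each year's face-value components
    # and utilities, then sum per individual
    for (col in comp_cols) {
      redone <- tapply(h[[col]] * h$discount_factor, h$id, sum)
      stored <- res$per_person[[col]]
      names(stored) <- res$per_person$id
      got <- rep(0, nrow(co))
      names(got) <- co$id
      got[names(redone)] <- redone
      expect_equal(unname(got[as.character(co$id)]), unname(stored),
                   tolerance = 1e-10)
    }
    redone_q <- tapply(h$utility * h$discount_factor, h$id, sum)
    got_q <- rep(0, nrow(co))
    names(got_q) <- co$id
    got_q[names(redone_q)] <- redone_q
    expect_equal(unname(got_q[as.character(res$per_person$id)]),
                 res$per_person$qalys, tolerance = 1e-10)
    # component tags partition the total cost
    total <- rowSums(res$per_person[, comp_cols])
    expect_equal(res$summary$mean_total_cost, mean(total),
                 tolerance = 1e-10)
    expect_equal(res$summary$mean_total_cost,
                 res$summary$mean_health_cost +
                   res$summary$mean_social_cost, tolerance = 1e-10)
  }
})

test_that("with shared draws the intervention cannot increase diabetes incidence", {
  co <- sample_cohort(4000, seed = 44)
  cmp <- compare_arms(co, "no_dementia", seed = 45)
  expect_lte(cmp$dpp$summary$per_1000[["diabetes_diagnoses"]],
             cmp$control$summary$per_1000[["diabetes_diagnoses"]])
})

test_that("the indirect channel cannot increase dementia incidence when survival is equalised", {
  # with every mortality hazard ratio at 1 the two arms share identical
  # death times, isolating the diabetes/stroke -> dementia channel
  p <- unit_hr_params()
  co <- sample_cohort(4000, seed = 46)
  cmp <- compare_arms(co, "dementia_only", p, seed = 47)
  expect_equal(cmp$incremental$life_years, 0)
  expect_lte(cmp$dpp$summary$per_1000[["dementia_diagnoses"]],
             cmp$control$summary$per_1000[["dementia_diagnoses"]])
})

test_that("subgroup stratification reduces to the whole-cohort comparison", {
  sg <- run_subgroups(cohort_small, "dementia_only", seed = 48,
                      age_bands = list(c(0, 200)), hba1c_bands = list())
  cmp <- compare_arms(cohort_small, "dementia_only", seed = 48)
  expect_equal(sg$inc_cost, cmp$incremental$cost)
  expect_equal(sg$inc_qalys, cmp$incremental$qalys)
  expect_equal(sg$net_benefit, cmp$incremental$net_benefit)
  expect_equal(sg$n, nrow(cohort_small))

  # an empty band is flagged, not an error
  sg2 <- run_subgroups(cohort_small, "dementia_only", seed = 48,
                       age_bands = list(c(0, 5)), hba1c_bands = list())
  expect_equal(sg2$n, 0L)
  expect_true(is.na(sg2$net_benefit))
})

test_that("a degenerate PSA collapses onto the deterministic result", {
  p <- zero_se_params()
  co <- sample_cohort(200, seed = 51)
  psa <- run_psa(co, "dementia_only", p, n_samples = 4,
                 lambda_grid = c(0, 20000, 40000), seed = 52)
  det <- compare_arms(co, "dementia_only", p, seed = 52)
  expect_equal(psa$samples$net_benefit,
               rep(det$incremental$net_benefit, 4))
  # step-function CEAC: every sample agrees, probabilities are 0 or 1
  expect_true(all(psa$ceac$probability %in% c(0, 1)))
})

test_that("PSA draws respect their distributional families", {
  set.seed(61)
  draws <- replicate(200, {
    p <- draw_psa_parameters()
    c(hr = p$dementia$mortality$hr_60_84,
      or = p$dementia$risk_reduction$or_obese,
      cost = p$economics$costs$dementia_health[["moderate"]],
      util = p$economics$utilities$mmse[["0-9"]],
      bmi = p$intervention$delta[["bmi"]])
  })
  expect_true(all(draws["hr", ] > 0))
  expect_true(all(draws["or", ] > 0))
  expect_true(all(draws["cost", ] >= 0))
  expect_true(all(draws["util", ] > 0 & draws["util", ] <= 1))
  expect_equal(mean(draws["bmi", ]), -1.47, tolerance = 0.05)
  expect_equal(sd(draws["bmi", ]), 0.156, tolerance = 0.05)
  expect_equal(mean(draws["cost", ]), 8293, tolerance = 8293 * 0.05)
})

test_that("the CEAC is a proper curve: lambda-0 limit and monotonicity", {
  samples <- data.frame(inc_cost = c(-50, 20, 100, -10),
                        inc_qalys = c(0.01, 0.02, 0.001, 0))
  ceac <- ceac_from_samples(samples, c(0, 1e4, 2e4, 1e5))
  expect_equal(ceac$probability[1], mean(samples$inc_cost < 0))
  # all dQALY >= 0: the curve cannot decrease in lambda
  expect_true(all(diff(ceac$probability) >= 0))
  expect_true(all(ceac$probability >= 0 & ceac$probability <= 1))
})

test_that("frozen CAIDE mode holds the year-1 risk reduction for the horizon", {
  # with survival equalised, the frozen mode (full year-1 offsets, all
  # 20 years) can only prevent diagnoses relative to the recompute mode
  p <- unit_hr_params()
  p$dementia$risk_reduction$mode <- "frozen"
  co <- sample_cohort(2000, seed = 55)
  frozen <- run_arm(co, "reduced_dementia_risk", "dpp", p, seed = 56)
  p$dementia$risk_reduction$mode <- "recompute"
  recomputed <- run_arm(co, "reduced_dementia_risk", "dpp", p, seed = 56)
  expect_gt(frozen$counters[["caide_applications"]], 0)
  expect_lte(frozen$summary$per_1000[["dementia_diagnoses"]],
             recomputed$summary$per_1000[["dementia_diagnoses"]])
})
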