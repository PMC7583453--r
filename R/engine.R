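## Named random-number streams, one matrix [individual x cycle] per event
## type, drawn in a fixed order from one seed so that both arms -- and all
## three scenarios -- see identical draws (common random numbers). Having
## a dedicated stream per event type means switching the dementia module
## on or off cannot perturb the cardiovascular or mortality draws.
make_draws <- function(n, n_years, seed) {
  set.seed(seed)
  z <- list()
  for (f in c("bmi", "sbp", "total_chol", "hdl_chol", "hba1c"))
    z[[f]] <- matrix(stats::rnorm(n * n_years), n, n_years)
  u <- list()
  for (e in c("diabetes", "cvd", "stroke", "cancer", "osteoarthritis",
              "depression", "chf", "dementia", "mmse_onset", "death"))
    u[[e]] <- matrix(stats::runif(n * n_years), n, n_years)
  list(z = z, u = u)
}

#' Simulate one arm of the cohort over its lifetime
#'
#' Runs the annual-cycle microsimulation for every individual until death
#' or the age cap: metabolic trajectories (with the intervention's
#' tapering offsets in the `dpp` arm), comorbid events, dementia
#' diagnosis/progression according to the scenario, mortality, and the
#' discounted cost and QALY ledgers. Scenario gating: `no_dementia`
#' disables the dementia machinery entirely; `dementia_only` models
#' dementia but applies no direct intervention effect on its incidence;
#' `reduced_dementia_risk` additionally applies the CAIDE-derived
#' relative risk in the intervention arm. Each individual carries both
#' the counterfactual and the on-treatment factor values, so control and
#' intervention arms run with identical random streams and differ only
#' through the intervention offsets.
#'
#' @param cohort Cohort data.frame from [sample_cohort()] or
#'   [read_cohort()].
#' @param scenario One of `"no_dementia"`, `"dementia_only"`,
#'   `"reduced_dementia_risk"`.
#' @param arm `"control"` or `"dpp"`.
#' @param params Full parameter list.
#' @param seed Integer seed for the event streams.
#' @param age_cap Simulate to death or this age (default 100).
#' @param keep_history Keep the per-person per-year accrual ledger
#'   (memory-heavy; intended for audits on small cohorts).
#' @return An object of class `dpp_arm_result`: per-person discounted
#'   means (`summary`), per-1000 lifetime first-event counts, the mean
#'   discounted cost accrued in each model year (`yearly_cost`),
#'   instrumentation `counters` (risk-score evaluations, CAIDE
#'   applications), the per-person ledger (`per_person`) and, optionally,
#'   the full `history`.
#' @export
run_arm <- function(cohort,
                    scenario = c("no_dementia", "dementia_only",
                                 "reduced_dementia_risk"),
                    arm = c("control", "dpp"),
                    params = default_parameters(), seed = 1L,
                    age_cap = 100, keep_history = FALSE) {
  scenario <- match.arg(scenario)
  arm <- match.arg(arm)
  n <- nrow(cohort)
  if (n == 0) stop("cohort is empty", call. = FALSE)
  if (age_cap < max(cohort$age))
    stop("age_cap must be at least the oldest cohort age", call. = FALSE)

  n_years <- as.integer(floor(age_cap - min(cohort$age))) + 1L
  draws <- make_draws(n, n_years, seed)
  econ <- params$economics
  r <- econ$discount_rate
  iv <- params$intervention
  rr_cfg <- params$dementia$risk_reduction
  factors <- c("bmi", "sbp", "total_chol", "hdl_chol", "hba1c")

  cf <- list(bmi = cohort$bmi, sbp = cohort$sbp,
             total_chol = cohort$total_chol, hdl_chol = cohort$hdl_chol,
             hba1c = cohort$hba1c)
  st <- list(
    age = cohort$age, sex = cohort$sex, smoking = cohort$smoking,
    on_antihypertensives = cohort$on_antihypertensives,
    anxiety = cohort$anxiety, nsaid_use = cohort$nsaid_use,
    baseline_eq5d = cohort$baseline_eq5d,
    diabetes_diagnosed = cohort$diabetes_diagnosed,
    cvd_history = cohort$cvd_history,
    stroke_history = cohort$stroke_history,
    chf = cohort$chf, cancer = cohort$cancer,
    osteoarthritis = cohort$osteoarthritis,
    depression = cohort$depression,
    dementia_diagnosed = cohort$dementia_diagnosed,
    mmse = rep(NA_real_, n)
  )
  alive <- rep(TRUE, n)
  age_dx <- rep(NA_real_, n)
  prev_rate <- rep(0, n)
  rr_frozen <- NULL

  comp_names <- cost_component_names()
  comp_acc <- matrix(0, n, length(comp_names),
                     dimnames = list(NULL, comp_names))
  qaly <- life_years <- disc_life_years <- numeric(n)
  yearly_cost <- numeric(n_years)
  counters <- c(thin_evaluations = 0, caide_applications = 0)
  history <- if (keep_history) vector("list", n_years) else NULL

  for (y in seq_len(n_years)) {
    age <- cohort$age + (y - 1)
    active <- alive & age <= age_cap
    if (!any(active)) break

    if (y > 1) {
      for (f in factors)
        cf[[f]] <- project_factor(cf[[f]], age, f, params,
                                  draws$z[[f]][, y])
    }
    treated <- cf
    if (arm == "dpp" && y <= iv$duration) {
      for (f in names(iv$delta)) {
        off <- intervention_offset(iv$delta[[f]], y, iv$duration)
        rng <- params$trajectories$range[[f]]
        treated[[f]] <- clamp(treated[[f]] + off, rng[1], rng[2])
      }
    }
    st$age <- age
    st$bmi <- treated$bmi
    st$sbp <- treated$sbp
    st$total_chol <- treated$total_chol
    st$hdl_chol <- treated$hdl_chol
    st$hba1c <- treated$hba1c

    u_y <- lapply(draws$u[c("diabetes", "cvd", "stroke", "cancer",
                            "osteoarthritis", "depression", "chf")],
                  function(m) m[, y])
    ev <- simulate_events(st, params, u_y)
    for (fl in c("diabetes_diagnosed", "cvd_history", "stroke_history",
                 "cancer", "osteoarthritis", "depression", "chf"))
      st[[fl]] <- st[[fl]] | (ev[[fl]] & active)
    st$cvd_event_this_year <- ev$cvd_event_this_year & active

    st$dementia_new <- rep(FALSE, n)
    if (scenario != "no_dementia") {
      prog <- active & st$dementia_diagnosed
      if (any(prog)) {  # decline applies from the cycle after diagnosis
        rate <- annual_mmse_change(st$mmse[prog], age_dx[prog],
                                   prev_rate[prog], params)
        st$mmse[prog] <- clamp(st$mmse[prog] + rate, 0, 30)
        prev_rate[prog] <- rate
      }
      direct <- scenario == "reduced_dementia_risk" && arm == "dpp" &&
        y <= rr_cfg$horizon
      if (direct && rr_cfg$mode == "frozen" && y == 1)
        rr_frozen <- caide_relative_risk(cf, treated, 1, params)
      elig <- active & !st$dementia_diagnosed &
        age >= params$dementia$incidence$min_age
      if (any(elig)) {
        counters[["thin_evaluations"]] <-
          counters[["thin_evaluations"]] + sum(elig)
        rr_extra <- 1
        if (direct) {
          rr_extra <- if (rr_cfg$mode == "frozen") rr_frozen
                      else caide_relative_risk(cf, treated, y, params)
          counters[["caide_applications"]] <-
            counters[["caide_applications"]] + sum(elig)
        }
        # the diagnosis risk score is evaluated on counterfactual
        # metabolic values: the intervention's metabolic effect reaches
        # dementia incidence only through the diabetes and stroke flags
        # (indirect) and, in the reduced-risk scenario, the CAIDE
        # relative risk (direct)
        st_thin <- st
        st_thin$bmi <- cf$bmi
        p_dem <- dementia_diagnosis_probability(st_thin, params, rr_extra)
        newdx <- elig & draws$u$dementia[, y] < p_dem
        if (any(newdx)) {
          st$mmse[newdx] <- sample_mmse_at_diagnosis(
            params = params, u = draws$u$mmse_onset[newdx, y])
          st$dementia_diagnosed[newdx] <- TRUE
          st$dementia_new <- newdx
          age_dx[newdx] <- age[newdx]
          prev_rate[newdx] <- 0
        }
      }
    }

    q_death <- annual_death_probability(st, params)
    died <- active & draws$u$death[, y] < q_death
    alive[died] <- FALSE
    accrue <- if (isTRUE(econ$accrue_death_year)) active else active & alive

    comp <- annual_costs(st, arm, y, params)
    util <- annual_utility(st, params)
    dfac <- (1 + r)^-(y - 1)

    accrued <- matrix(0, n, length(comp_names),
                      dimnames = list(NULL, comp_names))
    if (any(accrue))
      accrued[accrue, ] <- comp[accrue, , drop = FALSE] * dfac
    # the intervention fee is paid up front, so it is charged even to
    # individuals who die within the first cycle
    paid_anyway <- arm == "dpp" && y == 1 && !isTRUE(econ$accrue_death_year)
    if (paid_anyway) {
      extra <- active & !accrue
      accrued[extra, "intervention"] <- iv$cost * dfac
    }
    comp_acc <- comp_acc + accrued
    qaly[accrue] <- qaly[accrue] + util[accrue] * dfac
    life_years[accrue] <- life_years[accrue] + 1
    disc_life_years[accrue] <- disc_life_years[accrue] + dfac
    yearly_cost[y] <- sum(accrued) / n

    if (keep_history) {
      rows <- which(accrue | rowSums(accrued) > 0)
      if (length(rows)) {
        h <- data.frame(id = cohort$id[rows], year = y, age = age[rows],
                        accruing = accrue[rows], utility = util[rows],
                        discount_factor = dfac)
        # face-value (undiscounted) amounts actually accrued this cycle
        h <- cbind(h, as.data.frame(accrued[rows, , drop = FALSE] / dfac))
        h$utility[!h$accruing] <- 0
        history[[y]] <- h
      }
    }
  }

  per_person <- data.frame(id = cohort$id, as.data.frame(comp_acc),
                           qalys = qaly, life_years = life_years,
                           disc_life_years = disc_life_years)
  total_cost <- rowSums(comp_acc)
  health_cost <- total_cost - comp_acc[, "dementia_social"]
  res <- list(
    scenario = scenario, arm = arm, n = n, seed = seed,
    summary = list(
      mean_total_cost = mean(total_cost),
      mean_health_cost = mean(health_cost),
      mean_social_cost = mean(comp_acc[, "dementia_social"]),
      mean_dementia_cost = mean(comp_acc[, "dementia_health"] +
                                  comp_acc[, "dementia_social"]),
      mean_cvd_cost = mean(comp_acc[, "cvd"]),
      mean_intervention_cost = mean(comp_acc[, "intervention"]),
      mean_qalys = mean(qaly),
      mean_life_years = mean(life_years),
      mean_disc_life_years = mean(disc_life_years),
      per_1000 = c(
        diabetes_diagnoses = 1000 * sum(st$diabetes_diagnosed) / n,
        cvd_events = 1000 * sum(st$cvd_history) / n,
        dementia_diagnoses = 1000 * sum(st$dementia_diagnosed) / n
      )
    ),
    yearly_cost = yearly_cost,
    counters = counters,
    per_person = per_person
  )
  if (keep_history) res$history <- do.call(rbind, history)
  class(res) <- "dpp_arm_result"
  res
}

#' Two-arm comparison with common random numbers
#'
#' Runs the control and intervention arms on the same cohort with
#' identical random streams and returns the incremental results:
#' differences of every summary quantity (intervention minus control),
#' the incremental net monetary benefit at the configured willingness to
#' pay (computed on the stored, unrounded values), the per-1000
#' differences in lifetime event counts, and the cumulative incremental
#' cost by model year.
#'
#' @inheritParams run_arm
#' @return An object of class `dpp_comparison` with elements `control`,
#'   `dpp` (the two [run_arm()] results) and `incremental`.
#' @export
compare_arms <- function(cohort,
                         scenario = c("no_dementia", "dementia_only",
                                      "reduced_dementia_risk"),
                         params = default_parameters(), seed = 1L,
                         age_cap = 100, keep_history = FALSE) {
  scenario <- match.arg(scenario)
  ctrl <- run_arm(cohort, scenario, "control", params, seed, age_cap,
                  keep_history)
  dpp <- run_arm(cohort, scenario, "dpp", params, seed, age_cap,
                 keep_history)
  sc <- ctrl$summary
  sd_ <- dpp$summary
  inc <- list(
    cost = sd_$mean_total_cost - sc$mean_total_cost,
    health_cost = sd_$mean_health_cost - sc$mean_health_cost,
    social_cost = sd_$mean_social_cost - sc$mean_social_cost,
    dementia_cost = sd_$mean_dementia_cost - sc$mean_dementia_cost,
    cvd_cost = sd_$mean_cvd_cost - sc$mean_cvd_cost,
    qalys = sd_$mean_qalys - sc$mean_qalys,
    life_years = sd_$mean_life_years - sc$mean_life_years,
    per_1000 = sd_$per_1000 - sc$per_1000,
    yearly_cumulative_cost = cumsum(dpp$yearly_cost - ctrl$yearly_cost)
  )
  inc$net_benefit <- incremental_net_benefit(inc$qalys, inc$cost,
                                             params$economics$lambda)
  out <- list(scenario = scenario, n = ctrl$n, seed = seed,
              control = ctrl, dpp = dpp, incremental = inc,
              lambda = params$economics$lambda)
  class(out) <- "dpp_comparison"
  out
}

#' @export
print.dpp_arm_result <- function(x, ...) {
  cat("Microsimulation arm result\n")
  cat(sprintf("  scenario: %s, arm: %s, n = %d, seed = %d\n",
              x$scenario, x$arm, x$n, x$seed))
  s <- x$summary
  cat(sprintf("  discounted cost/person: %.0f (health %.0f, social %.0f)\n",
              s$mean_total_cost, s$mean_health_cost, s$mean_social_cost))
  cat(sprintf("  discounted QALYs/person: %.3f; life years/person: %.2f\n",
              s$mean_qalys, s$mean_life_years))
  cat(sprintf(
    "  per 1000: %.0f diabetes, %.0f CVD, %.0f dementia diagnoses\n",
    s$per_1000[["diabetes_diagnoses"]], s$per_1000[["cvd_events"]],
    s$per_1000[["dementia_diagnoses"]]))
  invisible(x)
}

#' @export
print.dpp_comparison <- function(x, ...) {
  cat("Incremental results (intervention - control)\n")
  cat(sprintf("  scenario: %s, n = %d\n", x$scenario, x$n))
  inc <- x$incremental
  cat(sprintf("  incremental cost/person: %.1f GBP\n", inc$cost))
  cat(sprintf("  incremental QALYs/person: %.4f\n", inc$qalys))
  cat(sprintf("  incremental net benefit at %.0f GBP/QALY: %.1f GBP\n",
              x$lambda, inc$net_benefit))
  invisible(x)
}
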