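#' Convert an annual hazard to an annual probability
#'
#' `p = 1 - exp(-h)` for a constant hazard `h` over one cycle.
#'
#' @param h Non-negative annual hazard(s).
#' @return Probability in `[0, 1)`.
#' @export
hazard_to_probability <- function(h) {
  if (any(h < 0)) stop("hazard must be >= 0", call. = FALSE)
  1 - exp(-h)
}

#' @rdname hazard_to_probability
#' @param p Probability in `[0, 1)`.
#' @export
probability_to_hazard <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)", call. = FALSE)
  -log(1 - p)
}

#' Baseline annual mortality
#'
#' Baseline probability of death `q(age, sex)`. If a lifetable
#' data.frame (`age`, `q_male`, `q_female`) is configured it is used with
#' constant extrapolation at the ends; otherwise a synthetic
#' Gompertz-Makeham law `q = min(q_cap, a + exp(b + c*age))` is applied,
#' scaled for males by a configurable excess and capped at `q_cap`.
#'
#' @param age Age(s) in years.
#' @param sex Character vector, `"male"` or `"female"`.
#' @param params Full parameter list or the `comorbidity$mortality` block.
#' @return Baseline annual death probability, same length as `age`.
#' @export
baseline_mortality <- function(age, sex, params = default_parameters()) {
  mort <- if (!is.null(params$comorbidity)) params$comorbidity$mortality
          else params
  lt <- mort$lifetable
  if (!is.null(lt)) {
    idx <- findInterval(age, lt$age, all.inside = TRUE)
    q <- ifelse(sex == "male", lt$q_male[idx], lt$q_female[idx])
  } else {
    mk <- mort$makeham
    q <- mk[["a"]] + exp(mk[["b"]] + mk[["c"]] * age)
    q <- ifelse(sex == "male", q * mort$male_excess, q)
  }
  pmin(q, mort$q_cap)
}

#' Apply condition hazard ratios to a baseline death probability
#'
#' Converts `q` to a hazard, multiplies by the hazard ratio of each
#' condition the individual has (cardiovascular history, cancer, diagnosed
#' diabetes, and -- after dementia diagnosis -- the age-banded dementia
#' mortality hazard ratio: 4.54 at ages 60-84, 2.77 at 85+), and converts
#' back: `p = 1 - exp(-(-log(1 - q)) * HR_total)`.
#'
#' @param q Baseline annual death probability in `[0, 1)`.
#' @param state One-row-per-individual data.frame (or list of vectors)
#'   with `age`, `cvd_history`, `cancer`, `diabetes_diagnosed`,
#'   `dementia_diagnosed`.
#' @param params Full parameter list.
#' @return Adjusted annual death probability.
#' @export
#' @examples
#' st <- data.frame(age = 70, cvd_history = FALSE, cancer = FALSE,
#'                  diabetes_diagnosed = FALSE, dementia_diagnosed = TRUE)
#' apply_mortality_hrs(0.02, st)  # ~0.0876
apply_mortality_hrs <- function(q, state, params = default_parameters()) {
  mort <- params$comorbidity$mortality
  dem <- params$dementia$mortality
  h <- probability_to_hazard(q)
  hr <- rep(1, length(state$age))
  hr <- hr * ifelse(state$cvd_history, mort$hr_cvd, 1)
  hr <- hr * ifelse(state$cancer, mort$hr_cancer, 1)
  hr <- hr * ifelse(state$diabetes_diagnosed, mort$hr_diabetes, 1)
  dem_hr <- ifelse(state$age >= 85, dem$hr_85_plus,
                   ifelse(state$age >= 60, dem$hr_60_84, 1))
  hr <- hr * ifelse(state$dementia_diagnosed, dem_hr, 1)
  1 - exp(-h * hr)
}

#' Annual probability of death
#'
#' Combines the baseline lifetable with the condition hazard ratios via
#' [baseline_mortality()] and [apply_mortality_hrs()].
#'
#' @param state Individual state data.frame (needs `age`, `sex` and the
#'   condition flags).
#' @param params Full parameter list.
#' @return Annual death probability per individual.
#' @export
annual_death_probability <- function(state, params = default_parameters()) {
  q <- baseline_mortality(state$age, state$sex, params)
  apply_mortality_hrs(q, state, params)
}

#' Annual cardiovascular event hazard
#'
#' Simplified single log-linear hazard on age (per decade), SBP (per
#' 10 mm Hg), sex, current smoking, diagnosed diabetes and the
#' total:HDL cholesterol ratio, centred at the cohort-average profile.
#' A calibration stand-in for the risk-engine equations of the published
#' model, not an estimate.
#'
#' @param state Individual state (needs `age`, `sbp`, `sex`, `smoking`,
#'   `diabetes_diagnosed`, `total_chol`, `hdl_chol`).
#' @param params Full parameter list or its `comorbidity` block.
#' @return Annual hazard per individual.
#' @export
cvd_hazard <- function(state, params = default_parameters()) {
  cm <- if (!is.null(params$comorbidity)) params$comorbidity else params
  cv <- cm$cvd
  lp <- cv$log_baseline +
    cv$b_age_decade * (state$age - cv$age_ref) / 10 +
    cv$b_sbp_10 * (state$sbp - cv$sbp_ref) / 10 +
    cv$b_male * (state$sex == "male") +
    cv$b_smoker * (state$smoking == "current") +
    cv$b_diabetes * state$diabetes_diagnosed +
    cv$b_tc_hdl * (state$total_chol / state$hdl_chol - cv$tc_hdl_ref)
  exp(lp)
}

#' Simulate one cycle of comorbid events
#'
#' Applies the annual event rules to every individual: diabetes is
#' diagnosed when HbA1c is at or above the diagnostic threshold and the
#' detection draw succeeds; a cardiovascular event occurs with the
#' probability implied by [cvd_hazard()] and is a stroke with probability
#' `stroke_fraction`; cancer, osteoarthritis, depression and heart
#' failure follow their age-dependent incidence rules. All disease flags
#' are absorbing.
#'
#' @param state Individual state data.frame / list of vectors.
#' @param params Full parameter list.
#' @param uniforms Named list of uniform draws (`diabetes`, `cvd`,
#'   `stroke`, `cancer`, `osteoarthritis`, `depression`, `chf`), each the
#'   same length as the state.
#' @return The state with updated flags plus `cvd_event_this_year`.
#' @export
simulate_events <- function(state, params = default_parameters(), uniforms) {
  cm <- params$comorbidity

  newly_diabetic <- !state$diabetes_diagnosed &
    state$hba1c >= cm$diabetes$hba1c_threshold &
    uniforms$diabetes < cm$diabetes$detection_prob
  state$diabetes_diagnosed <- state$diabetes_diagnosed | newly_diabetic

  p_cvd <- hazard_to_probability(cvd_hazard(state, params))
  event <- uniforms$cvd < p_cvd
  state$cvd_event_this_year <- event
  state$cvd_history <- state$cvd_history | event
  stroke <- event & uniforms$stroke < cm$stroke_fraction
  state$stroke_history <- state$stroke_history | stroke

  for (cond in c("cancer", "osteoarthritis", "depression", "chf")) {
    co <- cm$incidence[[cond]]
    p <- hazard_to_probability(exp(co[["intercept"]] +
                                     co[["age_slope"]] * state$age))
    state[[cond]] <- state[[cond]] | (uniforms[[cond]] < p)
  }
  state
}

#' Read a lifetable from CSV
#'
#' Expects columns `age`, `q_male`, `q_female` with annual death
#' probabilities; the table plugs into
#' `params$comorbidity$mortality$lifetable`.
#'
#' @param path CSV file path.
#' @return A data.frame sorted by age.
#' @export
read_lifetable <- function(path) {
  lt <- utils::read.csv(path)
  required <- c("age", "q_male", "q_female")
  if (!all(required %in% names(lt)))
    stop("lifetable needs columns age, q_male, q_female", call. = FALSE)
  lt[order(lt$age), , drop = FALSE]
}
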