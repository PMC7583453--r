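#' Age-related utility multiplier
#'
#' Smooth decrement applied to baseline utility as individuals age:
#' `max(floor, 1 - coef * max(0, age - knot)^2)` with defaults
#' `coef = 2e-4`, `knot = 40`, `floor = 0.4`. A configurable stand-in for
#' published age-decrement tariffs.
#'
#' @param age Age(s) in years.
#' @param params Full parameter list or the `economics$utilities` block.
#' @return Multiplier in `[floor, 1]`.
#' @export
age_utility_multiplier <- function(age, params = default_parameters()) {
  ut <- if (!is.null(params$economics)) params$economics$utilities else params
  am <- ut$age_mult
  pmax(am$floor, 1 - am$coef * pmax(0, age - am$knot)^2)
}

#' Annual utility of an individual
#'
#' Multiplicative utility model: baseline EQ-5D times the age multiplier
#' times one multiplier per active condition (cardiovascular history,
#' cancer, osteoarthritis, depression, heart failure, diagnosed
#' diabetes) times the MMSE-band multiplier after dementia diagnosis.
#' Multiplicative decrements avoid double counting quality-of-life loss
#' under multimorbidity; the result never exceeds the baseline-times-age
#' term.
#'
#' @param state Individual state (needs `baseline_eq5d`, `age`, the
#'   condition flags and, for diagnosed individuals, `mmse`).
#' @param params Full parameter list.
#' @return Utility per individual (<= 1 per year lived).
#' @export
#' @examples
#' st <- data.frame(baseline_eq5d = 0.9, age = 40, cvd_history = FALSE,
#'                  cancer = FALSE, osteoarthritis = FALSE,
#'                  depression = FALSE, chf = FALSE,
#'                  diabetes_diagnosed = FALSE, dementia_diagnosed = TRUE,
#'                  mmse = 7)
#' annual_utility(st)  # 0.9 * 0.478
annual_utility <- function(state, params = default_parameters()) {
  ut <- params$economics$utilities
  u <- state$baseline_eq5d * age_utility_multiplier(state$age, params)
  cm <- ut$condition
  u <- u * ifelse(state$cvd_history, cm[["cvd"]], 1)
  u <- u * ifelse(state$cancer, cm[["cancer"]], 1)
  u <- u * ifelse(state$osteoarthritis, cm[["osteoarthritis"]], 1)
  u <- u * ifelse(state$depression, cm[["depression"]], 1)
  u <- u * ifelse(state$chf, cm[["chf"]], 1)
  u <- u * ifelse(state$diabetes_diagnosed, cm[["diabetes"]], 1)
  dem <- state$dementia_diagnosed
  if (any(dem)) {
    mult <- rep(1, length(u))
    mult[dem] <- mmse_utility_multiplier(state$mmse[dem], params)
    u <- u * mult
  }
  u
}

## canonical cost component order used by the ledger
cost_component_names <- function() {
  c("diabetes", "cvd", "cancer", "osteoarthritis", "depression", "chf",
    "dementia_health", "dementia_social", "intervention")
}

#' Annual cost components of an individual
#'
#' Additive cost ledger for one cycle, tagged by component: diabetes,
#' cardiovascular (event-year vs history-year rates), cancer,
#' osteoarthritis, depression, heart failure, dementia health and social
#' care by severity band (mild/moderate/severe), a one-off dementia
#' diagnosis cost (default 0) and the intervention cost (GBP 270, year 1
#' of the intervention arm only). Aggregates: health care cost is every
#' component except dementia social care; social care cost is the
#' dementia social component. Costs are in 2016-2017 GBP.
#'
#' @param state Individual state.
#' @param arm `"control"` or `"dpp"`.
#' @param year Model cycle (year 1 carries the intervention cost).
#' @param params Full parameter list.
#' @return Numeric matrix, one row per individual, one column per
#'   component (see `attr(, "aggregates")` note in Details).
#' @export
#' @examples
#' st <- data.frame(diabetes_diagnosed = FALSE, cvd_history = FALSE,
#'                  cvd_event_this_year = FALSE, cancer = FALSE,
#'                  osteoarthritis = FALSE, depression = FALSE,
#'                  chf = FALSE, dementia_diagnosed = TRUE,
#'                  dementia_new = FALSE, mmse = 15)
#' rowSums(annual_costs(st, "control", 2))  # moderate dementia year
annual_costs <- function(state, arm = c("control", "dpp"), year = 1,
                         params = default_parameters()) {
  arm <- match.arg(arm)
  cc <- params$economics$costs
  n <- length(state$dementia_diagnosed)
  comp <- matrix(0, n, length(cost_component_names()),
                 dimnames = list(NULL, cost_component_names()))
  comp[, "diabetes"] <- cc$diabetes * state$diabetes_diagnosed
  ev <- state$cvd_event_this_year
  if (is.null(ev)) ev <- rep(FALSE, n)
  comp[, "cvd"] <- cc$cvd_event * ev +
    cc$cvd_history * (state$cvd_history & !ev)
  comp[, "cancer"] <- cc$cancer * state$cancer
  comp[, "osteoarthritis"] <- cc$osteoarthritis * state$osteoarthritis
  comp[, "depression"] <- cc$depression * state$depression
  comp[, "chf"] <- cc$chf * state$chf

  dem <- state$dementia_diagnosed
  if (any(dem)) {
    band <- severity_band(state$mmse[dem])$cost_band
    hc <- sc <- numeric(sum(dem))
    priced <- band != "none"
    hc[priced] <- cc$dementia_health[band[priced]]
    sc[priced] <- cc$dementia_social[band[priced]]
    comp[dem, "dementia_health"] <- hc
    comp[dem, "dementia_social"] <- sc
    newdx <- state$dementia_new
    if (!is.null(newdx) && any(newdx))
      comp[newdx, "dementia_health"] <-
        comp[newdx, "dementia_health"] + params$dementia$diagnosis_cost
  }
  if (arm == "dpp" && year == 1)
    comp[, "intervention"] <- params$intervention$cost
  comp
}

#' Discount a value to present terms
#'
#' `value / (1 + r)^t` with cycle index `t` starting at 0, so the first
#' model year is undiscounted.
#'
#' @param value Cost (GBP) or QALY amount(s).
#' @param t Cycle index (0 for the first year).
#' @param r Annual discount rate (default 0.035).
#' @return Discounted value(s).
#' @export
#' @examples
#' discount(100, 2)  # 93.351
discount <- function(value, t, r = 0.035) {
  if (r < 0) stop("discount rate must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  value / (1 + r)^t
}

#' Incremental net monetary benefit
#'
#' `INB = lambda * delta_QALY - delta_cost`; positive values mean the
#' intervention is cost-effective at willingness to pay `lambda`.
#'
#' @param delta_qaly Incremental QALYs per person.
#' @param delta_cost Incremental cost per person (GBP).
#' @param lambda Willingness to pay per QALY (default GBP 20,000).
#' @return Net monetary benefit in GBP.
#' @export
#' @examples
#' incremental_net_benefit(0.0433, -121)  # 987
incremental_net_benefit <- function(delta_qaly, delta_cost, lambda = 20000) {
  lambda * delta_qaly - delta_cost
}
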