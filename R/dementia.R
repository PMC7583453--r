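#' Covariate relative risk of dementia diagnosis
#'
#' Multiplicative relative risk from the primary-care (THIN-style) risk
#' score: per-unit BMI and BMI-squared terms centred at a reference BMI,
#' plus hazard ratios for antihypertensive use, stroke history and
#' diagnosed diabetes, and optional extra covariate hazard ratios
#' (depression, anxiety, NSAID use, smoking, sex) defaulting to 1:
#' `RR = hr_bmi^(bmi - ref) * hr_bmi_sq^(bmi^2 - ref^2) * hr_aht^[aht] *
#' hr_stroke^[stroke] * hr_diabetes^[diabetes] * prod(extra HRs)`.
#'
#' @param state Individual state (needs `bmi`, `on_antihypertensives`,
#'   `stroke_history`, `diabetes_diagnosed`; optionally `depression`,
#'   `anxiety`, `nsaid_use`, `smoking`, `sex` for the extra HRs).
#' @param params Full parameter list or the `dementia$incidence` block.
#' @return Relative risk per individual (positive).
#' @export
#' @examples
#' st <- data.frame(bmi = 28, on_antihypertensives = FALSE,
#'                  stroke_history = TRUE, diabetes_diagnosed = TRUE)
#' thin_relative_risk(st)  # 1.781 * 1.332
thin_relative_risk <- function(state, params = default_parameters()) {
  inc <- if (!is.null(params$dementia)) params$dementia$incidence else params
  ref <- inc$bmi_reference
  rr <- inc$hr_bmi^(state$bmi - ref) *
    inc$hr_bmi_sq^(state$bmi^2 - ref^2) *
    inc$hr_antihypertensives^as.numeric(state$on_antihypertensives) *
    inc$hr_stroke^as.numeric(state$stroke_history) *
    inc$hr_diabetes^as.numeric(state$diabetes_diagnosed)
  chr <- inc$covariate_hr
  if (!is.null(chr)) {
    if (!is.null(state$depression))
      rr <- rr * chr[["depression"]]^as.numeric(state$depression)
    if (!is.null(state$anxiety))
      rr <- rr * chr[["anxiety"]]^as.numeric(state$anxiety)
    if (!is.null(state$nsaid_use))
      rr <- rr * chr[["nsaid"]]^as.numeric(state$nsaid_use)
    if (!is.null(state$smoking))
      rr <- rr * chr[["current_smoker"]]^as.numeric(state$smoking == "current")
    if (!is.null(state$sex))
      rr <- rr * chr[["male"]]^as.numeric(state$sex == "male")
  }
  rr
}

#' Annual probability of dementia diagnosis
#'
#' Zero below age 60. From 60 onwards the age-banded baseline hazard
#' (per 1000 person-years, a configurable table) is multiplied by the
#' covariate relative risk from [thin_relative_risk()] and an optional
#' extra relative risk (the direct risk-reduction scenario), then
#' converted to a probability: `p = 1 - exp(-h0 * RR * rr_extra)`.
#'
#' @param state Individual state (needs `age` plus the
#'   [thin_relative_risk()] columns).
#' @param params Full parameter list.
#' @param rr_extra Optional extra hazard multiplier (scalar or vector),
#'   e.g. the CAIDE-derived intervention relative risk.
#' @return Annual diagnosis probability per individual.
#' @export
dementia_diagnosis_probability <- function(state,
                                           params = default_parameters(),
                                           rr_extra = 1) {
  inc <- params$dementia$incidence
  tab <- inc$baseline_hazard
  p <- numeric(length(state$age))
  old <- state$age >= inc$min_age
  if (any(old)) {
    idx <- findInterval(state$age[old], tab$age_low)
    if (any(idx < 1))
      stop("no baseline dementia hazard for some ages", call. = FALSE)
    h0 <- tab$rate_per_1000py[idx] / 1000
    rr <- thin_relative_risk(subset_state(state, old), params)
    re <- if (length(rr_extra) == 1) rr_extra else rr_extra[old]
    p[old] <- 1 - exp(-h0 * rr * re)
  }
  p
}

#' Intervention relative risk of dementia from CAIDE risk factors
#'
#' Compares the taper-adjusted treated and counterfactual profiles on the
#' three CAIDE dichotomous factors -- obesity (BMI > 30 kg/m2),
#' hypertension (SBP > 140 mm Hg) and hyperlipidaemia (total cholesterol
#' > 6.5 mmol/L) -- and applies each factor's odds ratio as a hazard-rate
#' ratio for every threshold crossing:
#' `RR = prod(OR_f ^ (present_treated_f - present_control_f))`, so moving
#' a factor below its threshold contributes `1/OR_f`. The effect lasts
#' `horizon` years (default 20) after programme start; beyond it `RR = 1`.
#'
#' @param control Counterfactual profile: list/data.frame with `bmi`,
#'   `sbp`, `total_chol`.
#' @param treated On-treatment profile, same shape (values already
#'   taper-adjusted by [intervention_offset()]).
#' @param year_since_start Programme year, starting at 1.
#' @param params Full parameter list or the `dementia$risk_reduction`
#'   block.
#' @return Relative risk per individual; `<= 1` whenever treated values
#'   are at or below control values.
#' @export
#' @examples
#' caide_relative_risk(list(bmi = 31, sbp = 130, total_chol = 5),
#'                     list(bmi = 29.5, sbp = 130, total_chol = 5), 2)
caide_relative_risk <- function(control, treated, year_since_start,
                                params = default_parameters()) {
  rp <- if (!is.null(params$dementia)) params$dementia$risk_reduction
        else params
  if (any(year_since_start < 1))
    stop("year_since_start must be >= 1", call. = FALSE)
  if (year_since_start > rp$horizon)
    return(rep(1, length(as.numeric(control$bmi))))
  d_obese <- (treated$bmi > rp$bmi_obese) - (control$bmi > rp$bmi_obese)
  d_htn <- (treated$sbp > rp$sbp_hypertension) -
    (control$sbp > rp$sbp_hypertension)
  d_lip <- (treated$total_chol > rp$tc_hyperlipidemia) -
    (control$total_chol > rp$tc_hyperlipidemia)
  rp$or_obese^d_obese * rp$or_hypertension^d_htn * rp$or_hyperlipidemia^d_lip
}

#' Sample cognitive function at dementia diagnosis
#'
#' Heterogeneity in MMSE at diagnosis: `MMSE = 30 - G` with
#' `G ~ Gamma(shape, scale)`, clamped to `[0, 30]`. The default
#' parameters give mean MMSE about 21 with SD about 5, matching
#' population-study summary data; the draw is independent of age, sex
#' and health status.
#'
#' @param n Number of draws, or
#' @param u Optional uniform draws (length `n`) for common-random-number
#'   use; when supplied the gamma quantile function is applied to them.
#' @param params Full parameter list or the `dementia$onset_mmse` block.
#' @return MMSE scores in `[0, 30]`.
#' @export
sample_mmse_at_diagnosis <- function(n = 1, params = default_parameters(),
                                     u = NULL) {
  om <- if (!is.null(params$dementia)) params$dementia$onset_mmse else params
  g <- if (is.null(u)) stats::rgamma(n, shape = om$shape, scale = om$scale)
       else stats::qgamma(u, shape = om$shape, scale = om$scale)
  clamp(30 - g, 0, 30)
}

#' Annual rate of MMSE change after diagnosis
#'
#' Linear-spline progression model of the annual MMSE change:
#' `rate = intercept + b_pm1*PM1 + b_pm2*PM2 + b_pm3*PM3 + b_age*age +
#' b_prev_rate*prev_rate`, with spline pieces of the previous MMSE
#' `PM1 = min(prev, 9)`, `PM2 = max(0, min(prev - 9, 9))`,
#' `PM3 = max(0, min(prev - 18, 12))`. `age` is the individual's age at
#' diagnosis (the model's baseline age) and `prev_rate` the previous
#' year's rate (0 in the first year after diagnosis). The next MMSE is
#' `clamp(prev + rate, 0, 30)`.
#'
#' @param prev_mmse Previous MMSE score(s) in `[0, 30]`.
#' @param age Age(s) at diagnosis, years.
#' @param prev_rate Previous annual rate(s) of change (score/year).
#' @param params Full parameter list or the `dementia$progression` block.
#' @return Annual rate of change (score/year).
#' @export
#' @examples
#' annual_mmse_change(30, 75, 0)   # -2.0727 with the default coefficients
annual_mmse_change <- function(prev_mmse, age, prev_rate = 0,
                               params = default_parameters()) {
  pr <- if (!is.null(params$dementia)) params$dementia$progression else params
  if (any(prev_mmse < 0 | prev_mmse > 30))
    stop("prev_mmse must lie in [0, 30]", call. = FALSE)
  k <- pr$knots
  w <- pr$widths
  pm1 <- pmin(prev_mmse, k[1])
  pm2 <- pmax(0, pmin(prev_mmse - k[1], w[1]))
  pm3 <- pmax(0, pmin(prev_mmse - k[2], w[2]))
  pr$intercept + pr$b_pm1 * pm1 + pr$b_pm2 * pm2 + pr$b_pm3 * pm3 +
    pr$b_age * age + pr$b_prev_rate * prev_rate
}

#' Dementia severity banding from MMSE
#'
#' Maps an MMSE score to the cost band (mild 21-26, moderate 10-20,
#' severe 0-9; scores of 27+ carry no dementia cost although the
#' diagnosis is retained) and to the utility band of the multiplier table
#' (none for 26+, then 21-25, 15-20, 10-14, 0-9).
#'
#' @param mmse MMSE score(s) in `[0, 30]`.
#' @return Data.frame with `cost_band` (`none`/`mild`/`moderate`/
#'   `severe`) and `utility_band` (`none`/`21-25`/`15-20`/`10-14`/`0-9`).
#' @export
#' @examples
#' severity_band(c(22, 20, 9))
severity_band <- function(mmse) {
  if (any(is.na(mmse)) || any(mmse < 0 | mmse > 30))
    stop("mmse must lie in [0, 30]", call. = FALSE)
  cost_band <- ifelse(mmse < 10, "severe",
                      ifelse(mmse < 21, "moderate",
                             ifelse(mmse < 27, "mild", "none")))
  utility_band <- ifelse(mmse < 10, "0-9",
                         ifelse(mmse < 15, "10-14",
                                ifelse(mmse < 21, "15-20",
                                       ifelse(mmse < 26, "21-25", "none"))))
  data.frame(cost_band = cost_band, utility_band = utility_band,
             stringsAsFactors = FALSE)
}

#' MMSE-band utility multiplier
#'
#' Multiplier applied to the individual's utility after dementia
#' diagnosis: 1 for MMSE >= 26, otherwise the configured band value
#' (defaults 0.93 / 0.725 / 0.710 / 0.478 for bands 21-25 / 15-20 /
#' 10-14 / 0-9).
#'
#' @param mmse MMSE score(s).
#' @param params Full parameter list or the `economics$utilities` block.
#' @return Multiplier in (0, 1].
#' @export
mmse_utility_multiplier <- function(mmse, params = default_parameters()) {
  ut <- if (!is.null(params$economics)) params$economics$utilities else params
  band <- severity_band(mmse)$utility_band
  mult <- rep(1, length(mmse))
  known <- band != "none"
  mult[known] <- ut$mmse[band[known]]
  mult
}

## subset a state (data.frame or list of vectors) by a logical mask
subset_state <- function(state, mask) {
  if (is.data.frame(state)) return(state[mask, , drop = FALSE])
  lapply(state, function(x) if (length(x) == length(mask)) x[mask] else x)
}
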