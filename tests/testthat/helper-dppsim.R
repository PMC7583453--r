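# Shared fixtures: parameter variants used across test files.

# Intervention with no metabolic effect and no fee: the two arms must be
# indistinguishable under common random numbers.
null_intervention_params <- function(params = default_parameters()) {
  params$intervention$delta[] <- 0
  params$intervention$cost <- 0
  params
}

# Fee-only intervention: GBP 270 in year 1, no metabolic effect.
fee_only_params <- function(params = default_parameters()) {
  params$intervention$delta[] <- 0
  params
}

# All condition and dementia mortality hazard ratios set to 1, so
# survival is driven by the baseline lifetable alone.
unit_hr_params <- function(params = default_parameters()) {
  params$comorbidity$mortality$hr_cvd <- 1
  params$comorbidity$mortality$hr_cancer <- 1
  params$comorbidity$mortality$hr_diabetes <- 1
  params$dementia$mortality$hr_60_84 <- 1
  params$dementia$mortality$hr_85_plus <- 1
  params
}

# Zero every PSA standard error so parameter draws are degenerate.
zero_se_params <- function(params = default_parameters()) {
  params$intervention$se[] <- 0
  params$dementia$incidence$se[] <- 0
  params$dementia$risk_reduction$se[] <- 0
  params$dementia$mortality$se[] <- 0
  params$dementia$progression$se[] <- 0
  params$economics$costs$se_frac <- 0
  params$economics$utilities$se_frac <- 0
  params
}

# A one-row individual state with every flag off, at the given age.
blank_state <- function(age = 57, sex = "female", bmi = 28.5, sbp = 130,
                        total_chol = 5.2, hdl_chol = 1.5, hba1c = 6.2,
                        baseline_eq5d = 0.9) {
  data.frame(
    age = age, sex = sex, smoking = "never",
    on_antihypertensives = FALSE, anxiety = FALSE, nsaid_use = FALSE,
    bmi = bmi, sbp = sbp, total_chol = total_chol, hdl_chol = hdl_chol,
    hba1c = hba1c, baseline_eq5d = baseline_eq5d,
    diabetes_diagnosed = FALSE, cvd_history = FALSE,
    cvd_event_this_year = FALSE, stroke_history = FALSE, chf = FALSE,
    cancer = FALSE, osteoarthritis = FALSE, depression = FALSE,
    dementia_diagnosed = FALSE, dementia_new = FALSE, mmse = NA_real_,
    stringsAsFactors = FALSE
  )
}
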