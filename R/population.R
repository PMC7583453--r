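#' Sample a synthetic eligible cohort
#'
#' Generates `n` individuals statistically emulating the programme-eligible
#' population (impaired glucose regulation, HbA1c 6.0-6.4%, age >= 16, no
#' diagnosed diabetes). Continuous risk factors (age, BMI, SBP, total and
#' HDL cholesterol, HbA1c) are drawn through a Gaussian copula with the
#' configured marginal means/SDs and correlation; age is a truncated
#' normal on `age_range` and HbA1c a truncated normal on `hba1c_range`,
#' so every emitted individual is eligible by construction. Binary
#' attributes (sex, ethnicity, smoking status, antihypertensive use,
#' anxiety, NSAID use) are Bernoulli at the configured prevalences and the
#' socioeconomic band is uniform over 1-5. Baseline EQ-5D utility follows
#' a configurable age rule plus individual noise, clamped to `[0, 1]`.
#'
#' @param n Number of individuals (non-negative integer).
#' @param params Either a full parameter list from [default_parameters()]
#'   or its `population` block.
#' @param seed Integer seed; cohorts are reproducible field-for-field.
#' @return A data.frame with one row per individual: identifiers,
#'   demographics, risk factors, baseline utility and all disease-state
#'   flags initialised to `FALSE` (`alive = TRUE`).
#' @export
#' @examples
#' cohort <- sample_cohort(100, seed = 1)
#' all(is_eligible(cohort))
sample_cohort <- function(n, params = default_parameters(), seed = 1L) {
  pop <- if (!is.null(params$population)) params$population else params
  if (length(n) != 1 || is.na(n) || n < 0)
    stop("n must be a single non-negative integer", call. = FALSE)
  n <- as.integer(n)

  R <- pop$correlation
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  if (n == 0L) return(empty_cohort())

  set.seed(seed)
  # Gaussian copula: correlated normals -> uniforms -> marginal quantiles
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(R))
  Z <- matrix(stats::rnorm(n * nrow(R)), n) %*% t(L)
  U <- stats::pnorm(Z)
  colnames(U) <- colnames(R)

  age <- qnorm_trunc(U[, "age"], pop$age_mean, pop$age_sd,
                     pop$age_range[1], pop$age_range[2])
  hba1c <- qnorm_trunc(U[, "hba1c"], pop$hba1c_mean, pop$hba1c_sd,
                       pop$hba1c_range[1], pop$hba1c_range[2])
  bmi <- stats::qnorm(U[, "bmi"], pop$bmi_mean, pop$bmi_sd)
  sbp <- stats::qnorm(U[, "sbp"], pop$sbp_mean, pop$sbp_sd)
  tc <- stats::qnorm(U[, "total_chol"], pop$tc_mean, pop$tc_sd)
  hdl <- stats::qnorm(U[, "hdl_chol"], pop$hdl_mean, pop$hdl_sd)
  # keep values physiologically plausible
  bmi <- clamp(bmi, 13, 70)
  sbp <- clamp(sbp, 70, 250)
  tc <- clamp(tc, 1, 15)
  hdl <- clamp(hdl, 0.3, 5)

  sex <- ifelse(stats::runif(n) < pop$prop_male, "male", "female")
  ethnicity <- ifelse(stats::runif(n) < pop$prop_nonwhite,
                      "nonwhite", "white")
  u_smoke <- stats::runif(n)
  smoking <- ifelse(u_smoke < pop$prop_current_smoker, "current",
                    ifelse(u_smoke < pop$prop_current_smoker +
                             pop$prop_past_smoker, "past", "never"))
  on_aht <- stats::runif(n) < pop$prop_hypertension
  anxiety <- stats::runif(n) < pop$prop_anxiety
  nsaid <- stats::runif(n) < pop$prop_nsaid
  ses <- sample.int(5L, n, replace = TRUE)

  eq <- pop$eq5d
  eq5d <- eq$intercept - eq$age_slope * pmax(0, age - eq$age_knot) +
    stats::rnorm(n, 0, eq$noise_sd)
  eq5d <- clamp(eq5d, 0, 1)

  data.frame(
    id = seq_len(n), age = age, sex = sex, ethnicity = ethnicity,
    smoking = smoking, on_antihypertensives = on_aht, ses_band = ses,
    anxiety = anxiety, nsaid_use = nsaid,
    bmi = bmi, sbp = sbp, total_chol = tc, hdl_chol = hdl, hba1c = hba1c,
    baseline_eq5d = eq5d,
    diabetes_diagnosed = FALSE, cvd_history = FALSE, stroke_history = FALSE,
    chf = FALSE, cancer = FALSE, osteoarthritis = FALSE, depression = FALSE,
    dementia_diagnosed = FALSE, alive = TRUE,
    stringsAsFactors = FALSE
  )
}

empty_cohort <- function() {
  data.frame(
    id = integer(0), age = numeric(0), sex = character(0),
    ethnicity = character(0), smoking = character(0),
    on_antihypertensives = logical(0), ses_band = integer(0),
    anxiety = logical(0), nsaid_use = logical(0),
    bmi = numeric(0), sbp = numeric(0), total_chol = numeric(0),
    hdl_chol = numeric(0), hba1c = numeric(0), baseline_eq5d = numeric(0),
    diabetes_diagnosed = logical(0), cvd_history = logical(0),
    stroke_history = logical(0), chf = logical(0), cancer = logical(0),
    osteoarthritis = logical(0), depression = logical(0),
    dementia_diagnosed = logical(0), alive = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Programme eligibility
#'
#' An individual is eligible when aged 16 or over, HbA1c lies in the
#' impaired-glucose-regulation window 6.0-6.4% inclusive, and diabetes has
#' not been diagnosed.
#'
#' @param cohort Data.frame with columns `age`, `hba1c`,
#'   `diabetes_diagnosed` (one row per individual; vectorised).
#' @return Logical vector, one entry per row.
#' @export
is_eligible <- function(cohort) {
  if (any(is.na(cohort$hba1c)))
    stop("hba1c is undefined for some individuals", call. = FALSE)
  cohort$age >= 16 & cohort$hba1c >= 6.0 & cohort$hba1c <= 6.4 &
    !cohort$diabetes_diagnosed
}

#' Write / read a cohort as CSV
#'
#' Plain one-row-per-individual CSV with the fixed header produced by
#' [sample_cohort()]. On read, missing optional columns (state flags,
#' `ses_band`, `anxiety`, `nsaid_use`, `baseline_eq5d`) are filled from
#' defaults; the required core is demographics plus the six risk factors.
#'
#' @param cohort A cohort data.frame.
#' @param path File path.
#' @param params Parameter list used to fill a missing `baseline_eq5d`.
#' @return `read_cohort()` returns the cohort data.frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, params = default_parameters()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("age", "sex", "bmi", "sbp", "total_chol", "hdl_chol", "hba1c")
  missing_req <- setdiff(required, names(x))
  if (length(missing_req))
    stop("cohort file lacks required columns: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  n <- nrow(x)
  if (is.null(x$id)) x$id <- seq_len(n)
  if (is.null(x$ethnicity)) x$ethnicity <- "white"
  if (is.null(x$smoking)) x$smoking <- "never"
  if (is.null(x$on_antihypertensives)) x$on_antihypertensives <- FALSE
  if (is.null(x$ses_band)) x$ses_band <- 3L
  if (is.null(x$anxiety)) x$anxiety <- FALSE
  if (is.null(x$nsaid_use)) x$nsaid_use <- FALSE
  if (is.null(x$baseline_eq5d)) {
    eq <- params$population$eq5d
    x$baseline_eq5d <- clamp(
      eq$intercept - eq$age_slope * pmax(0, x$age - eq$age_knot), 0, 1)
  }
  for (fl in c("diabetes_diagnosed", "cvd_history", "stroke_history", "chf",
               "cancer", "osteoarthritis", "depression",
               "dementia_diagnosed")) {
    if (is.null(x[[fl]])) x[[fl]] <- FALSE
  }
  if (is.null(x$alive)) x$alive <- TRUE
  x
}

## quantile of a normal truncated to [lower, upper], copula-style
qnorm_trunc <- function(u, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + u * (pu - pl), mean, sd)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
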