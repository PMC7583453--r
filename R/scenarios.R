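#' Incremental results stratified by baseline subgroup
#'
#' Repeats the two-arm comparison on subsets of the cohort defined by
#' baseline age bands (membership `lo <= age < hi`) and/or HbA1c bands
#' (`lo <= hba1c <= hi`). Each band is simulated on its own members only,
#' with the same seed. Empty bands produce a flagged `NA` row rather than
#' an error.
#'
#' @param cohort Cohort data.frame.
#' @param scenario Scenario name as in [run_arm()].
#' @param params Full parameter list.
#' @param seed Integer seed.
#' @param age_bands List of `c(lo, hi)` age bands (default the four
#'   decade bands 40-50 through 70-80).
#' @param hba1c_bands List of `c(lo, hi)` HbA1c bands (default the
#'   lower-risk 6.0-6.1% and higher-risk 6.2-6.4% windows).
#' @param age_cap Passed to [run_arm()].
#' @return Data.frame with one row per band: `band_type`, `lo`, `hi`,
#'   `n`, `inc_cost`, `inc_qalys`, `net_benefit`.
#' @export
run_subgroups <- function(cohort,
                          scenario = c("no_dementia", "dementia_only",
                                       "reduced_dementia_risk"),
                          params = default_parameters(), seed = 1L,
                          age_bands = list(c(40, 50), c(50, 60),
                                           c(60, 70), c(70, 80)),
                          hba1c_bands = list(c(6.0, 6.1), c(6.2, 6.4)),
                          age_cap = 100) {
  scenario <- match.arg(scenario)
  bands <- c(
    lapply(age_bands, function(b) list(type = "age", lo = b[1], hi = b[2])),
    lapply(hba1c_bands, function(b) list(type = "hba1c", lo = b[1],
                                         hi = b[2]))
  )
  rows <- lapply(bands, function(b) {
    keep <- if (b$type == "age") {
      cohort$age >= b$lo & cohort$age < b$hi
    } else {
      cohort$hba1c >= b$lo & cohort$hba1c <= b$hi
    }
    n_band <- sum(keep)
    if (n_band == 0) {
      return(data.frame(band_type = b$type, lo = b$lo, hi = b$hi, n = 0L,
                        inc_cost = NA_real_, inc_qalys = NA_real_,
                        net_benefit = NA_real_))
    }
    cmp <- compare_arms(cohort[keep, , drop = FALSE], scenario, params,
                        seed, age_cap)
    data.frame(band_type = b$type, lo = b$lo, hi = b$hi, n = n_band,
               inc_cost = cmp$incremental$cost,
               inc_qalys = cmp$incremental$qalys,
               net_benefit = cmp$incremental$net_benefit)
  })
  do.call(rbind, rows)
}

#' Draw one probabilistic-sensitivity-analysis parameter sample
#'
#' Draws every uncertain parameter from its assigned distribution using
#' the current random-number state: the four metabolic effect sizes are
#' normal with their reported standard errors; the risk-score hazard
#' ratios, CAIDE odds ratios and dementia mortality hazard ratios are
#' lognormal (standard error on the printed scale, delta-method
#' `sdlog = se/mean`, median preserved); MMSE progression coefficients
#' are normal; dementia costs are gamma with a 10% standard error; the
#' MMSE utility multipliers are beta with a 10% standard error,
#' moment-matched. Parameters with a zero standard error are returned
#' unchanged, so a degenerate PSA reproduces the deterministic result.
#'
#' @param params Full parameter list (carries the standard errors).
#' @return A parameter list of the same shape with drawn values.
#' @export
draw_psa_parameters <- function(params = default_parameters()) {
  p <- params

  iv <- p$intervention
  p$intervention$delta <- stats::setNames(
    rnorm_se(iv$delta, iv$se[names(iv$delta)]), names(iv$delta))

  inc <- p$dementia$incidence
  for (nm in c("hr_bmi", "hr_bmi_sq", "hr_antihypertensives", "hr_stroke",
               "hr_diabetes"))
    p$dementia$incidence[[nm]] <- rlnorm_se(inc[[nm]], inc$se[[nm]])

  rr <- p$dementia$risk_reduction
  for (nm in c("or_obese", "or_hypertension", "or_hyperlipidemia"))
    p$dementia$risk_reduction[[nm]] <- rlnorm_se(rr[[nm]], rr$se[[nm]])

  mo <- p$dementia$mortality
  p$dementia$mortality$hr_60_84 <- rlnorm_se(mo$hr_60_84, mo$se[["hr_60_84"]])
  p$dementia$mortality$hr_85_plus <- rlnorm_se(mo$hr_85_plus,
                                               mo$se[["hr_85_plus"]])

  pg <- p$dementia$progression
  for (nm in c("intercept", "b_pm1", "b_pm2", "b_pm3", "b_age",
               "b_prev_rate"))
    p$dementia$progression[[nm]] <- rnorm_se(pg[[nm]], pg$se[[nm]])

  cc <- p$economics$costs
  f <- cc$se_frac
  p$economics$costs$dementia_health <- rgamma_frac(cc$dementia_health, f)
  p$economics$costs$dementia_social <- rgamma_frac(cc$dementia_social, f)

  ut <- p$economics$utilities
  p$economics$utilities$mmse <- rbeta_frac(ut$mmse, ut$se_frac)
  p
}

rnorm_se <- function(mean, se) {
  out <- mean
  pos <- se > 0
  if (any(pos)) out[pos] <- stats::rnorm(sum(pos), mean[pos], se[pos])
  out
}

## lognormal preserving the median, sdlog from the delta method
rlnorm_se <- function(mean, se) {
  if (se <= 0) return(mean)
  stats::rlnorm(1, meanlog = log(mean), sdlog = se / mean)
}

## gamma with sd = frac * mean (shape 1/frac^2)
rgamma_frac <- function(mean, frac) {
  if (frac <= 0) return(mean)
  shape <- 1 / frac^2
  out <- stats::rgamma(length(mean), shape = shape,
                       scale = mean * frac^2)
  stats::setNames(out, names(mean))
}

## beta moment-matched to mean m and sd = frac * m, kept in (0, 1]
rbeta_frac <- function(mean, frac) {
  if (frac <= 0) return(mean)
  v <- (frac * mean)^2
  a <- mean * (mean * (1 - mean) / v - 1)
  b <- (1 - mean) * (mean * (1 - mean) / v - 1)
  out <- stats::rbeta(length(mean), a, b)
  stats::setNames(pmin(pmax(out, 1e-6), 1), names(mean))
}

#' Probabilistic sensitivity analysis with CEAC output
#'
#' For each sample, draws one parameter set via [draw_psa_parameters()]
#' and computes one incremental result with [compare_arms()]; the event
#' streams use the same seed for every sample so only parameter
#' uncertainty varies. The cost-effectiveness acceptability curve is the
#' fraction of samples with positive net benefit at each willingness to
#' pay: `CEAC(lambda) = mean(lambda * dQALY - dCost > 0)`.
#'
#' @param cohort Cohort data.frame (subsample the full cohort for
#'   desk-scale runtimes).
#' @param scenario Scenario name.
#' @param params Full parameter list.
#' @param n_samples Number of PSA samples (the published analysis uses
#'   5000; the default here is desk-scale).
#' @param lambda_grid Willingness-to-pay grid for the CEAC, GBP/QALY.
#' @param seed Integer seed (parameter draws and event streams).
#' @param age_cap Passed to [run_arm()].
#' @return List with `samples` (data.frame: sample, inc_cost, inc_qalys,
#'   net_benefit) and `ceac` (data.frame: lambda, probability).
#' @export
run_psa <- function(cohort,
                    scenario = c("no_dementia", "dementia_only",
                                 "reduced_dementia_risk"),
                    params = default_parameters(), n_samples = 500,
                    lambda_grid = seq(0, 50000, by = 2500), seed = 1L,
                    age_cap = 100) {
  scenario <- match.arg(scenario)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (!length(lambda_grid)) stop("lambda_grid is empty", call. = FALSE)
  set.seed(seed)
  sampled <- replicate(n_samples, draw_psa_parameters(params),
                       simplify = FALSE)
  rows <- lapply(seq_len(n_samples), function(s) {
    cmp <- compare_arms(cohort, scenario, sampled[[s]], seed, age_cap)
    data.frame(sample = s, inc_cost = cmp$incremental$cost,
               inc_qalys = cmp$incremental$qalys,
               net_benefit = cmp$incremental$net_benefit)
  })
  samples <- do.call(rbind, rows)
  ceac <- ceac_from_samples(samples, lambda_grid)
  list(samples = samples, ceac = ceac)
}

#' Cost-effectiveness acceptability curve from PSA samples
#'
#' @param samples Data.frame with `inc_cost` and `inc_qalys` columns.
#' @param lambda_grid Willingness-to-pay grid.
#' @return Data.frame with `lambda` and `probability` (fraction of
#'   samples cost-effective at that lambda).
#' @export
ceac_from_samples <- function(samples, lambda_grid = seq(0, 50000, 2500)) {
  prob <- vapply(lambda_grid, function(l) {
    mean(l * samples$inc_qalys - samples$inc_cost > 0)
  }, numeric(1))
  data.frame(lambda = lambda_grid, probability = prob)
}
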