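#' Project a metabolic risk factor one year forward
#'
#' Annual drift-plus-noise update for one of the tracked factors
#' (`bmi`, `sbp`, `total_chol`, `hdl_chol`, `hba1c`):
#' `next = current + drift(age) + residual_sd * noise`, where
#' `drift(age) = intercept + age_slope*age + post60*(age >= 60)`, clamped
#' to the factor's documented physiological range (BMI 13-70 kg/m2,
#' SBP 70-250 mm Hg, total cholesterol 1-15 mmol/L, HDL 0.3-5 mmol/L,
#' HbA1c 3.5-20%). The drift coefficients are configurable stand-ins for
#' the cohort-study mixed models the published model uses.
#'
#' @param current Current factor value(s).
#' @param age Age(s) in years.
#' @param factor Factor name, one of the five above.
#' @param params Either a full parameter list or its `trajectories` block.
#' @param noise Standard-normal draw(s), same length as `current`
#'   (default 0 for a deterministic step).
#' @return Next-year value(s), clamped to the physiological range.
#' @export
#' @examples
#' project_factor(28, 57, "bmi", default_parameters(), noise = 0)
project_factor <- function(current, age, factor, params = default_parameters(),
                           noise = 0) {
  tr <- if (!is.null(params$trajectories)) params$trajectories else params
  if (!factor %in% names(tr$drift))
    stop("unknown factor: ", factor, call. = FALSE)
  d <- tr$drift[[factor]]
  drift <- d[["intercept"]] + d[["age_slope"]] * age +
    d[["post60"]] * (age >= 60)
  rng <- tr$range[[factor]]
  clamp(current + drift + tr$residual_sd[[factor]] * noise, rng[1], rng[2])
}

#' Intervention effect remaining in a given programme year
#'
#' The lifestyle intervention shifts each metabolic factor by its full
#' effect `delta` in year 1; the gap to the counterfactual then narrows
#' linearly and is gone after `duration` years:
#' `offset(y) = delta * max(0, (duration + 1 - y) / duration)`.
#'
#' @param delta Full-effect size in factor units (e.g. -1.47 kg/m2 BMI).
#' @param year_since_start Programme year, starting at 1.
#' @param duration Duration of effect in years (default 5).
#' @return Offset in factor units; 0 from year `duration + 1` onwards.
#' @export
#' @examples
#' intervention_offset(-1.47, 1)  # full effect
#' intervention_offset(-1.47, 3)  # tapered
#' intervention_offset(-1.47, 6)  # back to counterfactual
intervention_offset <- function(delta, year_since_start, duration = 5) {
  if (any(year_since_start < 1))
    stop("year_since_start must be >= 1", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  delta * pmax(0, (duration + 1 - year_since_start) / duration)
}
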