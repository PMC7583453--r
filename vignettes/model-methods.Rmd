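---
title: "Model structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dppsim)
```

`dppsim` is an annual-cycle, individual-level simulation of a
diabetes-prevention lifestyle programme in which dementia is an explicit
health outcome. This vignette documents the model itself: what each
module assumes, which parameters matter and why their defaults are what
they are, which components are deliberately simplified stand-ins, and
what the test suite does and does not establish about real populations.

## The three scenarios

The programme (a one-off £270 intensive lifestyle intervention for
people with HbA1c 6.0–6.4%) is always evaluated as a two-arm comparison
— intervention versus no intervention — under common random numbers.
Three scenarios vary how dementia enters:

* **no_dementia** — the dementia machinery is fully disabled; this is
  the baseline diabetes/CVD model.
* **dementia_only** — dementia incidence, progression, mortality, costs
  and utility decrements are simulated, but the intervention has *no
  direct* effect on dementia risk: its metabolic effects reach dementia
  only through reduced diabetes and stroke incidence.
* **reduced_dementia_risk** — additionally, the intervention's
  (tapering) changes in BMI, blood pressure and cholesterol reduce the
  dementia-diagnosis hazard through the CAIDE odds ratios for 20 years
  after programme start.

A consequence worth stating explicitly: the diagnosis risk score
contains BMI as a covariate, so feeding the intervention arm's shifted
BMI into it would create a direct metabolic effect on dementia even in
`dementia_only`. The engine therefore evaluates the risk score on
*counterfactual* metabolic values in both arms; arm differences reach
dementia incidence only through the diabetes and stroke flags and, in
`reduced_dementia_risk`, through the CAIDE relative risk. This keeps the
direct metabolic channel exclusively where the scenario design puts it.

## Synthetic cohort

`sample_cohort()` emulates the programme-eligible population of a
national health survey. Only *marginal* summaries of that population are
published (means/SDs of age, BMI, SBP, cholesterol, HbA1c; proportions
of sex, ethnicity, smoking, treated hypertension), so the joint
distribution is a modelling choice: a Gaussian copula with unit-diagonal
correlation, defaulting to BMI–SBP 0.2, BMI–HbA1c 0.15, age–SBP 0.3 and
0 elsewhere — plausible positive dependence among adiposity, blood
pressure and glycaemia without claiming more than the data support. Age
is truncated to [16, 90] and HbA1c to the eligibility window
[6.0, 6.4], so every emitted individual is eligible by construction.
Baseline EQ-5D follows `0.95 − 0.003·max(0, age − 40)` plus N(0, 0.1)
noise, clamped to [0, 1]; socioeconomic band is uniform over 1–5 and
anxiety (10%) and NSAID use (15%) are fixed prevalences — these
covariates exist so the risk-score surface is complete, and their
hazard ratios default to 1.

What the generator does *not* emulate: survey design weights, regional
or cohort effects, non-Gaussian marginal shapes (e.g. the BMI right
skew), and any dependence beyond the pairwise copula defaults. Tests
that pass on this cohort therefore establish the engine's internal
correctness and directional behaviour, not calibration to the real
eligible population.

## Metabolic trajectories and the intervention

Each factor follows `next = current + drift(age) + σ·ε` with
`drift = intercept + slope·age + Δ·[age ≥ 60]`, clamped to documented
physiological ranges (BMI 13–70 kg/m², SBP 70–250 mm Hg, TC 1–15, HDL
0.3–5 mmol/L, HbA1c 3.5–20%). The shipped drifts (BMI +0.05/yr before
60 and −0.05 after, SBP +0.5/yr, HbA1c +0.02/yr, TC +0.01/−0.02;
residual SDs BMI 0.3, SBP 3, TC 0.15, HDL 0.05, HbA1c 0.05) are
configurable stand-ins
for the cohort-study mixed models of the full model, not estimates.

The intervention applies its full effect in year 1 and returns to the
counterfactual after 5 years. The published description fixes the
endpoints but not the path; we use the simplest monotone interpolant,
a linear taper `offset(y) = δ·max(0, (D + 1 − y)/D)`. Each individual
carries both counterfactual and on-treatment values, so the
"return to the level they would have been" contract is exact and the
two arms share every random draw.

One structural consequence of this design deserves note: because
eligibility caps HbA1c at 6.4% and diabetes requires crossing 6.5%, a
five-year −0.2% offset delays few crossings, so the incremental number
of diabetes diagnoses is small (a few per 1000 rather than the order of
ten per 1000 a richer trajectory model produces). The direction is
guaranteed — with shared draws the intervention arm can never have
*more* diagnoses — but the magnitude of every downstream quantity that
flows through the diabetes channel is correspondingly conservative.

## Comorbidity stand-ins

The full model's risk-engine equations are out of scope here; the
module instead provides the minimum host physiology the dementia and
economics layers need, with every piece swappable:

* **Mortality.** A synthetic Gompertz–Makeham lifetable
  `q(age) = min(0.7, 2·10⁻⁴ + e^(−10.5 + 0.087·age))`, males scaled by
  1.3; a real lifetable can be supplied as CSV. Condition hazard ratios
  (CVD 1.5, cancer 2.0, diabetes 1.3) multiply on the hazard scale.
* **Cardiovascular events.** One log-linear hazard (per-decade age
  0.55, per-10 mm Hg SBP 0.12, male 0.3, current smoker 0.4, diabetes
  0.5, TC:HDL ratio 0.15) with the intercept set so the cohort-centre
  profile sees about 1%/year — a calibration knob, not a claim. A
  quarter of events are strokes.
* **Other conditions.** Annual hazards `exp(a + b·age)` for cancer,
  osteoarthritis, depression and heart failure, with absorbing flags.
* **Diabetes.** Diagnosed when HbA1c ≥ 6.5% and an annual detection
  draw (probability 0.3) succeeds.

Costs accumulate additively across conditions (accepting some double
counting, as the source model does); utility decrements multiply,
avoiding double counting of quality-of-life loss under multimorbidity.

## Dementia module

**Diagnosis.** From age 60, `p = 1 − exp(−h₀(age)·RR)`. The baseline
hazard table (per 1000 person-years: 2 at 60–64, 5 at 65–69, 11 at
70–74, 23 at 75–79, 45 at 80–84, 80 at 85+, equal by sex) is a
documented stand-in for the unpublished risk-score baseline; nothing in
the test suite depends on its absolute level. The covariate relative
risk uses the published per-unit BMI (0.940) and BMI² (1.003) hazard
ratios — centred at BMI 28, the cohort median, since the source does
not print its reference point — together with antihypertensives
(0.876), stroke (1.781) and diabetes (1.332).

**Direct risk reduction.** The CAIDE odds ratios (obesity 2.296,
hypertension 2.206, hyperlipidaemia 1.879) are applied as hazard-rate
ratios (a rare-event approximation, since no conversion is published)
whenever the intervention moves a factor across its category threshold
(BMI > 30, SBP > 140, TC > 6.5; strict inequalities per the source risk
score). By default the relative risk is *recomputed each cycle* against
taper-adjusted values, so it returns to 1 once the metabolic effect has
worn off unless a threshold crossing persists; setting
`dementia$risk_reduction$mode = "frozen"` instead holds the year-1 value for the whole 20-year horizon. Recompute
is the default because it keeps the dementia effect consistent with the
simulated metabolic state at every cycle.

**Onset severity and progression.** MMSE at diagnosis is
`30 − Gamma(3.24, 25/9)`, clamped to [0, 30] (mean 21, SD 5),
independent of age, sex and health. The annual MMSE change is a linear
spline in the previous score (pieces at 9 and 18 with widths 9 and 12),
age at diagnosis, and the previous year's rate. The printed spline
labels are ambiguous ("min(PrevMMSE, −9, 9)"); they are implemented as
`PM1 = min(prev, 9)`, `PM2 = max(0, min(prev − 9, 9))`,
`PM3 = max(0, min(prev − 18, 12))`, which reproduces the hand-evaluated
cases (−2.0727 at score 30, age 75; −1.4816 at score 5, age 80,
previous rate −2). The diagnosis year uses the sampled onset score with
no accrued decline; progression starts the following cycle with the
previous rate initialised to 0.

**Banding quirk, implemented literally.** The cost bands are mild
21–26, moderate 10–20, severe 0–9, while the utility bands stop at 25
(multiplier 1 from 26 up). A score of exactly 26 therefore carries a
mild-dementia cost but no utility decrement; scores of 27+ carry
neither, although the diagnosis (and its mortality hazard ratio)
remains.

**Mortality.** The published age-band labels conflict between table and
text; the text convention is adopted: hazard ratio 4.54 at ages 60–84
and 2.77 at 85+.

## Economics

Discounting is `1/(1.035)^t` with `t = 0` in the first model year
(whether the source discounts its first year is unstated; one
convention had to be fixed, and first-cycle-undiscounted composes
cleanly with the events-at-cycle-start design). There is no half-cycle
correction, matching the annual-cycle description. Individuals accrue
no costs or QALYs in the cycle of death (`accrue_death_year` flips
this), with one exception: the £270 intervention fee is paid up front
and is charged even to first-cycle deaths. The age-related utility
multiplier is `max(0.4, 1 − 2·10⁻⁴·(age − 40)²)`, a smooth stand-in for
published age-decrement tariffs.

## Engine, subgroups, PSA

Both arms and all scenarios share one seed-derived set of named random
streams (one matrix per event type), so activating the dementia module
cannot perturb cardiovascular or mortality draws, and arm differences
are pure intervention effects. Individuals are simulated to death or
age 100. Per-1000 event counts are lifetime *first-event* counts
(a person counts once), the closest reading of per-1000 reporting in
the source tables.

The PSA draws: metabolic effects ~ Normal(mean, SE); hazard and odds
ratios ~ lognormal with the median preserved and `sdlog = SE/mean`;
dementia costs ~ Gamma with 10% SE; utility multipliers ~
moment-matched Beta with 10% SE; MMSE progression coefficients ~
Normal. Draws are independent across parameters (no published
correlations) and the event streams reuse the same seed for every
sample, so a zero-SE PSA collapses exactly onto the deterministic
result.

## Problem sizes and numerical choices

The package's own analyses use desk-scale sizes chosen for a laptop
run: cohorts of 10,000 for marginal-accuracy and directional checks
(ten replicates for the scenario ordering), 100-person cohorts with
full ledger retention for the brute-force accounting audit, and a PSA
of 60–500 samples on cohorts of 500–2000 (the source analysis uses
5000 samples; `n_samples` scales up directly). Determinism is exact:
same seed, bit-identical results. Degenerate inputs are handled
explicitly: empty cohorts and negative sizes are errors, empty subgroup
bands are flagged rows, zero-SE PSA is the deterministic limit, and all
clamps (MMSE [0, 30], factor ranges, utilities [0, 1]) are hard
invariants under test.

## Known limitations

* Absolute levels (lifetime costs, dementia incidence, QALY totals) are
  *not* calibrated: the lifetable, comorbidity equations and baseline
  dementia hazard are stand-ins, and the synthetic lifetable in
  particular is light at very old ages, which inflates lifetime
  dementia exposure relative to the source model. Directional and
  structural results are the supported outputs.
* The dementia-only shift in net benefit is a near-cancellation of
  opposing channels (dementia costs in added life years versus indirect
  incidence reduction) and is small relative to Monte-Carlo noise in
  single replicates; it is only resolved in direction when averaged
  over replicates.
* The eligibility-window/threshold geometry makes the incremental
  diabetes channel structurally weak (see the trajectories section), so
  quantities downstream of it are conservative in magnitude.
* No dementia subtypes, no behavioural/functional severity scales, no
  post-diagnosis dementia treatment, no societal perspective or carer
  costs.
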