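Package: dppsim
Title: Microsimulation of Diabetes Prevention with Dementia Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level microsimulation of an intensive lifestyle
    intervention for people with impaired glucose regulation (the NHS
    Diabetes Prevention Programme eligibility window, HbA1c 6.0-6.4%),
    extended with dementia as an explicit health outcome. The model evolves
    metabolic risk factors (BMI, systolic blood pressure, cholesterol,
    HbA1c) in annual cycles, simulates diabetes, cardiovascular and other
    comorbid events, dementia diagnosis via a primary-care risk score with
    an optional direct risk reduction derived from the CAIDE midlife risk
    factors, MMSE-based dementia progression and severity banding, and
    accumulates discounted NHS and personal social services costs and
    QALYs. Provides two-arm comparisons with common random numbers across
    three dementia scenarios, subgroup stratification, probabilistic
    sensitivity analysis and cost-effectiveness acceptability curves, plus
    a synthetic-cohort generator emulating the eligible Health Survey for
    England population so the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
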