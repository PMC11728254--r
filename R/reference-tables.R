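# Published summary tables of the 299-patient emergency-department
# validation cohort that motivates this package. They serve two roles:
# default parameters for the synthetic cohort generator, and packaged
# fixtures for the exact-arithmetic acceptance checks. The expected-mortality
# column comes from the score's (unpublished) derivation cohort and is
# carried as a constant only.

#' Reference SIL stratum table
#'
#' Per-SIL-value patient and death counts from the validation cohort
#' (n = 299, 61 deaths), together with the expected mortality per stratum
#' from the derivation cohort.
#'
#' @return A `stratum_table`: columns `score_value` (0-6), `n_total`,
#'   `n_deaths`, `expected_mortality` (percent).
#' @export
reference_stratum_table <- function() {
  stratum_table(
    score_value = 0:6,
    n_total = c(87L, 104L, 52L, 36L, 15L, 2L, 3L),
    n_deaths = c(6L, 15L, 11L, 17L, 8L, 1L, 3L),
    expected_mortality = c(11.8, 23.4, 34.8, 42.2, 66.3, 85.4, 90.4)
  )
}

#' Reference cohort characteristics
#'
#' Headline counts of the validation cohort used as generator defaults and
#' acceptance fixtures: screening and confirmation totals, mortality by
#' diagnosis class, sex, and comorbidity 2x2 cells
#' (deaths/survivors with and without each comorbidity).
#'
#' @return A list with components `n_screened`, `n_confirmed`, `n_deaths`,
#'   `n_shock`, `shock_deaths`, `sepsis_deaths`, `n_male`, and `comorbidities`
#'   (data.frame with one row per comorbidity and the four 2x2 cells).
#' @export
reference_cohort_stats <- function() {
  list(
    n_screened = 315L,
    n_confirmed = 299L,
    n_deaths = 61L,
    n_shock = 106L,
    shock_deaths = 42L,
    sepsis_deaths = 19L,
    n_male = 124L,
    comorbidities = data.frame(
      comorbidity = c("hypertension", "diabetes", "renal_insufficiency",
                      "immunosuppression", "copd"),
      deaths_with = c(29L, 16L, 14L, 13L, 10L),
      survivors_with = c(103L, 55L, 16L, 47L, 18L),
      deaths_without = c(32L, 45L, 47L, 48L, 51L),
      survivors_without = c(135L, 183L, 222L, 191L, 220L)
    )
  )
}

#' Reference accuracy table
#'
#' The published sensitivity/specificity/predictive-value comparison of the
#' four scores on the validation cohort. Predictive values were
#' prevalence-adjusted by the original analysts; note that applying the
#' adjustment formulas to the printed sensitivity, specificity and
#' prevalence reproduces the printed NPV/PPV pairs only with the two columns
#' interchanged (see the package vignette).
#'
#' @return data.frame with columns `score`, `spec`, `sens`, `npv`, `ppv`.
#' @export
reference_accuracy_table <- function() {
  data.frame(
    score = c("qsofa", "news", "sofa", "sil"),
    spec = c(0.372, 0.595, 0.581, 0.678),
    sens = c(0.383, 0.628, 0.665, 0.694),
    npv = c(0.134, 0.290, 0.308, 0.362),
    ppv = c(0.704, 0.858, 0.861, 0.893)
  )
}
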