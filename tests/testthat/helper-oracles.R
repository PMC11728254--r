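# Independent oracles and tiny fixtures shared across tests.

# Brute-force Mann-Whitney AUC: enumerate every (death, survivor) pair.
# O(m*n); the reference against which the rank-based implementation is
# checked.
auc_pair_oracle <- function(scores, outcomes) {
  x <- scores[outcomes == 1]
  y <- scores[outcomes == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Expand a stratum table to per-patient vectors (independent of the
# package-internal helper).
expand_table <- function(tab) {
  scores <- rep(tab$score_value, tab$n_total)
  outcomes <- unlist(Map(function(n, d) c(rep(1L, d), rep(0L, n - d)),
                         tab$n_total, tab$n_deaths))
  list(scores = scores, outcomes = as.integer(outcomes))
}

# A random small cohort with both classes guaranteed.
random_cohort_vectors <- function(n) {
  scores <- sample(0:6, n, replace = TRUE)
  outcomes <- rbinom(n, 1, 0.3)
  if (all(outcomes == 0)) outcomes[1] <- 1L
  if (all(outcomes == 1)) outcomes[1] <- 0L
  list(scores = scores, outcomes = outcomes)
}

withr_tempfile <- function() tempfile(fileext = ".csv")

# A minimal well-formed cohort data.frame for I/O tests.
tiny_cohort <- function() {
  data.frame(
    id = 1:3, age = c(70, 55, 81), sex = c("male", "female", "female"),
    heart_rate = c(100, 130, 88), systolic_bp = c(120, 85, 110),
    respiratory_rate = c(16, 28, 20), temperature = c(37.0, 38.6, 36.2),
    spo2 = c(97, 90, 95), supplemental_o2 = c(FALSE, TRUE, FALSE),
    consciousness_gcs = c(15, 13, 15), lactate = c(1.2, 5.0, 2.4),
    pao2_fio2 = c(420, 180, 310), platelets = c(250, 80, 190),
    bilirubin = c(0.7, 2.4, 1.1), mean_arterial_pressure = c(90, 60, 78),
    vasopressor_category = c("none", "dopamine_mid", "none"),
    creatinine = c(0.9, 2.8, 1.3),
    comorbidity_hypertension = c(TRUE, FALSE, TRUE),
    comorbidity_diabetes = c(FALSE, FALSE, TRUE),
    comorbidity_renal_insufficiency = c(FALSE, TRUE, FALSE),
    comorbidity_immunosuppression = c(FALSE, FALSE, FALSE),
    comorbidity_copd = c(FALSE, TRUE, FALSE),
    diagnosis_class = c("sepsis", "septic_shock", "sepsis"),
    died = c(0L, 1L, 0L)
  )
}
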