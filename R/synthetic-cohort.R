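# Seeded synthetic emergency-department cohort generator.
#
# The generator emulates the statistical structure of the validation cohort:
# the SIL stratum distribution and per-stratum mortality, the sex and
# septic-shock marginals, and the comorbidity prevalences. Everything else
# (the joint distribution of comparator-score inputs) is a modelling
# construction: a shared latent severity variable loosely couples the NEWS,
# qSOFA and SOFA inputs to the SIL stratum so that comparator analyses are
# exercised with plausible correlation, without claiming to copy any real
# joint distribution.

#' Cohort generator configuration
#'
#' Defaults reproduce the validation cohort: stratum sizes 87, 104, 52, 36,
#' 15, 2, 3 over SIL values 0-6 (n = 299), stratum deaths 6, 15, 11, 17, 8,
#' 1, 3 (61 total, 20.4% mortality), male fraction 124/299, septic-shock
#' fraction 106/299, and the printed comorbidity prevalences.
#'
#' @param n Number of patients.
#' @param sil_stratum_probs Probabilities of SIL totals 0-6 (normalised).
#' @param stratum_mortality Death probability for each SIL total.
#' @param male_fraction Probability of male sex.
#' @param shock_fraction Marginal probability of septic shock (coupled to the
#'   SIL stratum but calibrated so the marginal is exact in expectation).
#' @param comorbidity_prevalences Named vector of comorbidity probabilities.
#' @param severity_loading Loading of the standardised SIL stratum on the
#'   latent severity variable driving the comparator-score inputs (0 =
#'   independent, 1 = strongly coupled). Default 0.5.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 299,
                          sil_stratum_probs = c(87, 104, 52, 36, 15, 2, 3) /
                            299,
                          stratum_mortality = c(6 / 87, 15 / 104, 11 / 52,
                                                17 / 36, 8 / 15, 1 / 2, 3 / 3),
                          male_fraction = 124 / 299,
                          shock_fraction = 106 / 299,
                          comorbidity_prevalences = c(
                            hypertension = 132 / 299, diabetes = 71 / 299,
                            renal_insufficiency = 30 / 299,
                            immunosuppression = 60 / 299, copd = 28 / 299),
                          severity_loading = 0.5) {
  if (n < 1) stop_invalid("n", "must be >= 1")
  if (length(sil_stratum_probs) != 7 || length(stratum_mortality) != 7) {
    stop_invalid("sil_stratum_probs", "seven strata (SIL 0-6) are required")
  }
  check_prob(stratum_mortality, "stratum_mortality")
  check_prob(male_fraction, "male_fraction")
  check_prob(shock_fraction, "shock_fraction")
  check_prob(comorbidity_prevalences, "comorbidity_prevalences")
  if (any(sil_stratum_probs < 0) ||
      abs(sum(sil_stratum_probs) - 1) > 1e-6) {
    stop_invalid("sil_stratum_probs", "must be non-negative and sum to 1")
  }
  out <- list(n = as.integer(n),
              sil_stratum_probs = sil_stratum_probs / sum(sil_stratum_probs),
              stratum_mortality = stratum_mortality,
              male_fraction = male_fraction, shock_fraction = shock_fraction,
              comorbidity_prevalences = comorbidity_prevalences,
              severity_loading = severity_loading)
  class(out) <- "cohort_config"
  out
}

# Truncated exponential on [lo, hi] (inverse-CDF; vectorised over u).
rtrunc_exp <- function(u, lo, hi, rate) {
  lo - log(1 - u * (1 - exp(-rate * (hi - lo)))) / rate
}

# Per-stratum shock probabilities proportional to stratum mortality,
# calibrated (with clipping at 1) so the marginal shock fraction equals the
# target exactly in expectation.
calibrate_shock_probs <- function(stratum_probs, mortality, target) {
  k <- length(mortality)
  p <- numeric(k)
  free <- rep(TRUE, k)
  for (iter in seq_len(k + 1)) {
    denom <- sum(stratum_probs[free] * mortality[free])
    rem <- target - sum(stratum_probs[!free] * p[!free])
    if (denom <= 0) {
      tot <- sum(stratum_probs[free])
      p[free] <- if (tot > 0) rem / tot else 0
      break
    }
    scale <- rem / denom
    clipped <- free & (scale * mortality > 1)
    if (!any(clipped)) {
      p[free] <- scale * mortality[free]
      break
    }
    p[clipped] <- 1
    free <- free & !clipped
  }
  pmin(1, pmax(0, p))
}

# Sampling intervals of shock index and lactate for each sub-score value.
# Bottom bands start at physiologic floors; unbounded top bands use a
# truncated exponential with a physiologic cap.
.si_bands <- list(c(0.35, 0.90), c(0.91, 1.35), c(1.36, 1.80), c(1.81, 3.00))
.lactate_bands <- list(c(0.30, 2.00), c(2.01, 4.00), c(4.01, 6.00),
                       c(6.01, 20.00))
.si_top_rate <- 2.0
.lactate_top_rate <- 0.30

sample_in_band <- function(sub_score, bands, top_rate) {
  n <- length(sub_score)
  u <- stats::runif(n)
  lo <- vapply(bands, `[`, numeric(1), 1)[sub_score + 1L]
  hi <- vapply(bands, `[`, numeric(1), 2)[sub_score + 1L]
  x <- ifelse(sub_score == 3L,
              rtrunc_exp(u, lo, hi, top_rate),
              lo + u * (hi - lo))
  round(x, 2)
}

#' Generate a synthetic triage cohort
#'
#' Draws each patient's SIL stratum, splits it uniformly over the valid
#' (shock-index points, lactate points) pairs, samples shock index and
#' lactate inside the corresponding published band, back-solves heart rate
#' and systolic pressure to reproduce the sampled shock index exactly at
#' two-decimal precision, draws death from the stratum mortality, and fills
#' in the remaining vitals, labs, demographics and comorbidities from
#' physiologic distributions tied to a shared latent severity variable.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the generator is fully reproducible.
#' @return data.frame in the cohort schema (see [cohort_schema()]), plus a
#'   bookkeeping column `sil_assigned` holding the drawn stratum.
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  if (missing(seed) || is.null(seed)) stop_invalid("seed", "is mandatory")
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  withr_seed(seed, {
    stratum <- sample(0:6, n, replace = TRUE, prob = config$sil_stratum_probs)
    died <- stats::rbinom(n, 1, config$stratum_mortality[stratum + 1L])

    # uniform split of the stratum total over valid (pis, pl) pairs
    pis <- vapply(stratum, function(t) {
      lo <- max(0L, t - 3L)
      hi <- min(3L, t)
      if (lo == hi) lo else sample(lo:hi, 1L)
    }, integer(1))
    pl <- as.integer(stratum - pis)

    si <- sample_in_band(pis, .si_bands, .si_top_rate)
    lactate <- sample_in_band(pl, .lactate_bands, .lactate_top_rate)

    # back-solve vitals: integer systolic pressure in a physiologic window,
    # heart rate = si * sbp so the rounded ratio reproduces si exactly
    sbp_lo <- pmax(65, ceiling(40 / si))
    sbp_hi <- pmin(170, floor(215 / si))
    sbp_hi <- pmax(sbp_hi, sbp_lo)
    systolic_bp <- sbp_lo + floor(stats::runif(n) * (sbp_hi - sbp_lo + 1))
    heart_rate <- round(si * systolic_bp, 6)

    # latent severity: standardised stratum + noise
    mu_s <- sum(0:6 * config$sil_stratum_probs)
    sd_s <- sqrt(sum((0:6 - mu_s)^2 * config$sil_stratum_probs))
    z <- config$severity_loading * (stratum - mu_s) / max(sd_s, 1e-9) +
      stats::rnorm(n)

    shock_p <- calibrate_shock_probs(config$sil_stratum_probs,
                                     config$stratum_mortality,
                                     config$shock_fraction)
    shock <- stats::rbinom(n, 1, shock_p[stratum + 1L]) == 1

    respiratory_rate <- pmin(45, pmax(8, round(16 + 3.5 * z +
                                                 stats::rnorm(n, 0, 2.5))))
    temperature <- pmin(41, pmax(34, round(37.2 + 0.5 * z +
                                             stats::rnorm(n, 0, 0.7), 1)))
    spo2 <- pmin(100, pmax(70, round(96 - 2.2 * pmax(z, 0) -
                                       stats::rexp(n, 1))))
    supplemental_o2 <- stats::runif(n) < stats::plogis(-1.5 + 0.8 * z)
    gcs <- pmax(3, pmin(15, 15 - stats::rpois(n, exp(-1.3 + 0.9 * z))))

    comorb <- vapply(config$comorbidity_prevalences,
                     function(p) stats::rbinom(n, 1, p) == 1,
                     logical(n))
    comorb <- matrix(comorb, nrow = n,
                     dimnames = list(NULL,
                                     names(config$comorbidity_prevalences)))

    pao2_fio2 <- pmin(520, pmax(60, round(340 - 55 * z +
                                            stats::rnorm(n, 0, 55))))
    platelets <- pmin(650, pmax(8, round(230 * exp(-0.18 * z +
                                                     stats::rnorm(n, 0,
                                                                  0.28)))))
    bilirubin <- pmin(15, pmax(0.1, round(exp(-0.45 + 0.45 * z +
                                                stats::rnorm(n, 0, 0.5)), 2)))
    creatinine <- pmin(12, pmax(0.3, round(
      exp(0.3 * z + stats::rnorm(n, 0, 0.35)) +
        1.5 * comorb[, "renal_insufficiency"], 2)))
    map <- pmin(130, pmax(40, round(0.7 * systolic_bp +
                                      stats::rnorm(n, 0, 6))))
    vaso_levels <- c("none", "dopamine_low", "dopamine_mid",
                     "dopamine_high_or_epi", "high_dose")
    vaso_p_shock <- c(0.30, 0.30, 0.20, 0.15, 0.05)
    vaso_p_sepsis <- c(0.95, 0.03, 0.012, 0.006, 0.002)
    vaso <- vapply(shock, function(s) {
      sample(vaso_levels, 1L, prob = if (s) vaso_p_shock else vaso_p_sepsis)
    }, character(1))

    # age: survivors centre ~72 (IQR 58-80); deaths older, ~74 (IQR 66-86)
    age <- ifelse(died == 1,
                  round(stats::rnorm(n, 75, 13)),
                  round(stats::rnorm(n, 69, 15)))
    age <- pmin(104, pmax(18, age))
    sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")

    cohort <- data.frame(
      id = seq_len(n), age = age, sex = sex,
      heart_rate = heart_rate, systolic_bp = systolic_bp,
      respiratory_rate = respiratory_rate, temperature = temperature,
      spo2 = spo2, supplemental_o2 = supplemental_o2,
      consciousness_gcs = gcs, lactate = lactate,
      pao2_fio2 = pao2_fio2, platelets = platelets, bilirubin = bilirubin,
      mean_arterial_pressure = map, vasopressor_category = vaso,
      creatinine = creatinine,
      comorbidity_hypertension = comorb[, "hypertension"],
      comorbidity_diabetes = comorb[, "diabetes"],
      comorbidity_renal_insufficiency = comorb[, "renal_insufficiency"],
      comorbidity_immunosuppression = comorb[, "immunosuppression"],
      comorbidity_copd = comorb[, "copd"],
      diagnosis_class = ifelse(shock, "septic_shock", "sepsis"),
      died = as.integer(died),
      sil_assigned = as.integer(stratum))
    cohort
  })
}

#' Round-trip consistency check
#'
#' Recomputes the shock index and SIL total from each record's stored heart
#' rate, systolic pressure and lactate and counts records whose recomputed
#' SIL total disagrees with the generator-assigned stratum. The contract for
#' any generated cohort is zero violations.
#'
#' @param cohort A cohort data.frame carrying a `sil_assigned` column.
#' @return Integer count of violating records (0 for an empty cohort).
#' @export
round_trip_check <- function(cohort) {
  if (nrow(cohort) == 0) return(0L)
  if (is.null(cohort$sil_assigned)) {
    stop_invalid("cohort", "no sil_assigned column (not a generated cohort?)")
  }
  si <- shock_index(cohort$heart_rate, cohort$systolic_bp)
  sil <- sil_points(si, cohort$lactate)
  sum(sil$total != cohort$sil_assigned)
}
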