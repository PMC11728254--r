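# NEWS, qSOFA and SOFA comparator calculators.
#
# All three scales are published bedside instruments; the tables below pin
# the published point bands. Functions are vectorised over patients and
# raise a missing-data error naming the absent component, because a missing
# vital silently scored as zero would bias every downstream accuracy
# statistic toward the null.

# TRUE when the patient is fully alert: GCS 15 (numeric input) or AVPU
# "alert"/"a" (character input).
is_alert <- function(consciousness) {
  if (is.numeric(consciousness)) {
    if (any(!is.na(consciousness) &
            (consciousness < 3 | consciousness > 15))) {
      stop_invalid("consciousness", "GCS must be in [3, 15]")
    }
    consciousness == 15
  } else {
    tolower(as.character(consciousness)) %in% c("alert", "a")
  }
}

.news_component <- function(x, breaks, points, name) {
  if (anyNA(x)) stop_missing(name)
  points[findInterval(x, breaks) + 1L]
}

#' National Early Warning Score (NEWS)
#'
#' Seven-component vital-sign aggregate, range 0-20. The default point
#' table is NEWS2 (Royal College of Physicians, 2017, SpO2 Scale 1); the
#' original 2012 NEWS is selectable via `version`, and scores identically on
#' the inputs recorded here (the revisions concern the hypercapnic SpO2
#' scale and "new confusion", neither of which is representable in this
#' schema). A score of 5 or more is the conventional escalation/admission
#' threshold.
#'
#' @param respiratory_rate breaths/min.
#' @param spo2 Peripheral oxygen saturation, percent (0-100).
#' @param supplemental_o2 Logical: any supplemental oxygen.
#' @param temperature Degrees Celsius.
#' @param systolic_bp mmHg.
#' @param heart_rate beats/min.
#' @param consciousness GCS integer 3-15 or AVPU level
#'   (`"alert"`, `"voice"`, `"pain"`, `"unresponsive"`).
#' @param version `"news2"` (default) or `"news2012"`.
#' @return Integer vector of NEWS totals in \[0, 20\].
#' @examples
#' news_points(16, 97, FALSE, 37, 120, 80, "alert")  # 0
#' @export
news_points <- function(respiratory_rate, spo2, supplemental_o2, temperature,
                        systolic_bp, heart_rate, consciousness,
                        version = c("news2", "news2012")) {
  version <- match.arg(version)
  args <- list(respiratory_rate = respiratory_rate, spo2 = spo2,
               supplemental_o2 = supplemental_o2, temperature = temperature,
               systolic_bp = systolic_bp, heart_rate = heart_rate,
               consciousness = consciousness)
  missing <- names(args)[vapply(args, function(a) anyNA(a) || length(a) == 0,
                                logical(1))]
  if (length(missing)) stop_missing(missing)
  if (any(spo2 < 0 | spo2 > 100)) stop_invalid("spo2", "must be in [0, 100]")
  check_positive(heart_rate, "heart_rate")
  check_positive(systolic_bp, "systolic_bp")

  pts <- .news_component(respiratory_rate, c(9, 12, 21, 25),
                         c(3L, 1L, 0L, 2L, 3L), "respiratory_rate") +
    .news_component(spo2, c(92, 94, 96), c(3L, 2L, 1L, 0L), "spo2") +
    ifelse(as.logical(supplemental_o2), 2L, 0L) +
    .news_component(temperature, c(35.05, 36.05, 38.05, 39.05),
                    c(3L, 1L, 0L, 1L, 2L), "temperature") +
    .news_component(systolic_bp, c(91, 101, 111, 220),
                    c(3L, 2L, 1L, 0L, 3L), "systolic_bp") +
    .news_component(heart_rate, c(41, 51, 91, 111, 131),
                    c(3L, 1L, 0L, 1L, 2L, 3L), "heart_rate") +
    ifelse(is_alert(consciousness), 0L, 3L)
  as.integer(pts)
}

#' Quick SOFA (qSOFA)
#'
#' One point each for respiratory rate >= 22/min, systolic blood pressure
#' <= 100 mmHg, and altered mentation (GCS < 15, or any AVPU level other
#' than alert), per the Sepsis-3 operationalisation. Range 0-3.
#'
#' @inheritParams news_points
#' @return Integer vector of qSOFA totals in \[0, 3\].
#' @examples
#' qsofa_points(22, 100, 14)  # 3: every criterion exactly at threshold
#' @export
qsofa_points <- function(respiratory_rate, systolic_bp, consciousness) {
  args <- list(respiratory_rate = respiratory_rate, systolic_bp = systolic_bp,
               consciousness = consciousness)
  missing <- names(args)[vapply(args, function(a) anyNA(a) || length(a) == 0,
                                logical(1))]
  if (length(missing)) stop_missing(missing)
  check_positive(systolic_bp, "systolic_bp")
  as.integer((respiratory_rate >= 22) + (systolic_bp <= 100) +
               !is_alert(consciousness))
}

# Per-system SOFA sub-scores, each 0-4 (1996 published bands).
sofa_respiration <- function(pao2_fio2) {
  4L - findInterval(pao2_fio2, c(100, 200, 300, 400))
}
sofa_coagulation <- function(platelets) {
  4L - findInterval(platelets, c(20, 50, 100, 150))
}
sofa_liver <- function(bilirubin) {
  findInterval(bilirubin, c(1.2, 2.0, 6.0, 12.0))
}
sofa_cardiovascular <- function(mean_arterial_pressure, vasopressor) {
  vp <- c(none = 0L, dopamine_low = 2L, dopamine_mid = 3L,
          dopamine_high_or_epi = 4L, high_dose = 4L)
  if (!all(vasopressor %in% names(vp))) {
    stop_invalid("vasopressor", paste("must be one of",
                                      paste(names(vp), collapse = ", ")))
  }
  base <- ifelse(mean_arterial_pressure < 70, 1L, 0L)
  pmax(base, vp[as.character(vasopressor)], na.rm = FALSE)
}
sofa_cns <- function(gcs) {
  4L - findInterval(gcs, c(6, 10, 13, 15))
}
sofa_renal <- function(creatinine) {
  findInterval(creatinine, c(1.2, 2.0, 3.5, 5.0))
}

#' Sequential Organ Failure Assessment (SOFA)
#'
#' Sum of six organ-system sub-scores (respiration, coagulation, liver,
#' cardiovascular, CNS, renal), each 0-4, total 0-24. Vasopressor dosing is
#' accepted as a pre-binned category rather than a rate in ug/kg/min because
#' triage data sets record the category only; respiratory-support status is
#' likewise not separated from the PaO2/FiO2 bands.
#'
#' In `strict` mode (default) any missing component yields an error listing
#' the absent components, and cohort-level callers propagate `NA` so the
#' record is excluded from SOFA analyses. With `strict = FALSE`, missing
#' systems contribute 0 points (permissive imputation).
#'
#' @param pao2_fio2 PaO2/FiO2 ratio.
#' @param platelets Platelet count, 10^3/uL.
#' @param bilirubin Total bilirubin, mg/dL.
#' @param mean_arterial_pressure mmHg.
#' @param vasopressor One of `"none"`, `"dopamine_low"`, `"dopamine_mid"`,
#'   `"dopamine_high_or_epi"`, `"high_dose"`.
#' @param consciousness GCS integer 3-15 (AVPU accepted and mapped
#'   alert = 15, voice = 13, pain = 9, unresponsive = 5).
#' @param creatinine mg/dL.
#' @param strict Logical; see Details.
#' @return Integer vector of SOFA totals in \[0, 24\].
#' @examples
#' sofa_points(450, 250, 0.8, 80, "none", 15, 0.9)  # 0
#' sofa_points(450, 90, 0.8, 80, "none", 15, 0.9)   # 2 (coagulation)
#' @export
sofa_points <- function(pao2_fio2, platelets, bilirubin,
                        mean_arterial_pressure, vasopressor, consciousness,
                        creatinine, strict = TRUE) {
  gcs <- if (is.numeric(consciousness)) consciousness else {
    c(alert = 15, voice = 13, pain = 9, unresponsive = 5)[
      tolower(as.character(consciousness))]
  }
  args <- list(pao2_fio2 = pao2_fio2, platelets = platelets,
               bilirubin = bilirubin,
               mean_arterial_pressure = mean_arterial_pressure,
               vasopressor = vasopressor, consciousness = gcs,
               creatinine = creatinine)
  missing <- names(args)[vapply(args, function(a) anyNA(a) || length(a) == 0,
                                logical(1))]
  if (length(missing) && strict) stop_missing(missing)

  zero_if_na <- function(x) ifelse(is.na(x), 0L, x)
  vaso <- ifelse(is.na(vasopressor), "none", as.character(vasopressor))
  total <- zero_if_na(sofa_respiration(pao2_fio2)) +
    zero_if_na(sofa_coagulation(platelets)) +
    zero_if_na(sofa_liver(bilirubin)) +
    zero_if_na(sofa_cardiovascular(
      ifelse(is.na(mean_arterial_pressure), 70, mean_arterial_pressure),
      vaso)) +
    zero_if_na(sofa_cns(gcs)) +
    zero_if_na(sofa_renal(creatinine))
  as.integer(total)
}
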