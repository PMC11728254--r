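#' Score a cohort table
#'
#' Appends the SIL breakdown and the NEWS, qSOFA and SOFA comparator scores
#' to a cohort table in the standard column schema (see [cohort_schema()]).
#' SOFA is `NA` for records with missing laboratory components when
#' `sofa_strict = TRUE`; the number of such exclusions is reported via a
#' message.
#'
#' @param cohort A data.frame in the cohort schema.
#' @param news_version Passed to [news_points()].
#' @param sofa_strict Logical; strict (`NA` + exclusion) versus permissive
#'   (score missing systems as 0) handling of absent SOFA inputs.
#' @return The input data.frame with columns `shock_index`, `sil_pis`,
#'   `sil_pl`, `sil_total`, `news`, `qsofa`, `sofa` appended.
#' @export
score_cohort <- function(cohort, news_version = "news2", sofa_strict = TRUE) {
  validate_cohort(cohort)
  si <- shock_index(cohort$heart_rate, cohort$systolic_bp)
  sil <- sil_points(si, cohort$lactate)
  cohort$shock_index <- sil$shock_index
  cohort$sil_pis <- sil$pis
  cohort$sil_pl <- sil$pl
  cohort$sil_total <- sil$total
  cohort$news <- news_points(cohort$respiratory_rate, cohort$spo2,
                             cohort$supplemental_o2, cohort$temperature,
                             cohort$systolic_bp, cohort$heart_rate,
                             cohort$consciousness_gcs,
                             version = news_version)
  cohort$qsofa <- qsofa_points(cohort$respiratory_rate, cohort$systolic_bp,
                               cohort$consciousness_gcs)
  sofa_cols <- c("pao2_fio2", "platelets", "bilirubin",
                 "mean_arterial_pressure", "vasopressor_category",
                 "creatinine", "consciousness_gcs")
  complete <- stats::complete.cases(cohort[sofa_cols])
  sofa <- rep(NA_integer_, nrow(cohort))
  if (any(complete)) {
    cc <- cohort[complete, ]
    sofa[complete] <- sofa_points(cc$pao2_fio2, cc$platelets, cc$bilirubin,
                                  cc$mean_arterial_pressure,
                                  cc$vasopressor_category,
                                  cc$consciousness_gcs, cc$creatinine,
                                  strict = TRUE)
  }
  if (!sofa_strict) {
    inc <- !complete
    if (any(inc)) {
      cc <- cohort[inc, ]
      sofa[inc] <- sofa_points(cc$pao2_fio2, cc$platelets, cc$bilirubin,
                               cc$mean_arterial_pressure,
                               cc$vasopressor_category,
                               cc$consciousness_gcs, cc$creatinine,
                               strict = FALSE)
    }
  } else if (any(!complete)) {
    message(sum(!complete),
            " record(s) lack SOFA components and are scored NA (strict mode)")
  }
  cohort$sofa <- sofa
  cohort
}
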