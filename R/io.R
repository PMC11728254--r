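# Cohort file schema and CSV I/O.
#
# One CSV format (UTF-8, dot decimal, mandatory header) is the sole exchange
# format for cohorts; units are documented in the schema registry rather
# than encoded in the headers.

#' Cohort column schema
#'
#' The registry of cohort columns: name, type, units, and whether the column
#' is mandatory for scoring. Extra columns in a file are passed through
#' untouched.
#'
#' @return data.frame with columns `column`, `type`, `units`, `mandatory`.
#' @export
cohort_schema <- function() {
  data.frame(
    column = c("id", "age", "sex", "heart_rate", "systolic_bp",
               "respiratory_rate", "temperature", "spo2", "supplemental_o2",
               "consciousness_gcs", "lactate", "pao2_fio2", "platelets",
               "bilirubin", "mean_arterial_pressure", "vasopressor_category",
               "creatinine", "comorbidity_hypertension",
               "comorbidity_diabetes", "comorbidity_renal_insufficiency",
               "comorbidity_immunosuppression", "comorbidity_copd",
               "diagnosis_class", "died"),
    type = c("integer", "numeric", "character", "numeric", "numeric",
             "numeric", "numeric", "numeric", "logical", "numeric", "numeric",
             "numeric", "numeric", "numeric", "numeric", "character",
             "numeric", "logical", "logical", "logical", "logical", "logical",
             "character", "integer"),
    units = c("", "years", "male/female", "beats/min", "mmHg", "breaths/min",
              "degC", "percent", "flag", "GCS 3-15", "mmol/L", "ratio",
              "1e3/uL", "mg/dL", "mmHg", "category", "mg/dL", "flag", "flag",
              "flag", "flag", "flag", "sepsis/septic_shock", "0/1"),
    mandatory = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

# Internal: check a data.frame carries the mandatory scoring columns.
validate_cohort <- function(cohort) {
  need <- c("heart_rate", "systolic_bp", "respiratory_rate", "temperature",
            "spo2", "supplemental_o2", "consciousness_gcs", "lactate")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop(sprintf("cohort is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads and type-checks a cohort file against [cohort_schema()]. Rows whose
#' mandatory fields are unparseable or out of contract (e.g. `died` not in
#' 0/1, non-positive heart rate) are rejected with a line-numbered message
#' and the remainder is loaded.
#'
#' @param path CSV file path.
#' @return data.frame of accepted records; attribute `rejected` holds the
#'   indices (file line numbers) of dropped rows.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_invalid("path", paste("no such file:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop_invalid("path", "empty cohort file")
  schema <- cohort_schema()
  missing <- setdiff(schema$column[schema$mandatory], names(raw))
  if (length(missing)) {
    stop(sprintf("schema error: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(raw)) next
    raw[[col]] <- switch(schema$type[i],
                         integer = suppressWarnings(as.integer(raw[[col]])),
                         numeric = suppressWarnings(as.numeric(raw[[col]])),
                         logical = as.logical(raw[[col]]),
                         as.character(raw[[col]]))
  }
  bad <- is.na(raw$heart_rate) | raw$heart_rate <= 0 |
    is.na(raw$systolic_bp) | raw$systolic_bp <= 0 |
    is.na(raw$lactate) | raw$lactate < 0 |
    is.na(raw$died) | !(raw$died %in% c(0L, 1L)) |
    is.na(raw$respiratory_rate) | is.na(raw$temperature) |
    is.na(raw$spo2) | raw$spo2 < 0 | raw$spo2 > 100 |
    is.na(raw$supplemental_o2) |
    is.na(raw$consciousness_gcs) | raw$consciousness_gcs < 3 |
    raw$consciousness_gcs > 15
  if (any(bad)) {
    # +1 for the header line
    message(sprintf("rejected %d row(s) at file line(s): %s", sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")))
  }
  out <- raw[!bad, , drop = FALSE]
  if (nrow(out) == 0) stop_invalid("path", "no valid rows in cohort file")
  rownames(out) <- NULL
  attr(out, "rejected") <- which(bad) + 1L
  out
}

#' Write a cohort CSV
#'
#' @param cohort data.frame in the cohort schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
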