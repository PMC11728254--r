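#' Shock index
#'
#' The shock index is heart rate divided by systolic blood pressure. Values
#' around or above 0.9 suggest haemodynamic compromise. The ratio is rounded
#' to two decimal places so that the published SIL point bands (0-0.90,
#' 0.91-1.35, 1.36-1.80, >= 1.81), printed at two-decimal precision, tile the
#' non-negative line with no gaps.
#'
#' @param heart_rate Heart rate in beats/min (strictly positive).
#' @param systolic_bp Systolic blood pressure in mmHg (strictly positive).
#' @return Numeric vector: `round(heart_rate / systolic_bp, 2)`.
#' @examples
#' shock_index(100, 100)  # 1.00
#' shock_index(145, 80)   # 1.81, the lowest value of the top band
#' @export
shock_index <- function(heart_rate, systolic_bp) {
  check_positive(heart_rate, "heart_rate")
  check_positive(systolic_bp, "systolic_bp")
  if (length(heart_rate) != length(systolic_bp)) {
    stop_invalid("systolic_bp", "length mismatch with heart_rate")
  }
  round(heart_rate / systolic_bp, 2)
}

# Band lower edges at two-decimal precision. A value v (already rounded to
# 2 dp) scores sum(v >= edges) points, so the closed printed intervals are
# exhaustive and non-overlapping.
.sil_si_edges <- c(0.91, 1.36, 1.81)
.sil_lactate_edges <- c(2.01, 4.01, 6.01)

#' SIL score from shock index and lactate
#'
#' The Shock Index/Lactate (SIL) score is the sum of a shock-index sub-score
#' (PIS, 0-3) and an arterial-lactate sub-score (PL, 0-3), giving a total of
#' 0-6. Point bands: shock index 0-0.90 scores 0, 0.91-1.35 scores 1,
#' 1.36-1.80 scores 2, >= 1.81 scores 3; lactate (mmol/L) 0-2.00 scores 0,
#' 2.01-4.00 scores 1, 4.01-6.00 scores 2, >= 6.01 scores 3. Inputs are
#' rounded to two decimals before binning, matching the printed precision of
#' the band edges.
#'
#' @param shock_index Dimensionless heart-rate/systolic-pressure ratio
#'   (non-negative). Typically the output of [shock_index()].
#' @param lactate Arterial lactate in mmol/L (non-negative).
#' @return A data.frame of class `sil_breakdown` with columns `shock_index`,
#'   `lactate`, `pis`, `pl`, `total`.
#' @examples
#' sil_points(0.50, 1.0)   # total 0
#' sil_points(1.90, 7.0)   # total 6 (maximum)
#' sil_points(1.00, 4.5)   # pis 1, pl 2, total 3
#' @export
sil_points <- function(shock_index, lactate) {
  check_nonnegative(shock_index, "shock_index")
  check_nonnegative(lactate, "lactate")
  if (length(shock_index) != length(lactate)) {
    stop_invalid("lactate", "length mismatch with shock_index")
  }
  si <- round(shock_index, 2)
  la <- round(lactate, 2)
  pis <- rowSums(outer(si, .sil_si_edges, `>=`))
  pl <- rowSums(outer(la, .sil_lactate_edges, `>=`))
  out <- data.frame(shock_index = si, lactate = la,
                    pis = as.integer(pis), pl = as.integer(pl),
                    total = as.integer(pis + pl))
  class(out) <- c("sil_breakdown", "data.frame")
  out
}

#' @export
print.sil_breakdown <- function(x, ...) {
  cat("SIL score breakdown (", nrow(x), " record", if (nrow(x) != 1) "s",
      ")\n", sep = "")
  print.data.frame(x, row.names = nrow(x) > 1, ...)
  invisible(x)
}
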