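#' Bootstrap calibration curve for a discrete severity score
#'
#' Fits a single-predictor logistic recalibration model of death on the
#' score, groups patients into bins by score value (bins with fewer than
#' `min_bin_n` patients are merged into the adjacent lower bin, as tiny
#' top strata are common with skewed severity scores), and estimates the
#' sampling variability of per-bin observed mortality by a seeded percentile
#' bootstrap: for each of `reps` resamples of patients with replacement, the
#' per-bin observed death proportion is recomputed, and the 2.5/97.5
#' percentiles across replicates form the band.
#'
#' @param scores Per-patient score values (discrete ordinal).
#' @param outcomes Binary vector, 1 = death.
#' @param reps Bootstrap replicates, default 1000.
#' @param seed Integer seed (mandatory: the band is a resampling quantity).
#' @param min_bin_n Minimum patients per bin before merging, default 5.
#' @return A list of class `calibration_curve`: `bins` (data.frame with
#'   `bin_label`, `score_lo`, `score_hi`, `n`, `predicted`, `observed`,
#'   `band_low`, `band_high`), the fitted `model` coefficients, `reps`,
#'   `seed`, and `merged` (number of merges performed).
#' @export
fit_calibration <- function(scores, outcomes, reps = 1000, seed,
                            min_bin_n = 5) {
  if (missing(seed) || is.null(seed)) stop_invalid("seed", "is mandatory")
  if (reps < 1) stop_invalid("reps", "must be >= 1")
  if (length(unique(outcomes)) < 2) {
    stop_invalid("outcomes", "both outcome classes must be present")
  }
  fit <- stats::glm(outcomes ~ scores, family = stats::binomial())
  pred <- stats::fitted(fit)

  # bin by score value, merging small bins leftward
  vals <- sort(unique(scores))
  counts <- as.integer(table(factor(scores, levels = vals)))
  grp <- seq_along(vals)
  merged <- 0L
  i <- length(vals)
  while (i >= 1) {
    members <- grp == grp[i]
    if (sum(counts[members]) < min_bin_n && any(grp < grp[i])) {
      target <- max(grp[grp < grp[i]])
      grp[members] <- target
      merged <- merged + 1L
      i <- which(grp == target)[1]
    } else i <- which(grp == grp[i])[1] - 1L
  }
  # leftmost bin may still be small; merge it rightward if possible
  first <- grp == grp[1]
  if (sum(counts[first]) < min_bin_n && length(unique(grp)) > 1) {
    grp[first] <- min(grp[!first])
    merged <- merged + 1L
  }
  bin_of_val <- match(grp, sort(unique(grp)))
  bin_idx <- bin_of_val[match(scores, vals)]
  nb <- max(bin_idx)

  bin_n <- tabulate(bin_idx, nb)
  observed <- as.numeric(tapply(outcomes, bin_idx, mean))
  predicted <- as.numeric(tapply(pred, bin_idx, mean))
  lo <- as.numeric(tapply(scores, bin_idx, min))
  hi <- as.numeric(tapply(scores, bin_idx, max))

  n <- length(scores)
  boot <- withr_seed(seed, {
    vapply(seq_len(reps), function(r) {
      ii <- sample.int(n, n, replace = TRUE)
      bi <- bin_idx[ii]
      deaths <- tabulate(bi[outcomes[ii] == 1], nb)
      tot <- tabulate(bi, nb)
      ifelse(tot > 0, deaths / tot, NA_real_)
    }, numeric(nb))
  })
  boot <- matrix(boot, nrow = nb)
  bands <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
                 na.rm = TRUE)

  out <- list(
    bins = data.frame(
      bin_label = ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi)),
      score_lo = lo, score_hi = hi, n = bin_n,
      predicted = predicted, observed = observed,
      band_low = bands[1, ], band_high = bands[2, ]),
    model = stats::coef(fit), reps = reps, seed = seed, merged = merged)
  class(out) <- "calibration_curve"
  out
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve (%d bins, %d bootstrap reps, seed %d",
              nrow(x$bins), x$reps, x$seed))
  if (x$merged > 0) cat(sprintf(", %d small-bin merge(s)", x$merged))
  cat(")\n")
  print.data.frame(x$bins, row.names = FALSE, digits = 3)
  invisible(x)
}
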