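# Diagnostic-accuracy statistics for ordinal severity scores against a
# binary mortality outcome.

#' Construct a stratum table
#'
#' A stratum table holds, for each value of a discrete ordinal score, the
#' number of patients and the number of deaths — the canonical summary of a
#' discrete score's relationship to mortality.
#'
#' @param score_value Integer score values (strictly increasing) — or, in the
#'   two-argument form `stratum_table(scores, outcomes)`, a per-patient score
#'   vector to be tabulated against the binary outcome vector `n_total`.
#' @param n_total Patients per stratum (or per-patient 0/1 outcomes in the
#'   two-argument form).
#' @param n_deaths Deaths per stratum.
#' @param expected_mortality Optional per-stratum expected mortality, percent.
#' @return data.frame of class `stratum_table`.
#' @examples
#' stratum_table(c(0, 1, 2), c(10, 10, 5), c(1, 3, 4))
#' stratum_table(c(0, 0, 1, 2, 2), c(0, 1, 0, 1, 1))  # tabulating form
#' @export
stratum_table <- function(score_value, n_total, n_deaths = NULL,
                          expected_mortality = NULL) {
  if (is.null(n_deaths)) {
    # tabulating form: score_value = per-patient scores, n_total = outcomes
    scores <- score_value
    outcomes <- n_total
    if (length(scores) != length(outcomes) || length(scores) == 0) {
      stop_invalid("outcomes", "must align with scores (length >= 1)")
    }
    if (!all(outcomes %in% c(0, 1))) {
      stop_invalid("outcomes", "must be binary 0/1")
    }
    vals <- sort(unique(scores))
    n_total <- as.integer(table(factor(scores, levels = vals)))
    n_deaths <- as.integer(tapply(outcomes, factor(scores, levels = vals),
                                  sum))
    score_value <- vals
  }
  if (any(n_deaths > n_total) || any(n_total < 0) || any(n_deaths < 0)) {
    stop_invalid("n_deaths", "must satisfy 0 <= n_deaths <= n_total")
  }
  if (is.unsorted(score_value, strictly = TRUE)) {
    stop_invalid("score_value", "must be strictly increasing")
  }
  out <- data.frame(score_value = score_value,
                    n_total = as.integer(n_total),
                    n_deaths = as.integer(n_deaths))
  if (!is.null(expected_mortality)) out$expected_mortality <- expected_mortality
  class(out) <- c("stratum_table", "data.frame")
  out
}

# Expand a stratum table back to per-patient (score, outcome) vectors.
expand_strata <- function(table) {
  scores <- rep(table$score_value, table$n_total)
  outcomes <- unlist(Map(function(n, d) c(rep(1L, d), rep(0L, n - d)),
                         table$n_total, table$n_deaths), use.names = FALSE)
  list(scores = scores, outcomes = as.integer(outcomes))
}

#' Dichotomize a score against an outcome
#'
#' A positive test is `score >= cutoff` (all scales handled here are
#' "higher is worse").
#'
#' @param scores Per-patient score values.
#' @param outcomes Binary vector, 1 = death.
#' @param cutoff Score value at and above which the test is positive.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`
#'   and the `cutoff`.
#' @export
dichotomize <- function(scores, outcomes, cutoff) {
  if (length(scores) == 0) stop_invalid("scores", "empty")
  if (length(scores) != length(outcomes)) {
    stop_invalid("outcomes", "length mismatch with scores")
  }
  if (!all(outcomes %in% c(0, 1))) stop_invalid("outcomes", "must be 0/1")
  pos <- scores >= cutoff
  out <- list(tp = sum(pos & outcomes == 1), fp = sum(pos & outcomes == 0),
              fn = sum(!pos & outcomes == 1), tn = sum(!pos & outcomes == 0),
              cutoff = cutoff)
  class(out) <- "confusion_counts"
  out
}

#' Sensitivity and specificity with binomial confidence intervals
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), each with a 95%
#' binomial CI — Wald ("standard formula") by default, Wilson optionally —
#' clipped to \[0, 1\].
#'
#' @param counts A `confusion_counts` object (or list with tp/fp/fn/tn).
#' @param ci One of `"wald"`, `"wilson"`.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `sensitivity`, `specificity`, each a named vector
#'   `(estimate, ci_low, ci_high)`, plus the input counts.
#' @export
sens_spec <- function(counts, ci = c("wald", "wilson"), conf_level = 0.95) {
  ci <- match.arg(ci)
  with(counts, {
    if (tp + fn < 1) stop_invalid("counts", "no positive outcomes (tp+fn = 0)")
    if (fp + tn < 1) stop_invalid("counts", "no negative outcomes (fp+tn = 0)")
  })
  binom_ci <- function(x, n) {
    p <- x / n
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    if (ci == "wald") {
      half <- z * sqrt(p * (1 - p) / n)
      lo <- p - half; hi <- p + half
    } else {
      den <- 1 + z^2 / n
      ctr <- (p + z^2 / (2 * n)) / den
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
      lo <- ctr - half; hi <- ctr + half
    }
    c(estimate = p, ci_low = max(0, lo), ci_high = min(1, hi))
  }
  list(sensitivity = binom_ci(counts$tp, counts$tp + counts$fn),
       specificity = binom_ci(counts$tn, counts$tn + counts$fp),
       counts = counts)
}

#' Prevalence-adjusted predictive values
#'
#' Post-test probabilities by Bayes' theorem at a stated disease prevalence,
#' rather than from the raw 2x2 counts:
#' \deqn{PPV = \frac{se \cdot p}{se \cdot p + (1-sp)(1-p)}, \qquad
#'       NPV = \frac{sp(1-p)}{sp(1-p) + (1-se)p}.}
#' Setting `prevalence` to the sample prevalence recovers the raw-count
#' predictive values exactly.
#'
#' @param sensitivity,specificity,prevalence Proportions in \[0, 1\].
#' @return Named list `ppv`, `npv`; a predictive value whose denominator is
#'   zero is returned as `NaN` with a warning (undefined, not an error).
#' @export
prevalence_adjusted_pv <- function(sensitivity, specificity, prevalence) {
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  check_prob(prevalence, "prevalence")
  ppv_den <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  npv_den <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (any(ppv_den == 0) || any(npv_den == 0)) {
    warning("predictive value undefined (zero denominator); returning NaN")
  }
  list(ppv = sensitivity * prevalence / ppv_den,
       npv = specificity * (1 - prevalence) / npv_den)
}

#' Full accuracy report at a cutoff
#'
#' Sensitivity, specificity (with CIs) and prevalence-adjusted predictive
#' values for a score dichotomized at a cutoff. When `cutoff` is `NULL`, all
#' observed cutoffs are scanned and the Youden-optimal one
#' (max sensitivity + specificity - 1) is reported.
#'
#' @inheritParams dichotomize
#' @param cutoff Score cutoff, or `NULL` for Youden-optimal.
#' @param prevalence Prevalence used for predictive-value adjustment;
#'   defaults to the sample prevalence.
#' @param ci CI method for sensitivity/specificity.
#' @return A list of class `accuracy_report`.
#' @export
accuracy_report <- function(scores, outcomes, cutoff = NULL,
                            prevalence = NULL, ci = "wald") {
  if (is.null(prevalence)) prevalence <- mean(outcomes)
  if (is.null(cutoff)) {
    cand <- sort(unique(scores))
    youden <- vapply(cand, function(k) {
      cc <- dichotomize(scores, outcomes, k)
      cc$tp / (cc$tp + cc$fn) + cc$tn / (cc$tn + cc$fp) - 1
    }, numeric(1))
    cutoff <- cand[which.max(youden)]
  }
  counts <- dichotomize(scores, outcomes, cutoff)
  ss <- sens_spec(counts, ci = ci)
  pv <- prevalence_adjusted_pv(ss$sensitivity[["estimate"]],
                               ss$specificity[["estimate"]], prevalence)
  out <- list(cutoff = cutoff, sensitivity = ss$sensitivity,
              specificity = ss$specificity, ppv = pv$ppv, npv = pv$npv,
              prevalence = prevalence, counts = counts)
  class(out) <- "accuracy_report"
  out
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy at cutoff >= %s (prevalence %.3f)\n", x$cutoff,
              x$prevalence))
  cat(sprintf("  sensitivity %.3f (%.3f-%.3f)\n", x$sensitivity[["estimate"]],
              x$sensitivity[["ci_low"]], x$sensitivity[["ci_high"]]))
  cat(sprintf("  specificity %.3f (%.3f-%.3f)\n", x$specificity[["estimate"]],
              x$specificity[["ci_low"]], x$specificity[["ci_high"]]))
  cat(sprintf("  PPV %.3f  NPV %.3f (prevalence-adjusted)\n", x$ppv, x$npv))
  cat(sprintf("  counts: tp %d fp %d fn %d tn %d\n", x$counts$tp, x$counts$fp,
              x$counts$fn, x$counts$tn))
  invisible(x)
}

#' Odds ratio from a 2x2 exposure-outcome table
#'
#' Cross-product odds ratio with a Wald log-scale confidence interval. The
#' Haldane-Anscombe 0.5 correction is applied to every cell when any cell is
#' zero.
#'
#' @param exposed_deaths,exposed_survivors,unexposed_deaths,unexposed_survivors
#'   Non-negative counts.
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `association_result`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value` (chi-square test of independence).
#' @export
odds_ratio_2x2 <- function(exposed_deaths, exposed_survivors,
                           unexposed_deaths, unexposed_survivors,
                           conf_level = 0.95) {
  cells <- c(exposed_deaths, exposed_survivors, unexposed_deaths,
             unexposed_survivors)
  check_nonnegative(cells, "counts")
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_invalid("counts", "all-zero margin")
  }
  if (any(cells == 0)) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- a * d / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- chi_square_2x2(matrix(c(exposed_deaths, exposed_survivors,
                               unexposed_deaths, unexposed_survivors),
                             nrow = 2, byrow = TRUE))
  out <- list(odds_ratio = or, ci_low = or * exp(-z * se),
              ci_high = or * exp(z * se), p_value = p)
  class(out) <- "association_result"
  out
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n", x$odds_ratio,
              x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction by default
#' (the convention of most statistical environments for 2x2 tables).
#'
#' @param counts 2x2 matrix of non-negative counts, or a `confusion_counts`
#'   list.
#' @param correct Apply the Yates continuity correction.
#' @return The two-sided p-value.
#' @export
chi_square_2x2 <- function(counts, correct = TRUE) {
  if (inherits(counts, "confusion_counts")) {
    counts <- matrix(c(counts$tp, counts$fp, counts$fn, counts$tn), nrow = 2,
                     byrow = TRUE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_invalid("counts", "zero margin")
  }
  suppressWarnings(stats::chisq.test(counts, correct = correct)$p.value)
}

#' Per-stratum observed mortality
#'
#' Observed mortality percent for each score value, plus the overall rate,
#' and a monotonicity report (is mortality non-decreasing in the score?).
#'
#' @param table A `stratum_table`.
#' @return List: `by_stratum` (data.frame with `score_value`, `n_total`,
#'   `n_deaths`, `mortality_pct`), `overall_pct`, `monotone`.
#' @export
stratum_mortality <- function(table) {
  if (!nrow(table)) stop_invalid("table", "empty stratum table")
  pct <- 100 * table$n_deaths / table$n_total
  list(by_stratum = data.frame(score_value = table$score_value,
                               n_total = table$n_total,
                               n_deaths = table$n_deaths,
                               mortality_pct = pct),
       overall_pct = 100 * sum(table$n_deaths) / sum(table$n_total),
       monotone = !is.unsorted(pct))
}

#' Expected versus observed stratum mortality
#'
#' Side-by-side expected and observed mortality percent per stratum, with an
#' exact (Clopper-Pearson) binomial confidence interval on the observed
#' proportion — small strata (n = 2 or 3 occur in practice) make the Wald
#' interval useless here.
#'
#' @param table A `stratum_table` carrying an `expected_mortality` column.
#' @param conf_level Confidence level, default 0.95.
#' @return data.frame: `score_value`, `expected_pct`, `found_pct`,
#'   `found_ci_low`, `found_ci_high`, `difference_pct`, `n_total`.
#' @export
expected_vs_found <- function(table, conf_level = 0.95) {
  if (is.null(table$expected_mortality)) {
    stop_invalid("table", "expected_mortality column is required")
  }
  found <- 100 * table$n_deaths / table$n_total
  cis <- t(mapply(function(x, n) {
    as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
  }, table$n_deaths, table$n_total))
  data.frame(score_value = table$score_value,
             expected_pct = table$expected_mortality,
             found_pct = found,
             found_ci_low = 100 * cis[, 1],
             found_ci_high = 100 * cis[, 2],
             difference_pct = found - table$expected_mortality,
             n_total = table$n_total)
}
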