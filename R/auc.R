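# Empirical ROC/AUC machinery for ordinal scores against binary mortality.
#
# The empirical AUC is the Mann-Whitney concordance probability: the chance
# that a randomly chosen death scores higher than a randomly chosen
# survivor, ties counted one half. Confidence intervals use the DeLong
# structural-component variance by default (the standard nonparametric
# method for correlated empirical ROC curves) or a seeded percentile
# bootstrap; paired curves are compared with the paired DeLong z-test.

# DeLong structural components via midranks: O(n log n), exact for ties.
# Returns auc, per-case components v10, per-control components v01, variance.
delong_components <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  case <- outcomes == 1
  m <- sum(case); n <- sum(!case)
  if (m == 0 || n == 0) {
    stop_invalid("outcomes", "both outcome classes must be present")
  }
  x <- scores[case]; y <- scores[!case]
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v10 <- (r_all[seq_len(m)] - r_x) / n             # P(X_i > Y) + 0.5 ties
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m     # P(X > Y_j) + 0.5 ties
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = auc, v10 = v10, v01 = v01, var = var_auc, m = m, n = n)
}

#' Empirical AUC of a discrete score
#'
#' Computes the tie-corrected concordance AUC, equal to the trapezoidal area
#' under the empirical ROC curve. Accepts either a [stratum_table()] (counts
#' per score value) or per-patient `scores` and `outcomes` vectors.
#'
#' @param table A `stratum_table`, or a per-patient score vector.
#' @param outcomes Binary outcome vector when `table` is a score vector.
#' @return The AUC as a single number in \[0, 1\].
#' @examples
#' tab <- stratum_table(c(0, 1), c(5, 5), c(0, 5))
#' empirical_auc(tab)  # 1: all deaths above all survivors
#' @export
empirical_auc <- function(table, outcomes = NULL) {
  if (inherits(table, "stratum_table")) {
    d <- table$n_deaths
    s <- table$n_total - table$n_deaths
    D <- sum(d); S <- sum(s)
    if (D == 0 || S == 0) {
      stop_invalid("table", "both outcome classes must be present")
    }
    cum_s <- cumsum(c(0, s[-length(s)]))  # survivors strictly below stratum
    (sum(d * cum_s) + 0.5 * sum(d * s)) / (D * S)
  } else {
    delong_components(table, outcomes)$auc
  }
}

#' AUC with confidence interval
#'
#' DeLong asymptotic CI by default; seeded percentile bootstrap optionally.
#' CIs are clipped to \[0, 1\] (degenerate at perfect separation).
#'
#' @param scores Per-patient score values.
#' @param outcomes Binary vector, 1 = death.
#' @param method `"delong"` or `"bootstrap"`.
#' @param reps Bootstrap replicates (bootstrap method only).
#' @param seed Integer seed (bootstrap method only; required there).
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `auc_estimate`: `auc`, `ci_low`, `ci_high`,
#'   `method`.
#' @export
auc_ci <- function(scores, outcomes, method = c("delong", "bootstrap"),
                   reps = 1000, seed = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  dl <- delong_components(scores, outcomes)
  alpha <- 1 - conf_level
  if (method == "delong") {
    z <- stats::qnorm(1 - alpha / 2)
    half <- z * sqrt(dl$var)
    ci <- c(dl$auc - half, dl$auc + half)
  } else {
    if (reps < 1) stop_invalid("reps", "must be >= 1")
    if (is.null(seed)) stop_invalid("seed", "required for bootstrap")
    idx_case <- which(outcomes == 1)
    idx_ctrl <- which(outcomes == 0)
    boot <- withr_seed(seed, {
      vapply(seq_len(reps), function(i) {
        ii <- c(sample(idx_case, replace = TRUE),
                sample(idx_ctrl, replace = TRUE))
        delong_components(scores[ii], outcomes[ii])$auc
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  }
  out <- list(auc = dl$auc, ci_low = max(0, min(ci[1], dl$auc)),
              ci_high = min(1, max(ci[2], dl$auc)), method = method)
  class(out) <- "auc_estimate"
  out
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f, %s)\n", x$auc, x$ci_low,
              x$ci_high, x$method))
  invisible(x)
}

#' Paired DeLong comparison of two AUCs
#'
#' Two-sided z-test of equal AUC for two scores measured on the same
#' patients, accounting for their correlation through the DeLong
#' structural-component covariance.
#'
#' @param scores_a,scores_b Paired per-patient score vectors.
#' @param outcomes Binary vector, 1 = death.
#' @return List: `p_value`, `auc_a`, `auc_b`, `delta`, `z`.
#' @export
compare_auc <- function(scores_a, scores_b, outcomes) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(outcomes)) {
    stop_invalid("scores_b", "scores must be paired on identical patients")
  }
  a <- delong_components(scores_a, outcomes)
  b <- delong_components(scores_b, outcomes)
  cov_ab <- stats::cov(a$v10, b$v10) / a$m + stats::cov(a$v01, b$v01) / a$n
  var_delta <- a$var + b$var - 2 * cov_ab
  delta <- a$auc - b$auc
  if (var_delta <= .Machine$double.eps) {
    z <- 0
    p <- 1
    if (abs(delta) > .Machine$double.eps^0.5) {
      # identical variance structure but different AUCs: degenerate
      z <- sign(delta) * Inf
      p <- 0
    }
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p_value = p, auc_a = a$auc, auc_b = b$auc, delta = delta, z = z)
}

#' Empirical ROC curve points
#'
#' (FPR, TPR) pairs at every cutoff of a discrete score, from (1, 1) down to
#' (0, 0), suitable for plotting or CSV export.
#'
#' @inheritParams auc_ci
#' @return data.frame with columns `cutoff`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, outcomes) {
  vals <- sort(unique(scores))
  rows <- lapply(c(vals, Inf), function(k) {
    cc <- dichotomize(scores, outcomes, k)
    data.frame(cutoff = k, fpr = cc$fp / (cc$fp + cc$tn),
               tpr = cc$tp / (cc$tp + cc$fn))
  })
  out <- do.call(rbind, c(list(data.frame(cutoff = -Inf, fpr = 1, tpr = 1)),
                          rows))
  out[nrow(out):1, , drop = FALSE]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
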