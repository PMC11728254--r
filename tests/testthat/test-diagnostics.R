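ref_tab <- reference_stratum_table()
ref <- expand_table(ref_tab)

test_that("dichotomize partitions the cohort at score >= cutoff", {
  cc <- dichotomize(c(0, 6), c(0, 1), 3)
  expect_identical(cc[c("tp", "fp", "fn", "tn")],
                   list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  cc <- dichotomize(c(0, 1, 2), c(0, 1, 0), 5)  # all below cutoff
  expect_identical(cc$tp, 0L)
  expect_identical(cc$fp, 0L)
  # reference stratum table expanded to 299 patients, cutoff 3
  cc <- dichotomize(ref$scores, ref$outcomes, 3)
  expect_identical(cc[c("tp", "fp", "fn", "tn")],
                   list(tp = 29L, fp = 27L, fn = 32L, tn = 211L))
  expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 299L)
  expect_error(dichotomize(numeric(0), numeric(0), 1), "empty")
  expect_error(dichotomize(1:3, 1:2 * 0, 1), "length mismatch")
})

test_that("ROC endpoints: cutoff -Inf / +Inf give the degenerate corners", {
  set.seed(3)
  rc <- random_cohort_vectors(60)
  lo <- sens_spec(dichotomize(rc$scores, rc$outcomes, -Inf))
  hi <- sens_spec(dichotomize(rc$scores, rc$outcomes, Inf))
  expect_equal(unname(lo$sensitivity["estimate"]), 1)
  expect_equal(unname(lo$specificity["estimate"]), 0)
  expect_equal(unname(hi$sensitivity["estimate"]), 0)
  expect_equal(unname(hi$specificity["estimate"]), 1)
})

test_that("sens_spec computes proportions with clipped binomial CIs", {
  ss <- sens_spec(dichotomize(c(0, 6), c(0, 1), 3))
  expect_equal(unname(ss$sensitivity["estimate"]), 1)
  expect_equal(unname(ss$specificity["estimate"]), 1)
  expect_lte(ss$sensitivity[["ci_high"]], 1)
  ss <- sens_spec(list(tp = 29, fp = 27, fn = 32, tn = 211))
  expect_equal(unname(ss$sensitivity["estimate"]), 29 / 61, tolerance = 1e-12)
  expect_equal(unname(ss$specificity["estimate"]), 211 / 238,
               tolerance = 1e-12)
  ss <- sens_spec(list(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_equal(unname(ss$sensitivity["estimate"]), 0)
  expect_equal(unname(ss$specificity["estimate"]), 1)
  expect_error(sens_spec(list(tp = 0, fp = 1, fn = 0, tn = 1)), "tp\\+fn")
  # Wilson interval is narrower than Wald near the boundary and never clips
  w <- sens_spec(list(tp = 19, fp = 10, fn = 1, tn = 30), ci = "wilson")
  expect_gt(w$sensitivity[["ci_low"]], 0)
  expect_lt(w$sensitivity[["ci_high"]], 1)
})

test_that("prevalence-adjusted predictive values follow Bayes' theorem", {
  pv <- prevalence_adjusted_pv(1, 1, 0.5)
  expect_equal(pv$ppv, 1)
  expect_equal(pv$npv, 1)
  # published sensitivity/specificity rows at the study prevalence 61/299
  pv <- prevalence_adjusted_pv(0.694, 0.678, 61 / 299)
  expect_equal(pv$ppv, 0.3558376, tolerance = 1e-6)
  expect_equal(pv$npv, 0.8963173, tolerance = 1e-6)
  pv <- prevalence_adjusted_pv(0.628, 0.595, 61 / 299)
  expect_equal(pv$ppv, 0.2843990, tolerance = 1e-6)
  expect_equal(pv$npv, 0.8618877, tolerance = 1e-6)
  expect_warning(prevalence_adjusted_pv(1, 1, 0), "undefined")
  expect_error(prevalence_adjusted_pv(1.2, 0.5, 0.5), "sensitivity")
})

test_that("adjustment at the sample prevalence equals raw-count PVs", {
  set.seed(11)
  for (i in 1:20) {
    rc <- random_cohort_vectors(80)
    cut <- sample(1:6, 1)
    cc <- dichotomize(rc$scores, rc$outcomes, cut)
    if (cc$tp + cc$fp == 0 || cc$tn + cc$fn == 0) next
    ss <- sens_spec(cc)
    pv <- prevalence_adjusted_pv(ss$sensitivity[["estimate"]],
                                 ss$specificity[["estimate"]],
                                 mean(rc$outcomes))
    expect_equal(pv$ppv, cc$tp / (cc$tp + cc$fp), tolerance = 1e-12)
    expect_equal(pv$npv, cc$tn / (cc$tn + cc$fn), tolerance = 1e-12)
  }
})

test_that("odds_ratio_2x2 reproduces the comorbidity associations", {
  # symmetric table
  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$odds_ratio, 1)
  # renal insufficiency row: OR 4.13 (printed 4.11), CI ~ (1.89, 9.05)
  renal <- odds_ratio_2x2(14, 16, 47, 222)
  expect_equal(renal$odds_ratio, 4.132979, tolerance = 1e-6)
  expect_equal(renal$ci_low, 1.888, tolerance = 1e-3)
  expect_equal(renal$ci_high, 9.046, tolerance = 1e-3)
  expect_lt(renal$p_value, 0.001)
  # septic shock row: OR 6.01 (printed 5.94)
  shock <- odds_ratio_2x2(42, 64, 19, 174)
  expect_equal(shock$odds_ratio, 6.009868, tolerance = 1e-6)
  expect_lt(shock$p_value, 0.001)
  expect_error(odds_ratio_2x2(0, 0, 5, 5), "margin")
})

test_that("odds ratio invariances hold on random tables (property)", {
  set.seed(5)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    a <- do.call(odds_ratio_2x2, as.list(cells))
    # swap both rows and both columns simultaneously: unchanged
    b <- odds_ratio_2x2(cells[4], cells[3], cells[2], cells[1])
    expect_equal(a$odds_ratio, b$odds_ratio, tolerance = 1e-12)
    # swap exposure labels: reciprocal
    c <- odds_ratio_2x2(cells[3], cells[4], cells[1], cells[2])
    expect_equal(a$odds_ratio, 1 / c$odds_ratio, tolerance = 1e-12)
  }
  # Haldane-Anscombe correction engages on zero cells
  z <- odds_ratio_2x2(0, 10, 5, 10)
  expect_true(is.finite(z$odds_ratio) && z$odds_ratio > 0)
})

test_that("chi_square_2x2 matches expectations and correction property", {
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2)), 1)
  expect_lt(chi_square_2x2(matrix(c(42, 64, 19, 174), 2, byrow = TRUE)),
            0.001)
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(rpois(4, 15) + 1, 2)
    pc <- chi_square_2x2(m, correct = TRUE)
    pu <- chi_square_2x2(m, correct = FALSE)
    expect_gte(pc, pu)  # corrected statistic <= uncorrected => larger p
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("stratum_mortality reproduces the Found column", {
  m <- stratum_mortality(ref_tab)
  expect_equal(m$by_stratum$mortality_pct[4], 100 * 17 / 36)  # 47.2%
  expect_equal(m$by_stratum$mortality_pct[7], 100)            # 3/3
  expect_equal(m$overall_pct, 100 * 61 / 299)                 # 20.4%
  zero <- stratum_table(0:2, c(5L, 5L, 5L), c(0L, 0L, 0L))
  expect_true(all(stratum_mortality(zero)$by_stratum$mortality_pct == 0))
  expect_error(stratum_mortality(ref_tab[0, ]), "empty")
})

test_that("expected_vs_found compares columns with exact binomial CIs", {
  evf <- expected_vs_found(ref_tab)
  expect_equal(evf$found_pct, 100 * ref_tab$n_deaths / ref_tab$n_total)
  expect_equal(evf$expected_pct, ref_tab$expected_mortality)
  # expected = observed exactly -> zero differences
  t2 <- stratum_table(0:1, c(10L, 10L), c(2L, 5L),
                      expected_mortality = c(20, 50))
  expect_true(all(expected_vs_found(t2)$difference_pct == 0))
  # n = 2 stratum has an exact CI spanning >= 50 percentage points
  n2 <- evf[evf$n_total == 2, ]
  expect_gte(n2$found_ci_high - n2$found_ci_low, 50)
  tab_no_exp <- stratum_table(0:1, c(5L, 5L), c(1L, 2L))
  expect_error(expected_vs_found(tab_no_exp), "expected_mortality")
})

test_that("accuracy_report scans cutoffs and reports the Youden optimum", {
  rep3 <- accuracy_report(ref$scores, ref$outcomes, cutoff = 3)
  expect_equal(rep3$counts$tp, 29L)
  auto <- accuracy_report(ref$scores, ref$outcomes)
  youden <- function(k) {
    cc <- dichotomize(ref$scores, ref$outcomes, k)
    cc$tp / (cc$tp + cc$fn) + cc$tn / (cc$tn + cc$fp) - 1
  }
  expect_equal(youden(auto$cutoff), max(sapply(0:6, youden)))
  # prevalence defaults to the sample prevalence
  expect_equal(auto$prevalence, 61 / 299)
})
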