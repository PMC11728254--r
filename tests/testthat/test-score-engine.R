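test_that("shock_index is the rounded HR/SBP ratio and validates input", {
  expect_equal(shock_index(100, 100), 1.00)
  expect_equal(shock_index(90, 100), 0.90)
  expect_equal(shock_index(145, 80), 1.81)  # lands on the top band edge
  expect_equal(shock_index(c(100, 145), c(100, 80)), c(1.00, 1.81))
  expect_error(shock_index(0, 100), "heart_rate")
  expect_error(shock_index(100, -5), "systolic_bp")
  expect_error(shock_index(NA, 100), "heart_rate")
})

test_that("sil_points reproduces the published bands and boundaries", {
  cases <- data.frame(
    si = c(0.50, 1.90, 1.00, 0.90, 0.91, 1.35, 1.36, 1.80, 1.81),
    la = c(1.0, 7.0, 4.5, 2.00, 2.01, 4.00, 4.01, 6.00, 6.01),
    pis = c(0L, 3L, 1L, 0L, 1L, 1L, 2L, 2L, 3L),
    pl = c(0L, 3L, 2L, 0L, 1L, 1L, 2L, 2L, 3L))
  got <- sil_points(cases$si, cases$la)
  expect_equal(got$pis, cases$pis)
  expect_equal(got$pl, cases$pl)
  expect_equal(got$total, cases$pis + cases$pl)
  expect_error(sil_points(-0.1, 1), "shock_index")
  expect_error(sil_points(1, -1), "lactate")
})

test_that("sil_points is monotone and bins tile the line (property)", {
  si_grid <- seq(0, 3.5, by = 0.01)
  la_grid <- seq(0, 22, by = 0.01)
  pis <- sil_points(si_grid, rep(1, length(si_grid)))$pis
  pl <- sil_points(rep(0.5, length(la_grid)), la_grid)$pl
  # monotone non-decreasing, every value in 0..3, steps of at most 1
  expect_true(all(diff(pis) >= 0) && all(diff(pl) >= 0))
  expect_true(all(pis %in% 0:3) && all(pl %in% 0:3))
  expect_true(all(diff(pis) <= 1) && all(diff(pl) <= 1))
  # totals stay in range and equal the sum of sub-scores on random pairs
  set.seed(42)
  si <- runif(500, 0, 4); la <- runif(500, 0, 25)
  bd <- sil_points(si, la)
  expect_true(all(bd$total == bd$pis + bd$pl))
  expect_true(all(bd$total >= 0 & bd$total <= 6))
})

test_that("news_points matches the pinned bands and flags >= 5", {
  # all components in the zero band
  expect_identical(news_points(16, 97, FALSE, 37, 120, 80, "alert"), 0L)
  # single 3-point abnormalities, one component at a time
  expect_identical(news_points(25, 97, FALSE, 37, 120, 80, "alert"), 3L)
  expect_identical(news_points(16, 91, FALSE, 37, 120, 80, "alert"), 3L)
  expect_identical(news_points(16, 97, FALSE, 34.9, 120, 80, "alert"), 3L)
  expect_identical(news_points(16, 97, FALSE, 37, 90, 80, "alert"), 3L)
  expect_identical(news_points(16, 97, FALSE, 37, 120, 135, "alert"), 3L)
  expect_identical(news_points(16, 97, FALSE, 37, 120, 80, 14), 3L)
  # supplemental oxygen scores 2
  expect_identical(news_points(16, 97, TRUE, 37, 120, 80, "alert"), 2L)
  # a severe patient crosses the admission threshold of 5
  severe <- news_points(24, 92, TRUE, 38.5, 95, 115, "voice")
  expect_gte(severe, 5L)
  # worst case hits the published maximum of 20
  expect_identical(news_points(30, 80, TRUE, 34, 60, 140, 3), 20L)
  expect_error(news_points(NA, 97, FALSE, 37, 120, 80, "alert"),
               "respiratory_rate")
  # both versions agree on representable inputs
  expect_identical(news_points(24, 92, TRUE, 38.5, 95, 115, "voice"),
                   news_points(24, 92, TRUE, 38.5, 95, 115, "voice",
                               version = "news2012"))
})

test_that("qsofa_points scores the three Sepsis-3 criteria", {
  expect_identical(qsofa_points(16, 130, "alert"), 0L)
  expect_identical(qsofa_points(22, 100, 14), 3L)  # all exactly at threshold
  expect_identical(qsofa_points(22, 130, "alert"), 1L)
  expect_identical(qsofa_points(21, 101, 15), 0L)  # all just below
  expect_error(qsofa_points(16, NA, "alert"), "systolic_bp")
})

test_that("sofa_points sums the six organ systems per the published bands", {
  expect_identical(sofa_points(450, 250, 0.8, 80, "none", 15, 0.9), 0L)
  expect_identical(sofa_points(450, 90, 0.8, 80, "none", 15, 0.9), 2L)
  expect_identical(sofa_points(50, 10, 15, 50, "high_dose", 3, 8), 24L)
  # each system alone
  expect_identical(sofa_points(250, 250, 0.8, 80, "none", 15, 0.9), 2L)
  expect_identical(sofa_points(450, 250, 2.5, 80, "none", 15, 0.9), 2L)
  expect_identical(sofa_points(450, 250, 0.8, 60, "none", 15, 0.9), 1L)
  expect_identical(sofa_points(450, 250, 0.8, 80, "dopamine_mid", 15, 0.9), 3L)
  expect_identical(sofa_points(450, 250, 0.8, 80, "none", 11, 0.9), 2L)
  expect_identical(sofa_points(450, 250, 0.8, 80, "none", 15, 3.6), 3L)
  # strict mode errors on missing components, permissive scores them 0
  expect_error(sofa_points(NA, 250, 0.8, 80, "none", 15, 0.9), "pao2_fio2")
  expect_identical(sofa_points(NA, 250, 0.8, 80, "none", 15, 3.6,
                               strict = FALSE), 3L)
})

test_that("score panel stays within published ranges on random cohorts", {
  set.seed(7)
  co <- generate_cohort(cohort_config(n = 400), seed = 99)
  sc <- score_cohort(co)
  expect_true(all(sc$news >= 0 & sc$news <= 20))
  expect_true(all(sc$qsofa >= 0 & sc$qsofa <= 3))
  expect_true(all(sc$sofa >= 0 & sc$sofa <= 24, na.rm = TRUE))
  expect_true(all(sc$sil_total == sc$sil_pis + sc$sil_pl))
  expect_true(all(sc$sil_total >= 0 & sc$sil_total <= 6))
})
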