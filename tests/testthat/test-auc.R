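ref_tab <- reference_stratum_table()
ref <- expand_table(ref_tab)

test_that("empirical_auc handles the degenerate cases", {
  perfect <- stratum_table(c(0L, 1L), c(5L, 5L), c(0L, 5L))
  expect_equal(empirical_auc(perfect), 1)
  single <- stratum_table(2L, 10L, 4L)
  expect_equal(empirical_auc(single), 0.5)  # pure ties
  expect_equal(empirical_auc(rep(3, 10), rep(c(0, 1), 5)), 0.5)
  all_dead <- stratum_table(0:1, c(3L, 3L), c(3L, 3L))
  expect_error(empirical_auc(all_dead), "both outcome classes")
})

test_that("empirical_auc on the reference table equals the pair oracle", {
  expect_equal(empirical_auc(ref_tab), 10789 / 14518, tolerance = 1e-12)
  expect_equal(empirical_auc(ref_tab),
               auc_pair_oracle(ref$scores, ref$outcomes), tolerance = 1e-12)
  # per-patient form agrees with the stratum-table form
  expect_equal(empirical_auc(ref$scores, ref$outcomes), empirical_auc(ref_tab),
               tolerance = 1e-12)
})

test_that("empirical_auc equals brute-force pair counting on 200 random
           small cohorts (property)", {
  set.seed(2024)
  for (i in 1:200) {
    rc <- random_cohort_vectors(sample(5:50, 1))
    expect_equal(empirical_auc(rc$scores, rc$outcomes),
                 auc_pair_oracle(rc$scores, rc$outcomes), tolerance = 1e-12)
  }
})

test_that("AUC symmetry and monotone-transform invariance (property)", {
  set.seed(77)
  for (i in 1:30) {
    rc <- random_cohort_vectors(40)
    a <- empirical_auc(rc$scores, rc$outcomes)
    # flipping the score flips the AUC
    expect_equal(empirical_auc(-rc$scores, rc$outcomes), 1 - a,
                 tolerance = 1e-12)
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(empirical_auc(exp(rc$scores / 2), rc$outcomes), a,
                 tolerance = 1e-12)
    expect_equal(empirical_auc(rc$scores * 10 + 3, rc$outcomes), a,
                 tolerance = 1e-12)
  }
})

test_that("auc_ci brackets the estimate and clips at perfect separation", {
  scores <- c(rep(0, 20), rep(1, 20))
  outcomes <- c(rep(0, 20), rep(1, 20))
  est <- auc_ci(scores, outcomes)
  expect_equal(est$auc, 1)
  expect_lte(est$ci_high, 1)
  expect_lte(est$ci_low, est$auc)
  # constant score: AUC 0.5
  est <- auc_ci(rep(2, 40), rep(c(0, 1), 20))
  expect_equal(est$auc, 0.5)
  # DeLong CI on the reference cohort covers the closed-form AUC
  est <- auc_ci(ref$scores, ref$outcomes)
  expect_lt(est$ci_low, 10789 / 14518)
  expect_gt(est$ci_high, 10789 / 14518)
  # bootstrap is seeded and reproducible
  b1 <- auc_ci(ref$scores, ref$outcomes, method = "bootstrap", reps = 100,
               seed = 4)
  b2 <- auc_ci(ref$scores, ref$outcomes, method = "bootstrap", reps = 100,
               seed = 4)
  expect_identical(b1, b2)
  expect_lt(b1$ci_low, b1$ci_high)
  expect_error(auc_ci(ref$scores, ref$outcomes, method = "bootstrap",
                      reps = 10), "seed")
})

test_that("compare_auc: identical scores give p = 1, separation gives p ~ 0", {
  expect_equal(compare_auc(ref$scores, ref$scores, ref$outcomes)$p_value, 1)
  n <- 200
  outcomes <- rep(c(0, 1), n / 2)
  perfect <- outcomes  # perfectly discriminating
  constant <- rep(1, n)
  expect_lt(compare_auc(perfect, constant, outcomes)$p_value, 0.001)
  expect_error(compare_auc(1:5, 1:4, c(0, 1, 0, 1, 0)), "paired")
})

test_that("compare_auc p-values are roughly uniform under H0 (simulation)", {
  set.seed(303)
  ps <- replicate(200, {
    latent <- rnorm(150)
    outcomes <- rbinom(150, 1, plogis(latent))
    if (length(unique(outcomes)) < 2) return(NA_real_)
    a <- latent + rnorm(150)
    b <- latent + rnorm(150)  # exchangeable noisy copies: H0 true
    compare_auc(a, b, outcomes)$p_value
  })
  ps <- ps[!is.na(ps)]
  # under H0 about 5% of p-values fall below 0.05; allow wide binomial slack
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
})

test_that("roc_points spans (0,0) to (1,1) and is monotone", {
  rp <- roc_points(ref$scores, ref$outcomes)
  expect_equal(rp$fpr[1], 0)
  expect_equal(rp$tpr[1], 0)
  expect_equal(rp$fpr[nrow(rp)], 1)
  expect_equal(rp$tpr[nrow(rp)], 1)
  expect_true(!is.unsorted(rp$fpr) && !is.unsorted(rp$tpr))
})
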