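test_that("empirical AUC matches brute-force pair counting and its symmetry", {
  expect_equal(empirical_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(empirical_auc(rep(5, 10), rep(0:1, 5)), 0.5)
  expect_error(empirical_auc(1:4, rep(1, 4)), "both classes")

  set.seed(7)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    scores <- round(rnorm(n, 0, 2), 1) # rounding forces some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    a <- empirical_auc(scores, labels)
    expect_equal(a, pair_count_auc(scores, labels))
    expect_equal(a + empirical_auc(-scores, labels), 1.0)
  }
})

test_that("DeLong variance agrees with the bootstrap and CIs behave", {
  sep <- delong_variance_and_ci(c(1, 2, 3, 10, 11, 12),
                                c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1.0)
  expect_equal(sep$se, 0)

  set.seed(11)
  n <- 50
  y <- rep(0:1, each = n / 2)
  s <- c(rnorm(n / 2, 0, 1), rnorm(n / 2, 1, 1))
  dl <- delong_variance_and_ci(s, y)
  expect_gte(dl$auc, dl$ci95[1])
  expect_lte(dl$auc, dl$ci95[2])

  boot <- replicate(2000, {
    i0 <- sample(which(y == 0), replace = TRUE)
    i1 <- sample(which(y == 1), replace = TRUE)
    empirical_auc(s[c(i0, i1)], y[c(i0, i1)])
  })
  expect_lt(abs(dl$se - sd(boot)) / sd(boot), 0.15)

  logit <- delong_variance_and_ci(s, y, logit_scale = TRUE)
  expect_gt(logit$ci95[1], 0)
  expect_lt(logit$ci95[2], 1)
})

test_that("paired DeLong test is zero for identical predictors and antisymmetric", {
  set.seed(12)
  y <- rep(0:1, each = 15)
  a <- rnorm(30) + y
  b <- rnorm(30) + 0.5 * y
  same <- delong_paired_test(a, a, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  ab <- delong_paired_test(a, b, y)
  ba <- delong_paired_test(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_error(delong_paired_test(a, b[-1], y), "length")
})

test_that("paired DeLong p is calibrated: uniform under the null", {
  set.seed(13)
  ps <- replicate(2000, {
    y <- rep(0:1, each = 20)
    delong_paired_test(rnorm(40), rnorm(40), y)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("binormal AUC has the closed-form values and limits", {
  expect_equal(binormal_auc(0, 1, 0, 1), 0.5)
  expect_error(binormal_auc(0, 0, 1, 1), "standard deviations")

  # strictly increasing in the positive-class mean
  aucs <- vapply(seq(0, 3, 0.5), function(m) binormal_auc(0, 1, m, 1.5),
                 numeric(1))
  expect_true(all(diff(aucs) > 0))

  # agreement with the empirical AUC on one large binormal sample
  set.seed(14)
  n <- 20000
  s <- c(rnorm(n, 10, 3), rnorm(n, 14, 4))
  y <- rep(0:1, each = n)
  emp <- empirical_auc(s, y)
  mc_se <- sqrt(emp * (1 - emp)) / sqrt(n) # conservative MC scale
  expect_lt(abs(emp - binormal_auc(10, 3, 14, 4)), 3 * pmax(mc_se, 0.004))
})

test_that("binormal AUCs from the study's group moments match its ROC table", {
  expect_lt(abs(binormal_auc(14.9, 8.9, 32.7, 15.0) - 0.846), 0.01)
  expect_lt(abs(binormal_auc(451, 157, 544, 183) - 0.653), 0.01)
})

test_that("ICC(2,1) behaves at agreement extremes and under grader shift", {
  x <- c(3, 7, 12, 20, 31)
  expect_equal(icc_agreement(x, x), 1.0)

  set.seed(15)
  sig <- rnorm(1000, 0, 2)
  noisy <- sig + rnorm(1000, 0, 6) # noise sd = 3x signal sd
  expect_lt(icc_agreement(sig, noisy), 0.2)

  # absolute agreement: a constant shift on one grader lowers the ICC
  a <- rnorm(500, 20, 5)
  b <- a + rnorm(500, 0, 1)
  expect_gt(icc_agreement(a, b), icc_agreement(a, b + 4))

  expect_error(icc_agreement(1:3, 1:4), "length")
  expect_error(icc_agreement(rep(2, 5), rep(2, 5)), "zero total variance")
})

test_that("pooled t-test matches hand computation and detects injection gap", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_equal(two_sample_t(c(1, 2, 3), c(4, 5, 6))$t, -3.674,
               tolerance = 1e-3)

  set.seed(16)
  hits <- mean(replicate(1000, {
    x <- rnorm(47, 2.4, 1.2)
    y <- rnorm(42, 5.9, 1.6)
    two_sample_t(x, y)$p < 0.001
  }))
  expect_gte(hits, 0.99)
})

test_that("uncorrected 2x2 chi-square reproduces the study's printed p-values", {
  sex <- chi_square_2x2(rbind(c(30, 17), c(26, 16)))
  expect_lt(abs(sex$p - 0.851), 0.005)

  eye <- chi_square_2x2(rbind(c(26, 21), c(23, 19)))
  expect_lt(abs(eye$p - 0.958), 0.005)

  flat <- chi_square_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "margin")
})
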