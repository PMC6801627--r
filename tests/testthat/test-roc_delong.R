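test_that("empirical AUC matches brute-force pair counting", {
  expect_equal(empirical_auc(c(2, 3), c(1, 2))$auc, 0.875)
  expect_equal(empirical_auc(c(5, 6), c(1, 2))$auc, 1)
  expect_equal(empirical_auc(5, 5)$auc, 0.5)
  withr::with_seed(11, {
    for (i in 1:50) {
      pos <- sample(0:5, sample(2:8, 1), replace = TRUE)
      neg <- sample(0:5, sample(2:8, 1), replace = TRUE)
      expect_equal(empirical_auc(pos, neg)$auc, brute_auc(pos, neg))
    }
  })
  expect_error(empirical_auc(numeric(0), 1), "non-empty")
})

test_that("AUC complementation and monotone-transform invariance hold", {
  withr::with_seed(12, {
    for (i in 1:25) {
      pos <- rnorm(10); neg <- rnorm(12)
      a <- empirical_auc(pos, neg)$auc
      expect_equal(a + empirical_auc(neg, pos)$auc, 1)
      expect_equal(empirical_auc(exp(pos), exp(neg))$auc, a)
    }
  })
})

test_that("DeLong components and variance match direct pairwise computation", {
  cases <- list(list(pos = c(1, 2, 3), neg = c(0, 1, 2)),
                list(pos = c(0.3, 0.9, 0.9, 1.7), neg = c(0.1, 0.9, 1.1)))
  for (cs in cases) {
    cmp <- uropanel:::delong_components(cs$pos, cs$neg)
    ref <- brute_components(cs$pos, cs$neg)
    expect_equal(cmp$v10, ref$v10)
    expect_equal(cmp$v01, ref$v01)
    ci <- delong_ci(cs$pos, cs$neg)
    expect_equal(ci$variance,
                 var(ref$v10) / length(cs$pos) + var(ref$v01) / length(cs$neg))
    expect_true(ci$ci_low <= ci$auc && ci$auc <= ci$ci_high)
  }
  # perfect separation: components constant, CI collapses to the point [1, 1]
  ci <- delong_ci(c(10, 11, 12), c(1, 2, 3))
  expect_equal(ci$variance, 0)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))
  expect_error(delong_ci(1, c(1, 2)), "at least 2")
})

test_that("DeLong variance shrinks roughly inversely with sample size", {
  v <- vapply(c(50, 100, 200), function(n) {
    withr::with_seed(n, delong_ci(rnorm(n, 1), rnorm(n))$variance)
  }, numeric(1))
  expect_lt(v[2] / v[1], 0.8)
  expect_lt(v[3] / v[2], 0.8)
})

test_that("paired DeLong test handles self-comparison, covariance sign and small cases", {
  withr::with_seed(13, {
    s <- rnorm(30); y <- rep(c(TRUE, FALSE), 15)
    self <- delong_paired_test(s, s, y)
    expect_equal(self$z, 0)
    expect_equal(self$p, 1)
    # anti-correlated scores: negative AUC covariance
    anti <- delong_paired_test(s, -s, y)
    expect_lte(anti$covariance, 0)
  })
  # n = 6: covariance against direct indicator computation
  a <- c(0.1, 0.8, 0.4, 0.9, 0.2, 0.6)
  b <- c(0.2, 0.6, 0.5, 0.7, 0.4, 0.3)
  y <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  got <- delong_paired_test(a, b, y)
  ra <- brute_components(a[y], a[!y]); rb <- brute_components(b[y], b[!y])
  expect_equal(got$covariance,
               cov(ra$v10, rb$v10) / 3 + cov(ra$v01, rb$v01) / 3)
  expect_true(got$p >= 0 && got$p <= 1)
})

test_that("DeLong AUC and CI agree with pROC on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    for (i in 1:5) {
      pos <- rnorm(40, 0.8); neg <- rnorm(35)
      ours <- delong_ci(pos, neg)
      ref <- pROC::ci.auc(pROC::roc(cases = pos, controls = neg,
                                    quiet = TRUE), method = "delong")
      expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
      expect_equal(c(ours$ci_low, ours$ci_high), as.numeric(ref[c(1, 3)]),
                   tolerance = 1e-8)
    }
    # paired test p-value against pROC's roc.test
    scores_a <- rnorm(60); scores_b <- 0.5 * scores_a + rnorm(60)
    y <- rep(c(TRUE, FALSE), 30)
    scores_a[y] <- scores_a[y] + 1
    ours <- delong_paired_test(scores_a, scores_b, y)
    ref <- pROC::roc.test(pROC::roc(y, scores_a, quiet = TRUE),
                          pROC::roc(y, scores_b, quiet = TRUE),
                          method = "delong")
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  })
})

test_that("ROC curve has proper endpoints and monotone SN/SP", {
  withr::with_seed(15, {
    s <- round(rnorm(40), 1); y <- rep(c(TRUE, FALSE), 20)
    rc <- roc_curve(s, y)
    expect_equal(rc$sn[1], 1); expect_equal(rc$sp[1], 0)
    expect_equal(rc$sn[nrow(rc)], 0); expect_equal(rc$sp[nrow(rc)], 1)
    expect_true(all(diff(rc$sn) <= 0))
    expect_true(all(diff(rc$sp) >= 0))
    grid <- sn_at_sp(s, y)
    expect_true(all(diff(grid$sn) <= 1e-9))
    expect_true(all(grid$sp_achieved >= grid$sp_target - 1e-9))
  })
})

test_that("stratified subsample AUC behaves at the degenerate corners", {
  coh <- toy_cohort(n_benign = 20, n_cancer = 25, d = c(m1 = 1), seed = 16)
  coh$concentrations[, 1] <- 1  # constant marker: every pair ties
  r <- stratified_subsample_auc(coh, "m1", n_iter = 20, seed = 1)
  expect_true(all(r$aucs == 0.5))
  # frac = 1 without replacement reproduces the full-data AUC each time
  coh2 <- toy_cohort(n_benign = 20, n_cancer = 25, d = c(m1 = 1), seed = 17)
  full <- empirical_auc(coh2$concentrations[coh2$samples$group == "malignant", 1],
                        coh2$concentrations[coh2$samples$group == "benign", 1])$auc
  r2 <- stratified_subsample_auc(coh2, "m1", n_iter = 10, frac = 1, seed = 2)
  expect_true(all(abs(r2$aucs - full) < 1e-12))
  # reproducible under a fixed master seed, and iteration draws differ
  r3 <- stratified_subsample_auc(coh2, "m1", n_iter = 50, frac = 0.8, seed = 3)
  r4 <- stratified_subsample_auc(coh2, "m1", n_iter = 50, frac = 0.8, seed = 3)
  expect_identical(r3$aucs, r4$aucs)
  expect_gt(length(unique(r3$aucs)), 1)
})

test_that("subsample draws preserve the class ratio by largest remainder", {
  y <- rep(c("a", "b"), c(125, 158))
  withr::with_seed(18, {
    idx <- uropanel:::stratified_indices(y, 0.8)
    expect_equal(sum(y[idx] == "a"), 100)
    expect_equal(sum(y[idx] == "b"), 126)  # quotas 100.0 + 126.4 -> round(226.4) = 226 total
    expect_false(anyDuplicated(idx) > 0)
    boot <- uropanel:::stratified_indices(y, 1, replace = TRUE)
    expect_equal(sum(y[boot] == "a"), 125)
  })
})
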