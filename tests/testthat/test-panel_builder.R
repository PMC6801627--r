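test_that("panel enumeration counts match binomial coefficients", {
  expect_length(enumerate_panels(letters[1:4], 2), choose(4, 2))
  expect_length(enumerate_panels(letters[1:2], 2), 1)
  pool23 <- paste0("m", 1:23)
  expect_length(enumerate_panels(pool23, 2:4),
                choose(23, 2) + choose(23, 3) + choose(23, 4))  # 10879
  expect_error(enumerate_panels(letters[1:3], 4), "exceeds")
  # deterministic lexicographic order
  expect_identical(enumerate_panels(c("a", "b", "c"), 2),
                   list(c("a", "b"), c("a", "c"), c("b", "c")))
})

test_that("F-score threshold matches exhaustive search and handles degenerate labels", {
  withr::with_seed(61, {
    for (i in 1:60) {
      n <- sample(5:25, 1)
      scores <- round(runif(n), 2)
      labels <- runif(n) < 0.5
      if (!any(labels)) labels[1] <- TRUE
      if (all(labels)) labels[1] <- FALSE
      expect_equal(choose_threshold_fscore(scores, labels),
                   brute_fscore_threshold(scores, labels))
    }
  })
  # perfectly separated: the returned threshold achieves F1 = 1
  s <- c(0.1, 0.2, 0.8, 0.9); y <- c(FALSE, FALSE, TRUE, TRUE)
  t <- choose_threshold_fscore(s, y)
  expect_true(t > 0.2 && t <= 0.8)
  expect_equal(sum((s >= t) == y), 4)
  # all-positive labels: predict everything positive
  expect_equal(choose_threshold_fscore(c(0.2, 0.6), c(TRUE, TRUE)), 0)
  expect_warning(t0 <- choose_threshold_fscore(rep(0.4, 5), c(TRUE, FALSE, TRUE, FALSE, TRUE)),
                 "identical")
  expect_equal(t0, 0.5)
})

test_that("panel fits are deterministic, separable-safe and covariate-aware", {
  coh <- toy_cohort(n_benign = 40, n_cancer = 40, d = c(a = 8, b = 8), seed = 62)
  m <- suppressWarnings(fit_panel(coh, c("a", "b")))
  ev <- evaluate_panel(m, coh)
  expect_equal(ev$all$confusion$sn, 100)
  expect_equal(ev$all$confusion$sp, 100)
  expect_equal(ev$all$auc$auc, 1)

  coh2 <- toy_cohort(n_benign = 60, n_cancer = 60, d = c(a = 1, b = 0.5), seed = 63)
  m1 <- fit_panel(coh2, c("a", "b"))
  m2 <- fit_panel(coh2, c("a", "b"))
  expect_lt(max(abs(m1$coef - m2$coef)), 1e-10)
  expect_equal(m1$intercept, m2$intercept)

  m3 <- fit_panel(coh2, c("a", "b"), include_menopause = TRUE)
  expect_true("menopause_post" %in% names(m3$coef))
  # unknown menopause samples excluded from covariate models only
  coh3 <- coh2; coh3$samples$menopause[1:5] <- "unknown"
  m4 <- fit_panel(coh3, c("a", "b"), include_menopause = TRUE)
  expect_equal(m4$n_train, 115)
  expect_equal(fit_panel(coh3, c("a", "b"))$n_train, 120)
  expect_true(all(is.na(predict_panel(m4, coh3)[1:5])))
})

test_that("a menopause-class association strengthens the covariate panel out of sample", {
  wins <- 0L; runs <- 40L
  for (s in seq_len(runs)) {
    coh <- toy_cohort(n_benign = 70, n_cancer = 70, d = c(a = 0.8, b = 0.4),
                      seed = 700 + s)
    withr::with_seed(800 + s, {
      y <- coh$samples$group == "malignant"
      # posterior odds of postmenopausal status ~3x higher in cancer
      p <- ifelse(y, 0.6, 1 - 1 / (1 + (0.6 / 0.4) / 3))
      coh$samples$menopause <- ifelse(runif(140) < p, "post", "pre")
      tr <- c(1:50, 71:120); te <- setdiff(1:140, tr)
    })
    m_plain <- fit_panel(subset_cohort(coh, tr), c("a", "b"))
    m_meno <- fit_panel(subset_cohort(coh, tr), c("a", "b"),
                        include_menopause = TRUE)
    auc_of <- function(m) evaluate_panel(m, subset_cohort(coh, te))$all$auc$auc
    wins <- wins + (auc_of(m_meno) >= auc_of(m_plain))
  }
  expect_gte(wins / runs, 0.8)
})

test_that("panel evaluation metrics are arithmetically exact and monotone", {
  cfg <- paperlike_scenario(correlated = TRUE, seed = 64)
  coh <- suppressMessages(apply_exclusions(generate_cohort(cfg)$cohort))
  m <- fit_panel(coh, c("HE4", "TTR", "CEA", "Creatinine"))
  ev <- evaluate_panel(m, coh)
  cf <- ev$all$confusion
  expect_equal(cf$ppv, 100 * cf$tp / (cf$tp + cf$fp))
  expect_equal(cf$npv, 100 * cf$tn / (cf$tn + cf$fn))
  expect_equal(cf$sn, 100 * cf$tp / (cf$tp + cf$fn))
  expect_equal(cf$sp, 100 * cf$tn / (cf$tn + cf$fp))
  for (sg in names(ev)) {
    expect_true(all(diff(ev[[sg]]$sn_at_sp$sn) <= 1e-9))
  }
  expect_equal(ev$early$n_pos + ev$advanced$n_pos, ev$all$n_pos)
  # evaluation is invariant to sample order
  perm <- withr::with_seed(65, sample(n_samples(coh)))
  ev_p <- evaluate_panel(m, subset_cohort(coh, perm))
  expect_equal(ev_p$all$auc$auc, ev$all$auc$auc)
  expect_equal(ev_p$advanced$confusion, ev$advanced$confusion)
})

test_that("nested CV recovers a planted pair and guards against noise inflation", {
  d <- c(a = 1.1, b = 0.9, n1 = 0, n2 = 0, n3 = 0, n4 = 0)
  coh <- toy_cohort(n_benign = 90, n_cancer = 90, d = d, seed = 66)
  ncv <- nested_cv_select(coh, nested_cv_config(
    outer_reps = 30, sizes = 2, pool = names(d), seed = 66))
  sel2 <- ncv$selection[ncv$selection$size == 2, ]
  expect_equal(sel2$panel[1], "a+b")
  expect_gte(sel2$selection_share[1], 0.9)

  # appending a pure-noise marker to the winner cannot buy held-out AUC
  reps <- 200L
  seeds <- uropanel:::derive_seeds(67L, reps)
  delta <- vapply(seq_len(reps), function(r) {
    withr::with_seed(seeds[r], {
      y <- coh$samples$group == "malignant"
      tr <- sort(uropanel:::stratified_indices(y, 0.8))
      te <- setdiff(seq_along(y), tr)
      m_win <- fit_panel(subset_cohort(coh, tr), c("a", "b"))
      m_noise <- fit_panel(subset_cohort(coh, tr), c("a", "b", "n1"))
      auc_of <- function(m) evaluate_panel(m, subset_cohort(coh, te))$all$auc$auc
      auc_of(m_noise) - auc_of(m_win)
    })
  }, numeric(1))
  expect_lt(mean(delta), 0.01)
})

test_that("held-out performance does not beat inner-CV estimates beyond noise", {
  cfg <- paperlike_scenario(seed = 68)
  coh <- suppressMessages(apply_exclusions(generate_cohort(cfg)$cohort))
  ncv <- nested_cv_select(coh, nested_cv_config(
    outer_reps = 40, sizes = c(2, 4),
    pool = c("HE4", "TTR", "CEA", "Creatinine", "VCAM", "Leptin", "NCAM", "MPO"),
    seed = 68))
  for (k in unique(ncv$holdout$size)) {
    h <- ncv$holdout[ncv$holdout$size == k, ]
    gap <- mean(h$holdout_auc) - mean(h$inner_auc)
    expect_lt(gap, 2 * sd(h$holdout_auc) / sqrt(nrow(h)) + 0.02)
  }
  # reproducibility under the master seed
  ncv2 <- nested_cv_select(coh, nested_cv_config(
    outer_reps = 5, sizes = 2, pool = c("HE4", "TTR", "CEA", "Creatinine"),
    seed = 99))
  ncv3 <- nested_cv_select(coh, nested_cv_config(
    outer_reps = 5, sizes = 2, pool = c("HE4", "TTR", "CEA", "Creatinine"),
    seed = 99))
  expect_identical(ncv2$holdout, ncv3$holdout)
})
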