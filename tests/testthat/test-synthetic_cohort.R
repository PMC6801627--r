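test_that("effect-size calibration inverts the binormal AUC formula", {
  expect_equal(effect_size_from_auc(0.822), 1.306, tolerance = 1e-3)
  for (a in c(0.6, 0.75, 0.9)) {
    expect_equal(pnorm(effect_size_from_auc(a) / sqrt(2)), a, tolerance = 1e-10)
  }
  expect_lt(effect_size_from_auc(0.5 + 1e-6), 1e-4)
  expect_error(effect_size_from_auc(0.5), "between")
  expect_error(effect_size_from_auc(1), "between")
})

test_that("generated cohorts honor configured counts exactly and reproduce bitwise", {
  cfg <- paperlike_scenario(seed = 71)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$samples, g2$cohort$samples)
  expect_identical(g1$cohort$concentrations, g2$cohort$concentrations)
  expect_identical(g1$truth, g2$truth)

  tab <- table(g1$cohort$samples$group)
  expect_equal(as.integer(tab[c("benign", "borderline", "malignant")]),
               c(125, 12, 158))
  stg <- g1$cohort$samples$figo_stage
  expect_equal(sum(stg %in% c("I", "II")), 48)
  expect_equal(sum(stg %in% c("III", "IV")), 110)
  expect_equal(sum(stg == "I"), 36)  # substage split follows the study table
  expect_equal(sum(g1$cohort$samples$menopause == "post" &
                   g1$cohort$samples$group == "malignant"), 92)
  expect_equal(sum(g1$cohort$samples$menopause == "unknown"), 1)
  expect_true(all(g1$cohort$concentrations > 0))

  # different seed, different draws, same accounting
  g3 <- generate_cohort(cfg, seed = 72)
  expect_false(identical(g1$cohort$concentrations, g3$cohort$concentrations))
  expect_equal(table(g3$cohort$samples$group), tab)
})

test_that("log-scale marginals have unit spread and calibrated separation", {
  cfg <- simulation_config(list(marker_spec("m", auc = 0.822)),
                           n_benign = 125, n_borderline = 0,
                           n_cancer_early = 0, n_cancer_advanced = 158)
  sds <- aucs <- numeric(60)
  for (s in seq_len(60)) {
    g <- generate_cohort(cfg, seed = 7000 + s)
    y <- g$cohort$samples$group == "malignant"
    lx <- log10(g$cohort$concentrations[, 1])
    # within-class (pooled) spread, so the class offset does not inflate it
    sds[s] <- sqrt((sum((lx[y] - mean(lx[y]))^2) + sum((lx[!y] - mean(lx[!y]))^2)) /
                   (length(lx) - 2))
    aucs[s] <- empirical_auc(lx[y], lx[!y])$auc
  }
  expect_lt(abs(mean(sds) - 1), 0.05)
  expect_lt(abs(mean(aucs) - 0.822), 0.01)
})

test_that("the study-like scenario encodes the intended structure", {
  cfg <- paperlike_scenario()
  expect_length(cfg$markers, 23)
  g <- generate_cohort(cfg, seed = 73)
  expect_setequal(g$truth$informative, c("HE4", "TTR", "CEA", "Creatinine"))
  tm <- g$truth$markers
  expect_equal(tm$direction[tm$marker == "CEA"], "lower_in_cancer")
  expect_equal(tm$direction[tm$marker == "Creatinine"], "lower_in_cancer")
  expect_equal(tm$direction[tm$marker == "HE4"], "higher_in_cancer")
  expect_true(all(tm$d_early[!tm$informative] == 0))
  # the latent score separates the classes
  y <- g$cohort$samples$group == "malignant"
  expect_gt(empirical_auc(g$truth$latent_score[y],
                          g$truth$latent_score[!y])$auc, 0.85)

  # TTR analog: early-stage separation exceeds advanced-stage on average
  diffs <- vapply(1:30, function(s) {
    gs <- generate_cohort(cfg, seed = 7300 + s)
    ys <- gs$cohort$samples$group == "malignant"
    stage <- gs$cohort$samples$figo_stage
    ttr <- gs$cohort$concentrations[, "TTR"]
    early <- empirical_auc(ttr[ys & stage %in% c("I", "II")], ttr[!ys &
                           gs$cohort$samples$group == "benign"])$auc
    adv <- empirical_auc(ttr[ys & stage %in% c("III", "IV")], ttr[!ys &
                         gs$cohort$samples$group == "benign"])$auc
    early - adv
  }, numeric(1))
  expect_gt(mean(diffs), 0)

  # correlated preset: informative block carries r = 0.3, nulls stay independent
  cfg_c <- paperlike_scenario(correlated = TRUE)
  inf <- match(c("HE4", "TTR", "CEA", "Creatinine"), cfg_c$marker_names)
  expect_true(all(cfg_c$correlation[inf, inf][upper.tri(diag(4))] == 0.3))
  expect_equal(sum(cfg_c$correlation != 0), 23 + 4 * 3)
  g_c <- generate_cohort(cfg_c, seed = 74)
  lx <- log10(g_c$cohort$concentrations[g_c$cohort$samples$group == "benign",
                                        c("HE4", "TTR")])
  expect_gt(cor(lx[, 1], lx[, 2]), 0.1)
})

test_that("degenerate and invalid configurations are rejected", {
  expect_error(simulation_config(list(marker_spec("m")),
                                 correlation = matrix(c(1, 0.5), 1, 2)),
               "symmetric")
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(simulation_config(rep(list(marker_spec("a")), 3)), "duplicate")
  expect_error(
    simulation_config(list(marker_spec("a"), marker_spec("b"), marker_spec("c")),
                      correlation = bad),
    "positive-definite")
})
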