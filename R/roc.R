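#' Empirical AUC via midranks
#'
#' The empirical AUC equals the Mann-Whitney pair statistic: the fraction of
#' (cancer, benign) score pairs in which the cancer sample scores higher,
#' ties counted 0.5. Computed from midranks in O(n log n).
#'
#' @param scores_pos scores of the positive (malignant) class.
#' @param scores_neg scores of the negative (benign) class.
#' @return object of class `auc_estimate` with fields `auc`, `n_pos`,
#'   `n_neg`; no CI (see [delong_ci()]).
#' @export
empirical_auc <- function(scores_pos, scores_neg) {
  m <- length(scores_pos); n <- length(scores_neg)
  if (m == 0 || n == 0) stop("both classes must be non-empty")
  if (anyNA(scores_pos) || anyNA(scores_neg)) stop("scores must not contain NA")
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  new_auc_estimate(auc, m, n, method = "empirical")
}

new_auc_estimate <- function(auc, n_pos, n_neg, ci_low = NA_real_,
                             ci_high = NA_real_, method = "empirical",
                             level = NA_real_, variance = NA_real_) {
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg,
                 ci_low = ci_low, ci_high = ci_high,
                 level = level, variance = variance, method = method),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (%.0f%% CI %.3f-%.3f, %s)",
                                             100 * x$level, x$ci_low,
                                             x$ci_high, x$method)
  cat(sprintf("AUC %.3f [%d pos / %d neg]%s\n", x$auc, x$n_pos, x$n_neg, ci))
  invisible(x)
}

# DeLong structural components via midranks.
# V10[i] = mean_j psi(pos_i, neg_j), V01[j] = mean_i psi(pos_i, neg_j),
# psi = 1, 0.5, 0 for pos > / = / < neg.
delong_components <- function(scores_pos, scores_neg) {
  m <- length(scores_pos); n <- length(scores_neg)
  r_all <- rank(c(scores_pos, scores_neg), ties.method = "average")
  r_pos <- rank(scores_pos, ties.method = "average")
  r_neg <- rank(scores_neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong confidence interval for an empirical AUC
#'
#' Nonparametric variance from DeLong's structural components (midrank
#' formulation); the CI is the normal-approximation interval clipped to
#' `[0, 1]`. Degenerate data (all components constant, e.g. perfect
#' separation) give zero variance and a point interval.
#'
#' @inheritParams empirical_auc
#' @param level confidence level (default 0.95).
#' @return an `auc_estimate` with `ci_low`, `ci_high`, `variance` and
#'   `method = "delong"`.
#' @export
delong_ci <- function(scores_pos, scores_neg, level = 0.95) {
  m <- length(scores_pos); n <- length(scores_neg)
  if (m < 2 || n < 2) stop("DeLong variance needs at least 2 samples per class")
  cmp <- delong_components(scores_pos, scores_neg)
  v <- var(cmp$v10) / m + var(cmp$v01) / n
  z <- qnorm(1 - (1 - level) / 2)
  new_auc_estimate(cmp$auc, m, n,
                   ci_low = max(0, cmp$auc - z * sqrt(v)),
                   ci_high = min(1, cmp$auc + z * sqrt(v)),
                   method = "delong", level = level, variance = v)
}

#' DeLong paired test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors measured on the same samples. The
#' covariance of the two empirical AUCs comes from the paired structural
#' components; the two-sided p-value uses the normal approximation of
#' `(auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)`.
#'
#' @param scores_a,scores_b numeric score vectors on the same samples.
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive (malignant).
#' @return object of class `delong_comparison` with fields `auc_a`,
#'   `auc_b`, `variance_a`, `variance_b`, `covariance`, `z`, `p`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have equal length")
  }
  y <- as.logical(labels)
  m <- sum(y); n <- sum(!y)
  if (m < 2 || n < 2) stop("both classes need at least 2 samples")
  ca <- delong_components(scores_a[y], scores_a[!y])
  cb <- delong_components(scores_b[y], scores_b[!y])
  va <- var(ca$v10) / m + var(ca$v01) / n
  vb <- var(cb$v10) / m + var(cb$v01) / n
  cv <- cov(ca$v10, cb$v10) / m + cov(ca$v01, cb$v01) / n
  vd <- va + vb - 2 * cv
  dl <- ca$auc - cb$auc
  if (vd <= 0) {
    if (abs(dl) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      warning("zero variance of the AUC difference with unequal AUCs; p = 0")
      z <- sign(dl) * Inf; p <- 0
    }
  } else {
    z <- dl / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, variance_a = va,
                 variance_b = vb, covariance = cv, z = z, p = p),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.3f vs %.3f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Empirical ROC curve
#'
#' Decision rule: `score >= threshold` predicts malignant. Thresholds run
#' over the distinct observed scores plus `Inf`, so the endpoints
#' (SN = 1, SP = 0) and (SN = 0, SP = 1) are always present; sensitivity is
#' non-increasing and specificity non-decreasing along the curve.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1, `TRUE` = malignant.
#' @return data frame with `threshold`, `sn`, `sp` (proportions in [0, 1]).
#' @export
roc_curve <- function(scores, labels) {
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop("both classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  sn <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  sp <- vapply(thr, function(t) mean(scores[!y] < t), numeric(1))
  data.frame(threshold = thr, sn = sn, sp = sp)
}

#' Sensitivity at fixed specificity targets
#'
#' Reads operating points off the step-function ROC without interpolation:
#' for each target, the largest sensitivity among thresholds whose
#' specificity meets or exceeds the target, with the achieved specificity
#' reported alongside.
#'
#' @inheritParams roc_curve
#' @param sp_targets specificity targets in percent.
#' @return data frame with `sp_target`, `sn`, `sp_achieved` (percent) and
#'   `threshold`.
#' @export
sn_at_sp <- function(scores, labels, sp_targets = c(70, 75, 80, 85, 90, 95)) {
  rc <- roc_curve(scores, labels)
  out <- lapply(sp_targets, function(tgt) {
    ok <- which(rc$sp * 100 >= tgt - 1e-9)
    best <- ok[rc$sn[ok] == max(rc$sn[ok])]
    i <- best[which.max(rc$sp[best])]  # among max-SN points, report the best SP
    data.frame(sp_target = tgt, sn = 100 * rc$sn[i],
               sp_achieved = 100 * rc$sp[i], threshold = rc$threshold[i])
  })
  do.call(rbind, out)
}

#' Stratified subsample (or bootstrap) mean AUC
#'
#' Per iteration, draws a fraction of each class — without replacement
#' (repeated leave-group-out subsets, the default) or with replacement
#' (bootstrap) — preserving the cancer-to-benign ratio by largest-remainder
#' rounding, and computes the empirical AUC of the draw. Reports the mean
#' AUC over iterations alongside the full-data DeLong CI.
#'
#' @param cohort a borderline-free [cohort()].
#' @param marker_or_scores a marker name, or a numeric score vector of
#'   length `n_samples(cohort)`.
#' @param n_iter number of iterations (study protocol: 2000).
#' @param frac fraction of each class drawn per iteration, in (0, 1].
#' @param seed master seed; iteration i runs on a sub-seed derived from it.
#' @param replace draw with replacement instead of subsetting.
#' @return object of class `subsample_auc`: `mean_auc`, `aucs` (per
#'   iteration), `full` (full-data `auc_estimate` with DeLong CI),
#'   `n_iter`, `frac`, `replace`.
#' @export
stratified_subsample_auc <- function(cohort, marker_or_scores, n_iter = 2000,
                                     frac = 0.8, seed = 1L, replace = FALSE) {
  stopifnot(n_iter >= 1, frac > 0, frac <= 1)
  y <- malignant_labels(cohort)
  scores <- if (is.character(marker_or_scores) && length(marker_or_scores) == 1) {
    if (!marker_or_scores %in% markers(cohort)) {
      stop("unknown marker: ", marker_or_scores)
    }
    cohort$concentrations[, marker_or_scores]
  } else {
    stopifnot(length(marker_or_scores) == n_samples(cohort))
    as.numeric(marker_or_scores)
  }
  keep <- !is.na(scores)
  scores <- scores[keep]; y <- y[keep]
  take <- largest_remainder(as.numeric(table(y)) * frac)
  if (any(take < 2)) stop("per-class subsample size below 2; raise frac")
  seeds <- derive_seeds(seed, n_iter)
  aucs <- vapply(seq_len(n_iter), function(i) {
    withr::with_seed(seeds[i], {
      idx <- stratified_indices(y, frac, replace = replace)
      empirical_auc(scores[idx][y[idx]], scores[idx][!y[idx]])$auc
    })
  }, numeric(1))
  structure(list(mean_auc = mean(aucs), aucs = aucs,
                 full = delong_ci(scores[y], scores[!y]),
                 n_iter = n_iter, frac = frac, replace = replace),
            class = "subsample_auc")
}

#' @export
print.subsample_auc <- function(x, ...) {
  cat(sprintf("mean AUC %.3f over %d %s draws (frac %.2f); full-data AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$mean_auc, x$n_iter,
              if (x$replace) "bootstrap" else "subsample",
              x$frac, x$full$auc, x$full$ci_low, x$full$ci_high))
  invisible(x)
}
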