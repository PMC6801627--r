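# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (midranks, cumulative counts).

# AUC by explicit enumeration of all case-control pairs, ties = 0.5.
brute_auc <- function(pos, neg) {
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# DeLong structural components by direct pairwise indicators.
brute_components <- function(pos, neg) {
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- vapply(pos, function(a) mean(vapply(neg, function(b) psi(a, b),
                                             numeric(1))), numeric(1))
  v01 <- vapply(neg, function(b) mean(vapply(pos, function(a) psi(a, b),
                                             numeric(1))), numeric(1))
  list(v10 = v10, v01 = v01)
}

# Exhaustive F-score threshold search over the same candidate set, written
# from the SN/PPV definition.
brute_fscore_threshold <- function(scores, labels, beta = 1) {
  y <- as.logical(labels)
  s <- sort(unique(scores))
  cand <- unique(sort(c(0, (s[-1] + s[-length(s)]) / 2, 1)))
  best_f <- -1; best_t <- NA
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    sn <- if (tp + fn > 0) tp / (tp + fn) else NA
    ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
    f <- if (is.na(sn) || sn + ppv == 0) 0 else
      (1 + beta^2) * sn * ppv / (beta^2 * ppv + sn)
    if (f > best_f + 1e-12 || (abs(f - best_f) <= 1e-12 && t > best_t)) {
      best_f <- f; best_t <- t
    }
  }
  best_t
}

# Small two-class cohort with named markers drawn N(mu, 1) on the log scale.
toy_cohort <- function(n_benign = 30, n_cancer = 30, d = c(m1 = 0),
                       seed = 1) {
  withr::with_seed(seed, {
    n <- n_benign + n_cancer
    group <- rep(c("benign", "malignant"), c(n_benign, n_cancer))
    conc <- sapply(names(d), function(mk) {
      10^(rnorm(n) + ifelse(group == "malignant", d[[mk]], 0))
    })
    colnames(conc) <- names(d)
    samples <- data.frame(
      sample_id = sprintf("T%03d", seq_len(n)), group = group,
      histology = "unspecified",
      figo_stage = ifelse(group == "malignant",
                          rep_len(c("II", "III"), n), "none"),
      menopause = sample(c("pre", "post"), n, replace = TRUE),
      age = round(rnorm(n, 50, 10), 1), stringsAsFactors = FALSE)
    cohort(samples, conc)
  })
}
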