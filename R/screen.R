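#' Per-marker differential screening between benign and cancer
#'
#' For each marker, a Welch t-test on log10-transformed concentrations
#' (half-minimum offset per marker) between the malignant and benign
#' classes, corrected for the number of testable markers. Direction is the
#' sign of the difference of class medians of the raw concentrations.
#' Markers with fewer than 2 observed values in either class are flagged
#' untestable and excluded from the correction denominator.
#'
#' @param cohort a borderline-free [cohort()].
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return data frame sorted by `p_corrected` ascending with columns
#'   `marker`, `direction`, `p_raw`, `p_corrected`, `testable`.
#' @export
screen_markers <- function(cohort, correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  y <- malignant_labels(cohort)
  res <- lapply(markers(cohort), function(mk) {
    x <- cohort$concentrations[, mk]
    ok <- !is.na(x)
    xp <- x[ok & y]; xn <- x[ok & !y]
    if (length(xp) < 2 || length(xn) < 2) {
      return(data.frame(marker = mk, direction = NA_character_,
                        p_raw = NA_real_, testable = FALSE))
    }
    lx <- log10_eps(x[ok])$values
    p <- t.test(lx[y[ok]], lx[!y[ok]])$p.value
    dirn <- if (median(xp) >= median(xn)) "higher_in_cancer" else "lower_in_cancer"
    data.frame(marker = mk, direction = dirn, p_raw = p, testable = TRUE)
  })
  res <- do.call(rbind, res)
  res$p_corrected <- NA_real_
  res$p_corrected[res$testable] <- p.adjust(res$p_raw[res$testable],
                                            method = correction)
  res <- res[order(res$p_corrected, res$marker), ]
  rownames(res) <- NULL
  res
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Compares a response across three or more groups (e.g. benign versus
#' early-stage versus advanced-stage) by one-way ANOVA, with Tukey's
#' honestly-significant-difference adjustment for all pairwise contrasts.
#'
#' @param values numeric response.
#' @param groups group labels with at least 3 levels, each with at least 2
#'   observations.
#' @return list with `f` (ANOVA F statistic), `p` (ANOVA p-value) and
#'   `pairs` (data frame: `contrast`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 3) {
    stop("fewer than 3 groups; use a two-group test (e.g. screen_markers)")
  }
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  fit <- aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$groups
  pairs <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1], pairs = pairs)
}

#' Single-marker AUC ranking, overall and by stage group
#'
#' For every marker, the stratified subsample mean AUC and full-data DeLong
#' CI for all cancers versus all benign, early-stage cancers (FIGO I-II)
#' versus all benign, and advanced-stage cancers (III-IV) versus all
#' benign. Marker orientation is preserved: an AUC below 0.5 is reported
#' as-is (direction is captured by [screen_markers()]).
#'
#' @inheritParams stratified_subsample_auc
#' @return data frame, one row per marker, sorted by all-sample mean AUC
#'   descending, with mean AUC and DeLong CI columns per subgroup.
#' @export
rank_single_markers <- function(cohort, n_iter = 2000, frac = 0.8, seed = 1L,
                                replace = FALSE) {
  stage <- ifelse(cohort$samples$figo_stage %in% c("I", "II"), "early",
                  ifelse(cohort$samples$figo_stage %in% c("III", "IV"),
                         "advanced", "none"))
  y <- malignant_labels(cohort)
  subgroups <- list(all = rep(TRUE, n_samples(cohort)),
                    early = !y | stage == "early",
                    advanced = !y | stage == "advanced")
  seeds <- derive_seeds(seed, length(markers(cohort)))
  rows <- lapply(seq_along(markers(cohort)), function(k) {
    mk <- markers(cohort)[k]
    cols <- lapply(names(subgroups), function(sg) {
      sub <- subset_cohort(cohort, subgroups[[sg]])
      r <- stratified_subsample_auc(sub, mk, n_iter = n_iter, frac = frac,
                                    seed = seeds[k], replace = replace)
      out <- data.frame(r$mean_auc, r$full$ci_low, r$full$ci_high)
      names(out) <- paste0(c("auc_", "ci_low_", "ci_high_"), sg)
      out
    })
    cbind(data.frame(marker = mk), do.call(cbind, cols))
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$auc_all), ]
  rownames(res) <- NULL
  res
}
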