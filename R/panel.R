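#' Enumerate candidate marker panels
#'
#' All unordered subsets of each requested size, in deterministic
#' lexicographic order with respect to the pool's ordering (smaller sizes
#' first).
#'
#' @param pool character vector of marker names.
#' @param sizes subset sizes, a subset of 2:4 by convention.
#' @return list of character vectors.
#' @export
enumerate_panels <- function(pool, sizes = 2:4) {
  stopifnot(length(pool) >= 1, !anyDuplicated(pool))
  if (max(sizes) > length(pool)) {
    stop("requested panel size exceeds the candidate pool")
  }
  out <- list()
  for (k in sort(sizes)) {
    out <- c(out, combn(pool, k, simplify = FALSE))
  }
  out
}

#' F-score-optimal decision threshold
#'
#' Scans candidate thresholds (midpoints between adjacent distinct sorted
#' scores, plus 0 and 1) for the one maximizing the F-score of the
#' cancer-positive decision rule `score >= threshold`; F1 by default
#' (harmonic mean of sensitivity and positive predictive value). Ties are
#' broken toward higher specificity (the largest qualifying threshold).
#'
#' @param scores predicted probabilities (or scores in [0, 1]).
#' @param labels logical or 0/1, `TRUE` = cancer.
#' @param beta F-score weight; `beta = 1` gives F1.
#' @return the selected threshold.
#' @export
choose_threshold_fscore <- function(scores, labels, beta = 1) {
  y <- as.logical(labels)
  stopifnot(length(scores) == length(y), !anyNA(scores))
  if (!any(!y)) return(0)   # no negatives: predicting everything positive is optimal
  if (!any(y)) return(1)    # no positives: F undefined everywhere; predict nothing
  s <- sort(unique(scores))
  if (length(s) == 1) {
    warning("all scores identical; threshold defaults to 0.5")
    return(0.5)
  }
  cand <- unique(sort(c(0, (s[-1] + s[-length(s)]) / 2, 1)))
  b2 <- beta^2
  f <- vapply(cand, function(t) {
    tp <- sum(scores >= t & y)
    fp <- sum(scores >= t & !y)
    fn <- sum(scores < t & y)
    den <- (1 + b2) * tp + b2 * fn + fp
    if (den == 0) 0 else (1 + b2) * tp / den
  }, numeric(1))
  best <- which(f >= max(f) - 1e-12)
  cand[max(best)]
}

#' Fit a logistic panel model
#'
#' Unpenalized logistic regression of malignancy on the standardized
#' (log10-scale) concentrations of the selected markers, optionally with
#' menopausal status (post = 1, pre = 0) as a covariate; samples of unknown
#' menopausal status are removed from covariate models only. Samples
#' missing any selected marker are dropped (complete-case per analysis).
#' The decision threshold is set by [choose_threshold_fscore()] on the
#' training scores. Perfectly separated fits fall back to a small ridge
#' stabilizer (1e-6) with a warning.
#'
#' @param train a borderline-free training [cohort()].
#' @param panel_markers 2 or more marker names.
#' @param include_menopause add the menopausal covariate.
#' @return object of class `panel_model`: `markers`, `include_menopause`,
#'   `params` (standardization), `intercept`, `coef`, `threshold`,
#'   `converged`, `n_train`.
#' @export
fit_panel <- function(train, panel_markers, include_menopause = FALSE) {
  stopifnot(length(panel_markers) >= 2)
  absent <- setdiff(panel_markers, markers(train))
  if (length(absent)) stop("markers not in cohort: ", paste(absent, collapse = ", "))
  keep <- stats::complete.cases(train$concentrations[, panel_markers, drop = FALSE])
  if (include_menopause) keep <- keep & train$samples$menopause != "unknown"
  coh <- subset_cohort(train, keep)
  y <- malignant_labels(coh)
  if (!any(y) || all(y)) stop("training data must contain both classes")
  std <- standardize(coh$concentrations[, panel_markers, drop = FALSE])
  x <- std$x
  if (include_menopause) {
    x <- cbind(x, menopause_post = as.numeric(coh$samples$menopause == "post"))
  }
  fit <- irls_logistic(x, as.numeric(y), ridge = 0)
  if (!fit$converged) {
    warning("separation or non-convergence; refitting with ridge 1e-6")
    fit <- irls_logistic(x, as.numeric(y), ridge = 1e-6)
  }
  cf <- fit$coef
  names(cf) <- c("(Intercept)", colnames(x))
  probs <- plogis(cbind(1, x) %*% cf)
  structure(list(markers = panel_markers,
                 include_menopause = include_menopause,
                 params = std$params, intercept = cf[[1]], coef = cf[-1],
                 threshold = choose_threshold_fscore(probs, y),
                 converged = fit$converged, n_train = nrow(x)),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel model: %s%s | threshold %.3f (n = %d)\n",
              paste(x$markers, collapse = "+"),
              if (x$include_menopause) " + menopause" else "",
              x$threshold, x$n_train))
  invisible(x)
}

#' Predicted cancer probabilities from a panel model
#'
#' Applies the stored training standardization and coefficients; samples
#' missing a panel marker (or, for covariate models, of unknown menopausal
#' status) receive `NA`.
#'
#' @param model a [fit_panel()] model.
#' @param cohort a [cohort()] containing the panel markers.
#' @return numeric vector of probabilities, one per cohort sample.
#' @export
predict_panel <- function(model, cohort) {
  ok <- stats::complete.cases(cohort$concentrations[, model$markers, drop = FALSE])
  if (model$include_menopause) ok <- ok & cohort$samples$menopause != "unknown"
  out <- rep(NA_real_, n_samples(cohort))
  if (!any(ok)) return(out)
  sub <- subset_cohort(cohort, ok)
  x <- apply_standardization(model$params, sub)
  if (model$include_menopause) {
    x <- cbind(x, menopause_post = as.numeric(sub$samples$menopause == "post"))
  }
  out[ok] <- plogis(model$intercept + as.numeric(x %*% model$coef))
  out
}

confusion_metrics <- function(pred, y) {
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sn = pct(tp, tp + fn), sp = pct(tn, tn + fp),
       ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn))
}

#' Evaluate a panel model on a cohort
#'
#' Scores the cohort with [predict_panel()] and reports, overall and per
#' stage subgroup (early-stage cancers versus all benign, advanced versus
#' all benign): the AUC with its DeLong 95% CI, the confusion metrics
#' (SN/SP/PPV/NPV, percent) at the model threshold, and the
#' sensitivity-at-fixed-specificity grid. Borderline samples are ignored;
#' subgroups with fewer than 2 cancers are skipped with a warning.
#'
#' @param model a [fit_panel()] model.
#' @param cohort evaluation [cohort()].
#' @param sp_targets specificity grid in percent.
#' @return object of class `panel_evaluation`: a named list of subgroup
#'   evaluations (`all`, `early`, `advanced`), each with `auc`
#'   (`auc_estimate`), `confusion`, `sn_at_sp`, `n_pos`, `n_neg`.
#' @export
evaluate_panel <- function(model, cohort,
                           sp_targets = c(70, 75, 80, 85, 90, 95)) {
  cohort <- subset_cohort(cohort, cohort$samples$group != "borderline")
  p <- predict_panel(model, cohort)
  ok <- !is.na(p)
  y <- cohort$samples$group[ok] == "malignant"
  p <- p[ok]
  stage <- cohort$samples$figo_stage[ok]
  early <- y & stage %in% c("I", "II")
  advanced <- y & stage %in% c("III", "IV")
  sub <- list(all = y | !y, early = early | !y, advanced = advanced | !y)
  out <- list()
  for (sg in names(sub)) {
    use <- sub[[sg]]
    ys <- y[use]; ps <- p[use]
    if (sum(ys) < 2) {
      warning("subgroup '", sg, "' has fewer than 2 cancers; skipped")
      next
    }
    out[[sg]] <- list(
      auc = delong_ci(ps[ys], ps[!ys]),
      confusion = confusion_metrics(ps >= model$threshold, ys),
      sn_at_sp = sn_at_sp(ps, ys, sp_targets),
      n_pos = sum(ys), n_neg = sum(!ys))
  }
  structure(out, class = "panel_evaluation", threshold = model$threshold)
}

#' @export
print.panel_evaluation <- function(x, ...) {
  for (sg in names(x)) {
    e <- x[[sg]]
    cat(sprintf("%-9s AUC %.3f (%.3f-%.3f)  SN %.1f%%  SP %.1f%%  PPV %.1f%%  NPV %.1f%%  [%d/%d]\n",
                sg, e$auc$auc, e$auc$ci_low, e$auc$ci_high,
                e$confusion$sn, e$confusion$sp, e$confusion$ppv,
                e$confusion$npv, e$n_pos, e$n_neg))
  }
  invisible(x)
}

#' Nested cross-validation configuration
#'
#' @param outer_frac fraction of each class drawn into the outer training
#'   set (study protocol: 0.8).
#' @param outer_reps outer repetitions (study protocol: 2000; reducible).
#' @param inner_folds folds of the inner cross-validation (10).
#' @param inner_reps inner fold re-randomizations per outer repetition.
#' @param sizes candidate panel sizes (subset of 2:4).
#' @param pool explicit candidate marker pool, or `NULL` to take the top
#'   `pool_size` markers from [rank_by_lasso()].
#' @param pool_size pool size when ranked automatically (default 8).
#' @param pool_rank_iters lasso repetitions used to rank the pool.
#' @param ridge ridge stabilizer used inside the inner-loop logistic fits.
#' @param seed master seed.
#' @return object of class `nested_cv_config`.
#' @export
nested_cv_config <- function(outer_frac = 0.8, outer_reps = 2000,
                             inner_folds = 10, inner_reps = 1,
                             sizes = 2:4, pool = NULL, pool_size = 8,
                             pool_rank_iters = 25, ridge = 1e-6, seed = 1L) {
  stopifnot(outer_frac > 0, outer_frac < 1, outer_reps >= 1,
            inner_folds >= 2, inner_reps >= 1,
            all(sizes %in% 2:4), length(sizes) >= 1)
  structure(list(outer_frac = outer_frac, outer_reps = as.integer(outer_reps),
                 inner_folds = as.integer(inner_folds),
                 inner_reps = as.integer(inner_reps),
                 sizes = sort(unique(as.integer(sizes))), pool = pool,
                 pool_size = as.integer(pool_size),
                 pool_rank_iters = as.integer(pool_rank_iters),
                 ridge = ridge, seed = as.integer(seed)),
            class = "nested_cv_config")
}

#' Nested cross-validated panel selection
#'
#' Outer loop: `outer_reps` ratio-preserving draws of `outer_frac` of each
#' class form a training set; the remaining samples are untouched. Inner
#' loop: stratified repeated `inner_folds`-fold cross-validation on the
#' training set scores every candidate panel by its mean held-out AUC, all
#' panels sharing the fold assignment so comparisons are paired. The
#' best-scoring panel of each size is refit (unpenalized logistic) on the
#' full training set and its AUC recorded on the held-out 20%. Across
#' outer repetitions, the modal winner per size becomes the selected
#' panel, refit on the complete cohort via [fit_panel()].
#'
#' @param cohort a borderline-free [cohort()].
#' @param config a [nested_cv_config()].
#' @return object of class `nested_cv_result`: `models` (final
#'   `panel_model` per size), `summary` (per size: modal panel, selection
#'   share, mean/sd held-out AUC, full-data DeLong CI), `selection`
#'   (per-size winner tallies), `holdout` (per repetition and size: winner
#'   and held-out AUC), `pool`, `config`.
#' @export
nested_cv_select <- function(cohort, config = nested_cv_config()) {
  stopifnot(inherits(config, "nested_cv_config"))
  y0 <- malignant_labels(cohort)
  pool <- config$pool
  seeds <- derive_seeds(config$seed, config$outer_reps + 1L)
  if (is.null(pool)) {
    imp <- rank_by_lasso(cohort, n_iter = config$pool_rank_iters,
                         n_folds = config$inner_folds, seed = seeds[1])
    pool <- utils::head(imp$summary$marker, config$pool_size)
  }
  absent <- setdiff(pool, markers(cohort))
  if (length(absent)) stop("pool markers not in cohort: ", paste(absent, collapse = ", "))
  keep <- stats::complete.cases(cohort$concentrations[, pool, drop = FALSE])
  coh <- subset_cohort(cohort, keep)
  y <- as.numeric(y0[keep])

  panels <- enumerate_panels(pool, config$sizes)
  panel_names <- vapply(panels, paste, character(1), collapse = "+")
  panel_size <- lengths(panels)
  # logistic predictions are affine-invariant, so the inner loop can run on
  # the log10-transformed values directly (the half-minimum offset is
  # treated as fixed preprocessing; final models use training-only stats)
  x <- coh$concentrations[, pool, drop = FALSE]
  for (j in seq_len(ncol(x))) x[, j] <- log10_eps(x[, j])$values
  panel_idx0 <- lapply(panels, function(p) match(p, pool) - 1L)

  hold <- vector("list", config$outer_reps)
  for (r in seq_len(config$outer_reps)) {
    res <- withr::with_seed(seeds[r + 1L], {
      tr_idx <- sort(stratified_indices(y, config$outer_frac, replace = FALSE))
      te_idx <- setdiff(seq_along(y), tr_idx)
      xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
      score <- rep(0, length(panels))
      for (j in seq_len(config$inner_reps)) {
        foldid <- stratified_folds(ytr, config$inner_folds)
        score <- score + cv_panels_auc_cpp(xtr, ytr, panel_idx0, foldid,
                                           config$inner_folds, config$ridge)
      }
      score <- score / config$inner_reps
      rows <- lapply(config$sizes, function(k) {
        cand <- which(panel_size == k)
        win <- cand[which.max(score[cand])]
        fit <- irls_logistic(xtr[, panel_idx0[[win]] + 1L, drop = FALSE],
                             ytr, ridge = config$ridge)
        s_te <- as.numeric(cbind(1, x[te_idx, panel_idx0[[win]] + 1L,
                                      drop = FALSE]) %*% fit$coef)
        a <- empirical_auc(s_te[y[te_idx] == 1], s_te[y[te_idx] == 0])$auc
        data.frame(rep = r, size = k, panel = panel_names[win],
                   inner_auc = score[win], holdout_auc = a)
      })
      do.call(rbind, rows)
    })
    hold[[r]] <- res
  }
  holdout <- do.call(rbind, hold)

  selection <- do.call(rbind, lapply(config$sizes, function(k) {
    sub <- holdout[holdout$size == k, ]
    tab <- sort(table(sub$panel), decreasing = TRUE)
    agg <- vapply(names(tab), function(pn) mean(sub$holdout_auc[sub$panel == pn]),
                  numeric(1))
    data.frame(size = k, panel = names(tab), times_selected = as.integer(tab),
               selection_share = as.numeric(tab) / nrow(sub),
               mean_holdout_auc = agg, row.names = NULL)
  }))

  models <- list()
  summary_rows <- list()
  for (k in config$sizes) {
    sub <- selection[selection$size == k, ]
    modal <- sub$panel[which.max(sub$times_selected)]
    mk <- strsplit(modal, "+", fixed = TRUE)[[1]]
    model <- fit_panel(coh, mk)
    full_auc <- delong_ci_of_model(model, coh)
    hsub <- holdout[holdout$size == k, ]
    models[[as.character(k)]] <- model
    summary_rows[[as.character(k)]] <- data.frame(
      size = k, panel = modal,
      selection_share = max(sub$selection_share),
      mean_holdout_auc = mean(hsub$holdout_auc),
      sd_holdout_auc = sd(hsub$holdout_auc),
      full_auc = full_auc$auc, full_ci_low = full_auc$ci_low,
      full_ci_high = full_auc$ci_high, row.names = NULL)
  }
  structure(list(models = models, summary = do.call(rbind, summary_rows),
                 selection = selection, holdout = holdout,
                 pool = pool, config = config),
            class = "nested_cv_result")
}

delong_ci_of_model <- function(model, cohort) {
  p <- predict_panel(model, cohort)
  ok <- !is.na(p)
  y <- malignant_labels(subset_cohort(cohort, ok))
  delong_ci(p[ok][y], p[ok][!y])
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("nested CV over %d outer repetitions, pool: %s\n",
              x$config$outer_reps, paste(x$pool, collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
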