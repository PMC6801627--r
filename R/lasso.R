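#' Standardize cohort concentrations for penalized modeling
#'
#' Transforms each marker with `log10(x + eps)` (half-minimum offset) and
#' scales to mean 0, standard deviation 1. Constant columns are dropped
#' with a warning and recorded. The returned parameters (per-marker offset,
#' center, scale) are applied verbatim to held-out data so that test
#' samples never contribute to the training statistics.
#'
#' @param cohort a [cohort()], or a numeric samples-by-markers matrix.
#' @param transform `"log10_eps"` (default) or `"identity"`.
#' @return list with `x` (standardized matrix, retained markers only) and
#'   `params` (class `standardization_params`: data frame of `marker`,
#'   `eps`, `center`, `scale`, plus `transform` and `dropped`).
#' @export
standardize <- function(cohort, transform = c("log10_eps", "identity")) {
  transform <- match.arg(transform)
  x <- if (inherits(cohort, "cohort")) cohort$concentrations else as.matrix(cohort)
  if (nrow(x) < 2) stop("standardization needs at least 2 samples")
  eps <- rep(NA_real_, ncol(x))
  if (transform == "log10_eps") {
    for (j in seq_len(ncol(x))) {
      tr <- log10_eps(x[, j])
      x[, j] <- tr$values
      eps[j] <- tr$eps
    }
  }
  center <- colMeans(x, na.rm = TRUE)
  scale <- apply(x, 2, sd, na.rm = TRUE)
  keep <- !is.na(scale) & scale > 0
  if (any(!keep)) {
    warning("dropping constant marker(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2,
              scale[keep], `/`)
  params <- structure(
    list(table = data.frame(marker = colnames(x)[keep], eps = eps[keep],
                            center = center[keep], scale = scale[keep],
                            row.names = NULL),
         transform = transform, dropped = colnames(x)[!keep]),
    class = "standardization_params")
  list(x = xs, params = params)
}

#' Apply stored standardization parameters to new data
#'
#' @param params a `standardization_params` object from [standardize()].
#' @param cohort a [cohort()] or numeric matrix containing at least the
#'   parameterized markers.
#' @return standardized matrix over the parameterized markers, using the
#'   training offset, center and scale (held-out columns will not in
#'   general have unit variance).
#' @export
apply_standardization <- function(params, cohort) {
  x <- if (inherits(cohort, "cohort")) cohort$concentrations else as.matrix(cohort)
  tb <- params$table
  absent <- setdiff(tb$marker, colnames(x))
  if (length(absent)) stop("markers missing from data: ", paste(absent, collapse = ", "))
  x <- x[, tb$marker, drop = FALSE]
  if (params$transform == "log10_eps") {
    for (j in seq_len(ncol(x))) x[, j] <- log10(x[, j] + tb$eps[j])
  }
  sweep(sweep(x, 2, tb$center), 2, tb$scale, `/`)
}

#' Cross-validated L1-penalized logistic fit
#'
#' Fits the lasso logistic path (via glmnet) over a log-spaced lambda grid
#' running from the smallest all-zero lambda down by four decades, selects
#' the lambda minimizing the mean cross-validated binomial deviance over
#' stratified folds, and returns the full-data coefficients at that lambda.
#'
#' @param x standardized predictor matrix (no intercept column).
#' @param y logical or 0/1 response.
#' @param lambda_grid optional decreasing lambda sequence; computed from
#'   the data when `NULL` (100 points).
#' @param n_folds folds for the inner CV (default 10, stratified).
#' @param seed seed controlling the fold assignment.
#' @param path optional precomputed full-data `glmnet` path on `x` (an
#'   optimization for repeated calls on fixed data); must match
#'   `lambda_grid`.
#' @return list with `lambda` (selected), `coef` (named marker
#'   coefficients), `intercept`, `cv_deviance` (mean CV deviance per grid
#'   point) and `lambda_grid`.
#' @export
fit_l1_logistic_cv <- function(x, y, lambda_grid = NULL, n_folds = 10,
                               seed = 1L, path = NULL) {
  y <- as.numeric(as.logical(y))
  stopifnot(nrow(x) == length(y))
  if (is.null(path)) {
    path <- glmnet::glmnet(x, y, family = "binomial", standardize = FALSE,
                           lambda = lambda_grid, nlambda = 100,
                           lambda.min.ratio = 1e-4)
  }
  if (is.null(lambda_grid)) lambda_grid <- path$lambda
  foldid <- withr::with_seed(as.integer(seed), stratified_folds(y, n_folds))
  if (any(tapply(y, foldid, function(v) length(unique(v))) < 2)) {
    stop("a fold lost a class; reduce n_folds or enlarge the data")
  }
  dev <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    fit <- tryCatch(
      glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                     standardize = FALSE, lambda = lambda_grid),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("fold ", f, " failed to converge; skipped")
      next
    }
    # held-out binomial deviance straight from the coefficient path
    eta <- sweep(x[!tr, , drop = FALSE] %*% fit$beta, 2, fit$a0, `+`)
    p <- pmin(pmax(plogis(as.matrix(eta)), 1e-12), 1 - 1e-12)
    yy <- y[!tr]
    dev[f, seq_len(ncol(p))] <-
      colMeans(-2 * (yy * log(p) + (1 - yy) * log(1 - p)))
  }
  if (all(is.na(dev))) stop("all cross-validation folds failed")
  mdev <- colMeans(dev, na.rm = TRUE)
  best <- which.min(mdev)
  cf <- as.numeric(coef(path, s = lambda_grid[best], exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(x))
  list(lambda = lambda_grid[best], coef = cf[-1], intercept = cf[1],
       cv_deviance = mdev, lambda_grid = lambda_grid)
}

#' Marker importance from repeated cross-validated lasso fits
#'
#' Standardizes the full cohort (log10 scale), then repeats
#' [fit_l1_logistic_cv()] with re-randomized folds `n_iter` times and
#' aggregates the per-marker coefficient distributions. Markers are ranked
#' by mean absolute standardized coefficient (largest first); the fraction
#' of iterations with a nonzero coefficient is reported as the selection
#' frequency.
#'
#' @param cohort a borderline-free [cohort()].
#' @param n_iter number of CV repetitions (study protocol: 2000).
#' @param n_folds folds per repetition.
#' @param seed master seed; repetition i uses a derived sub-seed.
#' @return object of class `lasso_importance`: `summary` (data frame with
#'   `marker`, `mean_abs_coef`, `selection_freq`, `rank`, sorted by rank)
#'   and `coefficients` (iterations-by-markers matrix of fitted
#'   standardized coefficients).
#' @export
rank_by_lasso <- function(cohort, n_iter = 2000, n_folds = 10, seed = 1L) {
  stopifnot(n_iter >= 1)
  y <- malignant_labels(cohort)
  keep <- stats::complete.cases(cohort$concentrations)
  std <- standardize(subset_cohort(cohort, keep))
  x <- std$x
  yk <- y[keep]
  # the full-data path is deterministic given the data: compute it once
  path <- glmnet::glmnet(x, yk, family = "binomial", standardize = FALSE,
                         nlambda = 100, lambda.min.ratio = 1e-4)
  seeds <- derive_seeds(seed, n_iter)
  coefs <- matrix(NA_real_, n_iter, ncol(x),
                  dimnames = list(NULL, colnames(x)))
  for (i in seq_len(n_iter)) {
    fit <- fit_l1_logistic_cv(x, yk, lambda_grid = path$lambda,
                              n_folds = n_folds, seed = seeds[i], path = path)
    coefs[i, ] <- fit$coef
  }
  mac <- colMeans(abs(coefs))
  freq <- colMeans(coefs != 0)
  ord <- order(-mac, colnames(x))
  summary <- data.frame(marker = colnames(x)[ord], mean_abs_coef = mac[ord],
                        selection_freq = freq[ord],
                        rank = seq_along(ord), row.names = NULL)
  structure(list(summary = summary, coefficients = coefs,
                 params = std$params, n_iter = n_iter),
            class = "lasso_importance")
}

#' @export
print.lasso_importance <- function(x, ...) {
  cat(sprintf("lasso importance over %d CV repetitions; top markers:\n", x$n_iter))
  print(utils::head(x$summary, 8), row.names = FALSE)
  invisible(x)
}
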