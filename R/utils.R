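#' Derive independent iteration seeds from a master seed
#'
#' Draws `n` sub-seeds from the master seed so that iteration `i` can run on
#' its own reproducible stream regardless of execution order.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n, replace = FALSE))
}

#' Largest-remainder apportionment of a total across classes
#'
#' Allocates `round(sum(quota))` integer counts across classes proportionally
#' to `quota`, flooring first and then distributing the shortfall to the
#' largest fractional remainders (first-come tie-break).
#'
#' @param quota non-negative real quotas, one per class.
#' @return integer vector summing to `round(sum(quota))`.
#' @keywords internal
largest_remainder <- function(quota) {
  stopifnot(all(quota >= 0))
  total <- round(sum(quota))
  base <- floor(quota)
  short <- as.integer(total - sum(base))
  if (short > 0) {
    take <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Stratified index draw preserving class ratios
#'
#' Draws a fraction of each stratum, with per-stratum sizes fixed by
#' largest-remainder rounding so the class ratio of the draw matches the
#' cohort's as closely as integer counts allow.
#'
#' @param strata factor-like vector of stratum labels.
#' @param frac fraction of each stratum to draw, in (0, 1].
#' @param replace draw with replacement (bootstrap) or without (subsample).
#' @return integer vector of selected indices (unordered).
#' @keywords internal
stratified_indices <- function(strata, frac, replace = FALSE) {
  stopifnot(frac > 0, frac <= 1)
  strata <- as.factor(strata)
  sizes <- table(strata)
  take <- largest_remainder(as.numeric(sizes) * frac)
  idx <- unlist(lapply(seq_along(sizes), function(k) {
    pool <- which(strata == levels(strata)[k])
    if (take[k] == 0) return(integer(0))
    if (replace) pool[sample.int(length(pool), take[k], replace = TRUE)]
    else pool[sample.int(length(pool), take[k], replace = FALSE)]
  }), use.names = FALSE)
  idx
}

#' Stratified cross-validation fold assignment
#'
#' @param labels two-class (or multi-class) label vector.
#' @param n_folds number of folds.
#' @return integer fold id per observation, each class spread evenly.
#' @keywords internal
stratified_folds <- function(labels, n_folds) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    pool <- which(labels == lv)
    fold[pool] <- sample(rep_len(seq_len(n_folds), length(pool)))
  }
  fold
}

#' Log10 transform with a half-minimum offset
#'
#' Concentrations span orders of magnitude and may contain exact zeros; the
#' transform is `log10(x + eps)` with `eps` equal to half the smallest
#' positive value observed in `x` (or in `reference` when supplied, so
#' held-out data reuse the training offset).
#'
#' @param x non-negative numeric vector.
#' @param eps offset; computed from `x` when `NULL`.
#' @return list with `values` (transformed) and `eps` (offset used).
#' @keywords internal
log10_eps <- function(x, eps = NULL) {
  if (is.null(eps)) {
    pos <- x[!is.na(x) & x > 0]
    eps <- if (length(pos)) min(pos) / 2 else 1
  }
  list(values = log10(x + eps), eps = eps)
}

pct1 <- function(count, denom) round(100 * count / denom, 1)
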