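#' Standardized mean difference achieving a target binormal AUC
#'
#' Under the equal-variance binormal model (class scores Normal with unit
#' variance and mean gap `d`), the AUC is `pnorm(d / sqrt(2))`; inverting
#' gives `d = sqrt(2) * qnorm(auc)`.
#'
#' @param target_auc AUC in (0.5, 1).
#' @return effect size `d` (log10-scale standardized mean difference).
#' @export
effect_size_from_auc <- function(target_auc) {
  if (any(target_auc <= 0.5 | target_auc >= 1)) {
    stop("target_auc must lie strictly between 0.5 and 1")
  }
  sqrt(2) * qnorm(target_auc)
}

#' Specify one simulated marker
#'
#' A marker is either null (no `auc` given: identical distribution in both
#' classes) or informative with a target AUC, optionally stage-specific.
#' Log10 concentrations have unit standard deviation in every class; the
#' cancer-class mean is shifted by `d = effect_size_from_auc(auc)` in the
#' stated direction.
#'
#' @param name marker name.
#' @param auc overall target AUC in (0.5, 1); `NULL` for a null marker.
#' @param auc_early,auc_advanced stage-specific target AUCs (benign versus
#'   that stage group); default to `auc`.
#' @param direction `"higher"` (concentration raised in cancer) or
#'   `"lower"` (lowered, as for CEA and creatinine).
#' @param log_mean log10 mean concentration in the benign class (location
#'   only; does not affect AUC).
#' @return object of class `marker_spec`.
#' @export
marker_spec <- function(name, auc = NULL, auc_early = auc, auc_advanced = auc,
                        direction = c("higher", "lower"), log_mean = 0) {
  direction <- match.arg(direction)
  d_of <- function(a) if (is.null(a)) 0 else effect_size_from_auc(a)
  structure(list(name = name,
                 d_early = d_of(auc_early),
                 d_advanced = d_of(auc_advanced),
                 sign = if (direction == "higher") 1 else -1,
                 log_mean = log_mean),
            class = "marker_spec")
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults mirror the study cohort: 125 benign, 12 borderline and 158
#' malignant samples (48 early-stage, 110 advanced-stage), postmenopausal
#' fractions 25/124 among benign and 92/158 among cancers (one benign
#' patient of unstated status), with histology and FIGO substage
#' composition apportioned from the study table by largest remainder.
#'
#' @param markers list of [marker_spec()] objects.
#' @param n_benign,n_borderline,n_cancer_early,n_cancer_advanced class sizes.
#' @param correlation optional symmetric positive-definite correlation
#'   matrix on the log10 scale (marker order of `markers`); identity when
#'   `NULL`.
#' @param p_post_benign,p_post_borderline,p_post_cancer probability of
#'   postmenopausal status given class (applied as exact largest-remainder
#'   counts, not random draws).
#' @param n_menopause_unknown_benign benign samples with unrecorded status.
#' @param seed default seed used by [generate_cohort()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(markers,
                              n_benign = 125L, n_borderline = 12L,
                              n_cancer_early = 48L, n_cancer_advanced = 110L,
                              correlation = NULL,
                              p_post_benign = 25 / 124,
                              p_post_borderline = 2 / 12,
                              p_post_cancer = 92 / 158,
                              n_menopause_unknown_benign = 1L,
                              seed = 1L) {
  stopifnot(length(markers) >= 1,
            all(vapply(markers, inherits, logical(1), "marker_spec")),
            n_benign >= 0, n_borderline >= 0,
            n_cancer_early >= 0, n_cancer_advanced >= 0)
  nm <- vapply(markers, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate marker names in simulation config")
  K <- length(markers)
  if (is.null(correlation)) correlation <- diag(K)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      nrow(correlation) != K) {
    stop("correlation must be a symmetric matrix matching the marker count")
  }
  ch <- tryCatch(chol(correlation),
                 error = function(e) stop("correlation matrix is not positive-definite"))
  structure(list(markers = markers, marker_names = nm,
                 n_benign = as.integer(n_benign),
                 n_borderline = as.integer(n_borderline),
                 n_cancer_early = as.integer(n_cancer_early),
                 n_cancer_advanced = as.integer(n_cancer_advanced),
                 correlation = correlation, chol = ch,
                 p_post_benign = p_post_benign,
                 p_post_borderline = p_post_borderline,
                 p_post_cancer = p_post_cancer,
                 n_menopause_unknown_benign = as.integer(n_menopause_unknown_benign),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Study-table composition used to apportion histology and FIGO substages.
.histology_weights <- list(
  benign = c("Endometriosis" = 44, "Teratoma" = 30,
             "Mucinous cystadenoma" = 16, "Serous cystadenoma" = 9,
             "Inflammation" = 5, "Others" = 21),
  malignant = c("Serous adenocarcinoma" = 111, "Endometrioid adenocarcinoma" = 15,
                "Mucinous adenocarcinoma" = 12, "Clear cell carcinoma" = 12,
                "Other EOC" = 3, "Granulosa cell tumor" = 2,
                "Dysgerminoma" = 1, "Other non-EOC" = 2))
.stage_weights <- list(early = c(I = 36, II = 12), advanced = c(III = 91, IV = 19))

apportion <- function(weights, n) {
  if (n == 0) return(rep(character(0), 0))
  counts <- largest_remainder(weights / sum(weights) * n)
  rep(names(weights), counts)
}

menopause_vector <- function(n, p_post, n_unknown = 0L) {
  n_unknown <- min(n_unknown, n)
  known <- n - n_unknown
  n_post <- largest_remainder(c(known * p_post, known * (1 - p_post)))[1]
  c(rep("post", n_post), rep("pre", known - n_post), rep("unknown", n_unknown))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Log10 concentrations are drawn multivariate normal with unit marginal
#' variance: the benign class sits at each marker's baseline mean, the
#' cancer class is shifted by the marker's stage-specific effect size `d`
#' (signed by direction), and borderline samples sit at the midpoint `d/2`
#' (using the mean of the two stage effects). Values are exponentiated to
#' strictly positive concentrations. Class counts, menopausal counts,
#' histology and stage composition are deterministic; only concentrations,
#' ages and within-group assignment order are random. Fully determined by
#' the seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `cohort` (a [cohort()]) and `truth` (class
#'   `ground_truth`): per-marker effect sizes, the informative set and a
#'   per-sample latent class score (the effect-size-weighted sum of signed
#'   log10 deviations, i.e. the Fisher discriminant under independence).
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) seed <- config$seed
  withr::with_seed(as.integer(seed), {
    n_cancer <- config$n_cancer_early + config$n_cancer_advanced
    n <- config$n_benign + config$n_borderline + n_cancer
    if (n == 0) stop("empty cohort requested")
    K <- length(config$markers)
    group <- c(rep("benign", config$n_benign),
               rep("borderline", config$n_borderline),
               rep("malignant", n_cancer))
    stage_group <- c(rep("none", config$n_benign + config$n_borderline),
                     rep("early", config$n_cancer_early),
                     rep("advanced", config$n_cancer_advanced))

    d_early <- vapply(config$markers, `[[`, numeric(1), "d_early")
    d_adv <- vapply(config$markers, `[[`, numeric(1), "d_advanced")
    sgn <- vapply(config$markers, `[[`, numeric(1), "sign")
    base <- vapply(config$markers, `[[`, numeric(1), "log_mean")
    d_mid <- (d_early + d_adv) / 2

    shift <- matrix(0, n, K)
    shift[stage_group == "early", ] <- rep(sgn * d_early, each = sum(stage_group == "early"))
    shift[stage_group == "advanced", ] <- rep(sgn * d_adv, each = sum(stage_group == "advanced"))
    shift[group == "borderline", ] <- rep(sgn * d_mid / 2, each = config$n_borderline)

    z <- matrix(rnorm(n * K), n, K) %*% config$chol
    logconc <- sweep(z + shift, 2, base, `+`)
    conc <- 10^logconc
    colnames(conc) <- config$marker_names

    histology <- c(sample(apportion(.histology_weights$benign, config$n_benign)),
                   rep("Borderline tumor", config$n_borderline),
                   sample(apportion(.histology_weights$malignant, n_cancer)))
    figo <- rep("none", n)
    figo[stage_group == "early"] <- sample(apportion(.stage_weights$early, config$n_cancer_early))
    figo[stage_group == "advanced"] <- sample(apportion(.stage_weights$advanced, config$n_cancer_advanced))

    meno <- c(sample(menopause_vector(config$n_benign, config$p_post_benign,
                                      config$n_menopause_unknown_benign)),
              sample(menopause_vector(config$n_borderline, config$p_post_borderline)),
              sample(menopause_vector(n_cancer, config$p_post_cancer)))

    age <- numeric(n)
    cancerish <- group == "malignant"
    age[!cancerish] <- rnorm(sum(!cancerish), 40.6, 12.2)
    age[cancerish] <- rnorm(sum(cancerish), 53.8, 10.4)
    age <- pmax(age, 18)

    samples <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      group = group, histology = histology, figo_stage = figo,
      menopause = meno, age = round(age, 1),
      stringsAsFactors = FALSE)

    informative <- config$marker_names[d_mid > 0]
    latent <- as.numeric((logconc - rep(base, each = n)) %*% (sgn * d_mid))
    truth <- structure(list(
      markers = data.frame(marker = config$marker_names,
                           d_early = d_early, d_advanced = d_adv,
                           direction = ifelse(sgn > 0, "higher_in_cancer",
                                              "lower_in_cancer"),
                           informative = d_mid > 0, stringsAsFactors = FALSE),
      informative = informative,
      latent_score = latent), class = "ground_truth")

    list(cohort = cohort(samples, conc), truth = truth)
  })
}

#' Default study-like simulation scenario
#'
#' Twenty-three urinary markers named after the study panel: four
#' informative markers calibrated to the reported single-marker AUCs —
#' HE4 (0.822, higher in cancer), TTR (0.789 early-stage / 0.757
#' advanced-stage, higher), CEA (0.627, lower) and creatinine (0.622,
#' lower) — plus nineteen null markers, with the study's class sizes and
#' menopausal composition.
#'
#' @param correlated if `TRUE`, impose uniform r = 0.3 correlation among
#'   the four informative markers (independence otherwise); useful for
#'   stress-testing joint panel separation.
#' @param seed default seed stored in the config.
#' @return a [simulation_config()] with 23 markers.
#' @export
paperlike_scenario <- function(correlated = FALSE, seed = 1L) {
  null_names <- c("VCAM", "Leptin", "Prolactin", "CRP", "PDGF-AA", "NCAM",
                  "Mesomark", "MPO", "Cyfra21-1", "CA19-9", "IL6", "MIF",
                  "ApoAI", "ApoCIII", "PAI-1", "CA125", "OPN", "IL8", "CA15-3")
  specs <- c(list(marker_spec("HE4", auc = 0.822, direction = "higher"),
                  marker_spec("TTR", auc_early = 0.789, auc_advanced = 0.757,
                              direction = "higher"),
                  marker_spec("CEA", auc = 0.627, direction = "lower"),
                  marker_spec("Creatinine", auc = 0.622, direction = "lower")),
             lapply(null_names, marker_spec))
  # Table-2-like column order so informative markers are not positionally first
  ord <- match(c("HE4", "VCAM", "Leptin", "TTR", "Prolactin", "CRP", "PDGF-AA",
                 "NCAM", "Mesomark", "MPO", "Cyfra21-1", "CEA", "Creatinine",
                 "CA19-9", "IL6", "MIF", "ApoAI", "ApoCIII", "PAI-1", "CA125",
                 "OPN", "IL8", "CA15-3"),
               vapply(specs, `[[`, character(1), "name"))
  specs <- specs[ord]
  correlation <- NULL
  if (correlated) {
    K <- length(specs)
    correlation <- diag(K)
    inf <- which(vapply(specs, function(m) m$d_early > 0, logical(1)))
    correlation[inf, inf] <- 0.3
    diag(correlation) <- 1
  }
  simulation_config(specs, correlation = correlation, seed = seed)
}
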