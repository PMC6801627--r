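#' Pipeline configuration
#'
#' Bundles every stage option for [run_pipeline()]. The input is either a
#' cohort file path or a [simulation_config()]; the seed is mandatory and
#' drives every stochastic stage through derived sub-streams.
#'
#' @param input path to a cohort CSV/TSV, or a [simulation_config()].
#' @param out_dir output directory (created if absent).
#' @param seed master integer seed.
#' @param exclusions an [exclusion_rules()] set.
#' @param screen_correction multiplicity correction for screening.
#' @param subsample_iters,subsample_frac,subsample_replace options for the
#'   single-marker subsample AUC stage.
#' @param lasso_iters repetitions for [rank_by_lasso()].
#' @param nested a [nested_cv_config()] (its seed is overridden by `seed`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir, seed,
                            exclusions = exclusion_rules(),
                            screen_correction = "bonferroni",
                            subsample_iters = 2000, subsample_frac = 0.8,
                            subsample_replace = FALSE,
                            lasso_iters = 2000,
                            nested = nested_cv_config()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.character(input)) {
    if (!file.exists(input)) stop("input file not found: ", input)
  } else if (!inherits(input, "simulation_config")) {
    stop("input must be a file path or a simulation_config")
  }
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 exclusions = exclusions,
                 screen_correction = screen_correction,
                 subsample_iters = subsample_iters,
                 subsample_frac = subsample_frac,
                 subsample_replace = subsample_replace,
                 lasso_iters = lasso_iters, nested = nested),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# rolling polynomial hash over the serialized object; manifest fingerprint
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

eval_to_list <- function(ev) {
  lapply(unclass(ev), function(e) list(
    auc = round(e$auc$auc, 3),
    ci = round(c(e$auc$ci_low, e$auc$ci_high), 3),
    sn = round(e$confusion$sn, 1), sp = round(e$confusion$sp, 1),
    ppv = round(e$confusion$ppv, 1), npv = round(e$confusion$npv, 1),
    n_pos = e$n_pos, n_neg = e$n_neg,
    sn_at_sp = e$sn_at_sp))
}

#' Run the full panel-discovery pipeline
#'
#' Executes exclusions, per-marker screening, single-marker subsample AUC
#' ranking, lasso importance ranking, nested cross-validated panel
#' selection, and final evaluation (per stage subgroup and, for the
#' largest panel, with the menopausal covariate). Writes all reports to
#' `config$out_dir` along with a manifest recording the seed, package
#' version and a configuration fingerprint.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   vector of files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seeds <- derive_seeds(config$seed, 4L)
  files <- character(0)

  coh <- stage("load", {
    if (is.character(config$input)) read_cohort(config$input)
    else generate_cohort(config$input, seed = seeds[1])$cohort
  })
  summ <- stage("summary", summarize_cohort(coh))
  jsonlite::write_json(unclass(summ), out("cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, out("cohort_summary.json"))

  coh <- stage("exclusions", apply_exclusions(coh, config$exclusions))

  scr <- stage("screening", screen_markers(coh, config$screen_correction))
  files <- c(files, write_tsv(scr, out("screening.tsv")))

  single <- stage("single_marker_auc",
                  rank_single_markers(coh, n_iter = config$subsample_iters,
                                      frac = config$subsample_frac,
                                      seed = seeds[2],
                                      replace = config$subsample_replace))
  tab2 <- single
  num <- vapply(tab2, is.numeric, logical(1))
  tab2[num] <- lapply(tab2[num], round, 3)
  files <- c(files, write_tsv(tab2, out("single_marker_auc.tsv")))

  imp <- stage("lasso_rank",
               rank_by_lasso(coh, n_iter = config$lasso_iters, seed = seeds[3]))
  files <- c(files, write_tsv(imp$summary, out("lasso_rank.tsv")))
  long <- data.frame(iteration = rep(seq_len(nrow(imp$coefficients)),
                                     ncol(imp$coefficients)),
                     marker = rep(colnames(imp$coefficients),
                                  each = nrow(imp$coefficients)),
                     coefficient = as.numeric(imp$coefficients))
  files <- c(files, write_tsv(long, out("lasso_coefficients.tsv")))

  ncv_config <- config$nested
  ncv_config$seed <- seeds[4]
  if (is.null(ncv_config$pool)) {
    ncv_config$pool <- utils::head(imp$summary$marker, ncv_config$pool_size)
  }
  ncv <- stage("panel_selection", nested_cv_select(coh, ncv_config))
  files <- c(files, write_tsv(ncv$selection, out("panel_selection.tsv")))
  files <- c(files, write_tsv(ncv$summary, out("panel_summary.tsv")))

  evals <- stage("evaluation", {
    ev <- lapply(ncv$models, function(m) eval_to_list(evaluate_panel(m, coh)))
    top <- ncv$models[[length(ncv$models)]]
    meno_model <- fit_panel(coh, top$markers, include_menopause = TRUE)
    ev$with_menopause <- eval_to_list(evaluate_panel(meno_model, coh))
    ev
  })
  jsonlite::write_json(evals, out("panel_evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, out("panel_evaluation.json"))

  for (k in names(ncv$models)) {
    m <- ncv$models[[k]]
    p <- predict_panel(m, coh)
    ok <- !is.na(p)
    rc <- roc_curve(p[ok], malignant_labels(subset_cohort(coh, ok)))
    files <- c(files, write_tsv(rc, out(sprintf("roc_panel_%s.tsv", k))))
  }

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("uropanel")),
                   r_version = as.character(getRversion()),
                   config_hash = config_hash(unclass(config)[setdiff(names(config), "out_dir")]),
                   n_samples_analyzed = n_samples(coh),
                   files = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, out("manifest.json"))

  invisible(list(cohort = coh, summary = summ, screening = scr,
                 single_marker = single, lasso = imp, nested = ncv,
                 evaluations = evals, files = files))
}
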