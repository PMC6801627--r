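#' Construct a cohort table
#'
#' A cohort couples per-sample clinical metadata with a samples-by-markers
#' concentration matrix. Concentrations are in marker-native units (e.g.
#' pg/mL) and must be non-negative where observed; missing values are `NA`.
#'
#' @param samples data frame with columns `sample_id` (unique strings),
#'   `group` (`benign`, `borderline`, `malignant`), `histology` (free text),
#'   `figo_stage` (`I`, `II`, `III`, `IV`, `none`), `menopause` (`pre`,
#'   `post`, `unknown`) and `age` (years, `NA` allowed).
#' @param concentrations numeric matrix, one row per sample (in the same
#'   order as `samples`), one column per uniquely named marker.
#' @return object of class `cohort`.
#' @export
cohort <- function(samples, concentrations) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "histology", "figo_stage", "menopause", "age")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("samples is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "))
  }
  bad_group <- setdiff(unique(samples$group), c("benign", "borderline", "malignant"))
  if (length(bad_group)) {
    stop("unknown group label: ", paste(bad_group, collapse = ", "))
  }
  bad_stage <- setdiff(unique(samples$figo_stage), c("I", "II", "III", "IV", "none"))
  if (length(bad_stage)) {
    stop("unknown figo_stage label: ", paste(bad_stage, collapse = ", "))
  }
  bad_meno <- setdiff(unique(samples$menopause), c("pre", "post", "unknown"))
  if (length(bad_meno)) {
    stop("unknown menopause label: ", paste(bad_meno, collapse = ", "))
  }
  concentrations <- as.matrix(concentrations)
  if (ncol(concentrations) < 1) stop("cohort has no marker columns")
  if (nrow(concentrations) != nrow(samples)) {
    stop("concentration rows (", nrow(concentrations),
         ") do not match sample count (", nrow(samples), ")")
  }
  if (is.null(colnames(concentrations)) || anyDuplicated(colnames(concentrations))) {
    stop("marker names must be present and unique")
  }
  storage.mode(concentrations) <- "double"
  neg <- which(!is.na(concentrations) & concentrations < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative concentration at sample '%s', marker '%s'",
                 samples$sample_id[neg[1, 1]], colnames(concentrations)[neg[1, 2]]))
  }
  rownames(concentrations) <- samples$sample_id
  structure(list(samples = samples, concentrations = concentrations),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cnt <- table(factor(x$samples$group, c("benign", "borderline", "malignant")))
  cat(sprintf("cohort: %d samples (%d benign / %d borderline / %d malignant), %d markers\n",
              nrow(x$samples), cnt[["benign"]], cnt[["borderline"]],
              cnt[["malignant"]], ncol(x$concentrations)))
  invisible(x)
}

#' Number of samples in a cohort
#' @param x a `cohort`.
#' @return integer sample count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' Marker names of a cohort
#' @param x a `cohort`.
#' @return character vector of marker names in column order.
#' @export
markers <- function(x) colnames(x$concentrations)

#' Subset a cohort by sample index
#' @param x a `cohort`.
#' @param idx integer or logical index over samples.
#' @return a new `cohort` with the selected samples, order preserved.
#' @export
subset_cohort <- function(x, idx) {
  cohort(x$samples[idx, , drop = FALSE],
         x$concentrations[idx, , drop = FALSE])
}

#' Benign-versus-malignant class labels
#'
#' @param x a `cohort`; borderline samples are not labelled and must be
#'   excluded beforehand (see [apply_exclusions()]).
#' @return logical vector, `TRUE` for malignant.
#' @keywords internal
malignant_labels <- function(x) {
  if (any(x$samples$group == "borderline")) {
    stop("cohort still contains borderline samples; apply_exclusions() first")
  }
  x$samples$group == "malignant"
}

#' Read a cohort table from CSV/TSV
#'
#' Expects a UTF-8 file with one header row; comma or tab field separators
#' are auto-detected from the header. Metadata columns `sample_id`, `group`,
#' `histology`, `figo_stage`, `menopause`, `age` come first (any order);
#' every remaining column is a marker. `NA` is the missing token. A `schema`
#' mapping renames non-standard metadata headers.
#'
#' @param path file path.
#' @param schema optional named character vector mapping standard names to
#'   the file's column headers, e.g. `c(sample_id = "id")`.
#' @return a validated [cohort()]; input row order preserved.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   na.strings = "NA", check.names = FALSE,
                   stringsAsFactors = FALSE, encoding = "UTF-8")
  meta_cols <- c("sample_id", "group", "histology", "figo_stage", "menopause", "age")
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df)) {
        stop("schema column not found in file: ", schema[[std]])
      }
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  absent <- setdiff(meta_cols, names(df))
  if (length(absent)) stop("missing metadata columns: ", paste(absent, collapse = ", "))
  marker_cols <- setdiff(names(df), meta_cols)
  if (!length(marker_cols)) stop("no marker columns found in ", path)
  conc <- as.matrix(df[marker_cols])
  if (!is.numeric(conc)) {
    bad <- marker_cols[!vapply(df[marker_cols], is.numeric, logical(1))]
    stop("non-numeric concentration column(s): ", paste(bad, collapse = ", "))
  }
  samples <- df[meta_cols]
  samples$sample_id <- as.character(samples$sample_id)
  samples$age <- as.numeric(samples$age)
  out <- cohort(samples, conc)
  cnt <- table(factor(out$samples$group, c("benign", "borderline", "malignant")))
  message(sprintf("read %d samples (%d benign / %d borderline / %d malignant), %d markers",
                  n_samples(out), cnt[["benign"]], cnt[["borderline"]],
                  cnt[["malignant"]], length(marker_cols)))
  out
}

#' Write a cohort table to CSV/TSV
#'
#' Inverse of [read_cohort()]: metadata columns followed by one column per
#' marker, `NA` as the missing token.
#'
#' @param x a `cohort`.
#' @param path output path.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = "\t") {
  df <- cbind(x$samples, as.data.frame(x$concentrations, check.names = FALSE))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Exclusion rule set
#'
#' Each rule names a metadata field and the values whose samples are dropped.
#' The default reproduces the study design: borderline tumors are excluded
#' from the benign-versus-malignant analysis.
#'
#' @param ... named character vectors, e.g. `group = "borderline"`.
#' @return object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(...) {
  rules <- list(...)
  if (!length(rules)) rules <- list(group = "borderline")
  if (is.null(names(rules)) || any(!nzchar(names(rules)))) {
    stop("exclusion rules must be named by metadata field")
  }
  structure(rules, class = "exclusion_rules")
}

#' Drop samples matching exclusion rules
#'
#' @param x a `cohort`.
#' @param rules an [exclusion_rules()] set; default drops borderline tumors.
#' @return a new `cohort` without the matching samples; the input is
#'   untouched. Idempotent for a fixed rule set.
#' @export
apply_exclusions <- function(x, rules = exclusion_rules()) {
  stopifnot(inherits(x, "cohort"))
  if (!inherits(rules, "exclusion_rules")) rules <- do.call(exclusion_rules, as.list(rules))
  drop <- rep(FALSE, n_samples(x))
  for (field in names(rules)) {
    if (!field %in% names(x$samples)) {
      stop("exclusion rule references unknown field: ", field)
    }
    drop <- drop | x$samples[[field]] %in% rules[[field]]
  }
  message(sprintf("excluded %d of %d samples", sum(drop), length(drop)))
  subset_cohort(x, !drop)
}

#' Cohort accounting summary
#'
#' Counts and one-decimal percentages per pathology group (over the grand
#' total), histology (over its group total), menopausal status (over group
#' totals) and FIGO stage (over the malignant total), plus early (I+II)
#' versus advanced (III+IV) stage-group counts.
#'
#' @param x a non-empty `cohort`.
#' @return object of class `cohort_summary`: a list of data frames
#'   `groups`, `histology`, `menopause`, `stage`, `stage_groups`.
#' @export
summarize_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (n_samples(x) == 0) stop("cannot summarize an empty cohort")
  s <- x$samples
  total <- nrow(s)
  glv <- intersect(c("benign", "borderline", "malignant"), unique(s$group))
  gcnt <- vapply(glv, function(g) sum(s$group == g), integer(1))
  groups <- data.frame(group = glv, count = gcnt, pct = pct1(gcnt, total),
                       row.names = NULL)

  histology <- do.call(rbind, lapply(glv, function(g) {
    sub <- s[s$group == g, ]
    h <- sort(table(sub$histology), decreasing = TRUE)
    data.frame(group = g, histology = names(h), count = as.integer(h),
               pct = pct1(as.integer(h), nrow(sub)), row.names = NULL)
  }))

  menopause <- do.call(rbind, lapply(glv, function(g) {
    sub <- s[s$group == g, ]
    m <- vapply(c("pre", "post", "unknown"),
                function(v) sum(sub$menopause == v), integer(1))
    data.frame(group = g, menopause = names(m), count = as.integer(m),
               pct = pct1(as.integer(m), nrow(sub)), row.names = NULL)
  }))

  mal <- s[s$group == "malignant", ]
  stg <- vapply(c("I", "II", "III", "IV"),
                function(v) sum(mal$figo_stage == v), integer(1))
  stage <- data.frame(figo_stage = names(stg), count = as.integer(stg),
                      pct = pct1(as.integer(stg), nrow(mal)), row.names = NULL)
  sg <- c(early = sum(stg[c("I", "II")]), advanced = sum(stg[c("III", "IV")]))
  stage_groups <- data.frame(stage_group = names(sg), count = as.integer(sg),
                             pct = pct1(as.integer(sg), nrow(mal)), row.names = NULL)

  structure(list(total = total, groups = groups, histology = histology,
                 menopause = menopause, stage = stage,
                 stage_groups = stage_groups),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort summary:", x$total, "samples\n")
  print(x$groups, row.names = FALSE)
  cat("FIGO stage groups (of malignant):\n")
  print(x$stage_groups, row.names = FALSE)
  invisible(x)
}
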