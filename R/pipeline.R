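#' Run the full VOC biomarker-discovery pipeline
#'
#' Orchestrates the analysis end to end on one cohort:
#' internal-standard normalisation, median collapsing of technical
#' replicates, log transform + autoscaling, PCA outlier screening, PLS-DA
#' (components chosen by cross-validated Q2 when `A = "auto"`), an optional
#' permutation test, Monte-Carlo stability selection, the univariate
#' t/FDR/ROC battery, and the merge into a putative marker set. Every
#' random stage is derived from `seed`, so a rerun with the same inputs and
#' seed is reproducible bit for bit.
#'
#' @param cohort A `voc_cohort` from [generate_cohort()], or a raw cohort
#'   tibble (then supply `is_mapping`).
#' @param is_mapping Feature-to-internal-standard mapping; taken from the
#'   cohort object when omitted. `NULL` together with a plain tibble skips
#'   normalisation.
#' @param missing_policy Missing-value policy for [log_autoscale()].
#' @param A `"auto"` (choose by Q2, capped at 5) or an integer.
#' @param cv_folds Folds for Q2/AUC cross-validation.
#' @param n_permutations Label permutations for the validity test; `0`
#'   skips the test (and the validity gate).
#' @param validity_alpha Significance level of the permutation validity
#'   gate: when the PLS-DA model fails the permutation test
#'   (`p >= validity_alpha`), its stability selections are not admitted to
#'   the marker set — a non-discriminant model must not force markers, as
#'   in the acid-condition negative result. The stability table is still
#'   reported in full.
#' @param stability A [stability_spec()]; its seed is overridden by `seed`.
#' @param p_max,q_max,auc_min Univariate marker gate thresholds.
#' @param remove_outliers Drop subjects flagged by the outlier screen before
#'   modelling (default `FALSE`: the screen reports only).
#' @param out_dir Optional directory; when given, writes `summary.json`,
#'   `markers.tsv`, `stability.tsv` and `outliers.tsv`.
#' @param seed Master seed for all random stages.
#' @return An object of class `voc_run` bundling every stage result plus a
#'   one-row `summary` tibble and a `manifest` (seed, versions, input and
#'   output hashes).
#' @export
run_pipeline <- function(cohort, is_mapping = NULL,
                         missing_policy = "half_min", A = "auto",
                         cv_folds = 7, n_permutations = 199,
                         validity_alpha = 0.05,
                         stability = stability_spec(),
                         p_max = 0.05, q_max = 0.1, auc_min = 0.50,
                         remove_outliers = FALSE, out_dir = NULL,
                         seed = 1L) {
  if (inherits(cohort, "voc_cohort")) {
    raw <- cohort$table
    is_mapping <- is_mapping %||% cohort$is_mapping
  } else {
    raw <- cohort
  }
  seed <- as.integer(seed)

  # Each stage runs under a stage-named error wrapper; on failure a FAILED
  # marker naming the stage is left next to any partial outputs.
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "voclearn_error_pipeline", parent = e)
    })
  }

  normalized <- stage("normalize", {
    if (is.null(is_mapping)) raw else {
      normalize_to_internal_standard(raw, is_mapping)
    }
  })
  collapsed <- stage("collapse_replicates", {
    if ("replicate" %in% names(normalized)) {
      collapse_replicates(normalized)
    } else {
      normalized
    }
  })
  processed <- stage("log_autoscale",
                     log_autoscale(collapsed, missing_policy = missing_policy))
  log_data <- attr(processed, "log_data")

  pca <- stage("pca", fit_pca(
    processed,
    n_components = min(3L, nrow(processed) - 1L,
                       length(.feature_cols(processed)))
  ))
  outliers <- stage("outlier_screen", outlier_screen(pca))
  if (remove_outliers && any(outliers$report$flagged)) {
    keep <- !outliers$report$flagged
    processed <- processed[keep, ]
    log_data <- log_data[keep, ]
  }

  if (identical(A, "auto")) {
    A <- stage("choose_ncomp",
               choose_ncomp(processed, max_A = 5, k = cv_folds, seed = seed)$A)
  }
  model <- stage("plsda", post_transform(fit_plsda(processed, A = A)))
  cv <- stage("cross_validate",
              cross_validate(processed, A = A, k = cv_folds, seed = seed))
  perm <- if (n_permutations > 0) {
    stage("permutation_test",
          permutation_test(processed, A = A, n_perm = n_permutations,
                           k = cv_folds, seed = seed + 1L))
  }

  stability$seed <- seed + 2L
  stab <- stage("stability_select",
                stability_select(processed, spec = stability, A = A))
  uni <- stage("univariate", univariate_stats(log_data))
  multivariate_valid <- is.null(perm) || perm$p_value < validity_alpha
  stab_admitted <- stab
  if (!multivariate_valid) stab_admitted$selected <- character(0)
  markers <- merge_selections(stab_admitted, uni, p_max = p_max,
                              q_max = q_max, auc_min = auc_min)

  summary <- tibble::tibble(
    n_subjects = nrow(processed),
    n_features = length(.feature_cols(processed)),
    A = model$A,
    R2Y = model$R2Y,
    Q2 = cv$Q2,
    cv_auc = cv$cv_auc,
    permutation_p = if (is.null(perm)) NA_real_ else perm$p_value,
    multivariate_valid = multivariate_valid,
    stability_auc_median = stab$auc_median,
    stability_auc_p5 = stab$auc_p5,
    n_outliers_flagged = sum(outliers$report$flagged),
    n_markers = nrow(markers$members),
    seed = seed
  )
  manifest <- list(
    stage = "run_pipeline",
    seed = seed,
    package_version = as.character(utils::packageVersion("voclearn")),
    input_hash = rlang::hash(raw),
    summary_hash = rlang::hash(summary),
    markers_hash = rlang::hash(markers$members),
    stability_hash = rlang::hash(stab$selection_frequency)
  )

  run <- structure(
    list(summary = summary, model = model, cv = cv, permutation = perm,
         outliers = outliers, stability = stab, univariate = uni,
         markers = markers, processed = processed, manifest = manifest),
    class = "voc_run"
  )
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    c(as.list(run$summary), run$manifest),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(run$markers$members, file.path(out_dir, "markers.tsv"))
  readr::write_tsv(run$stability$selection_frequency,
                   file.path(out_dir, "stability.tsv"))
  readr::write_tsv(run$outliers$report, file.path(out_dir, "outliers.tsv"))
  invisible(out_dir)
}

#' @export
print.voc_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<voc_run> %d subjects x %d features\n",
           "  PLS-DA: A = %d, R2Y = %.3f, Q2 = %.3f, cv AUC = %.3f%s\n",
           "  stability: AUC median %.3f, 5th pct %.3f\n",
           "  markers: %d (outliers flagged: %d)\n"),
    s$n_subjects, s$n_features, s$A, s$R2Y, s$Q2, s$cv_auc,
    if (is.na(s$permutation_p)) "" else sprintf(", permutation p = %.4g",
                                                s$permutation_p),
    s$stability_auc_median, s$stability_auc_p5, s$n_markers,
    s$n_outliers_flagged
  ))
  invisible(x)
}

#' @method glance voc_run
#' @export
glance.voc_run <- function(x, ...) x$summary

#' @method tidy voc_run
#' @export
tidy.voc_run <- function(x, ...) x$markers$members
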