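#' Normalise peak areas to internal standards
#'
#' Replaces every feature's peak area by its ratio to the mapped
#' internal-standard peak area measured in the same injection, then drops the
#' internal-standard columns. Missing feature values stay missing; a missing
#' or nonpositive standard peak is an error because the whole injection is
#' then uninterpretable.
#'
#' @param data A cohort table: columns `subject_id`, `group`, `replicate`,
#'   feature columns and internal-standard columns.
#' @param mapping Named character vector: `names(mapping)` are feature
#'   columns, values are the internal-standard column each is normalised by.
#'
#' @return A tibble like `data` with ratio-normalised features and no
#'   internal-standard columns.
#' @export
normalize_to_internal_standard <- function(data, mapping) {
  feats <- names(mapping)
  standards <- unique(unname(mapping))
  missing_cols <- setdiff(c(feats, standards), names(data))
  if (length(missing_cols)) {
    abort(paste0("Columns not found in `data`: ",
                 paste(missing_cols, collapse = ", ")),
          class = "voclearn_error_parameter")
  }
  S <- as.matrix(data[standards])
  bad <- which(is.na(S) | S <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Internal standard '%s' is missing or nonpositive in injection %d (subject %s).",
      standards[bad[1, 2]], bad[1, 1], data$subject_id[bad[1, 1]]
    ), class = "voclearn_error_normalization")
  }
  out <- data
  for (f in feats) {
    out[[f]] <- data[[f]] / data[[mapping[[f]]]]
  }
  out[setdiff(names(out), setdiff(standards, feats))]
}

#' Collapse technical replicates to per-subject medians
#'
#' Reduces a table with several injections per subject to one row per subject
#' by taking, per feature, the median of that subject's non-missing replicate
#' values. A cell stays missing only if all replicates are missing.
#'
#' @param data A cohort table with a `replicate` column.
#' @return A tibble with one row per subject (columns `subject_id`, `group`,
#'   features), in order of first appearance.
#' @export
collapse_replicates <- function(data) {
  if (!"replicate" %in% names(data)) {
    abort("`data` must contain a `replicate` column.",
          class = "voclearn_error_input")
  }
  feats <- .feature_cols(data)
  med_na <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else median(x)
  }
  data |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feats), med_na),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$subject_id, unique(data$subject_id)))
}

#' Log-transform and autoscale a per-subject feature table
#'
#' The last preprocessing step: missing cells are imputed by half the
#' feature's minimum observed value (`half_min`, the usual detection-floor
#' convention for GC-MS) or the feature is dropped (`drop_feature`); values
#' are natural-log transformed; each feature is centred to mean 0 and scaled
#' to unit sample SD (autoscaling). Features that are missing in every
#' subject, or constant after the log, are dropped with a warning rather
#' than an error.
#'
#' @param data A per-subject table (`subject_id`, `group`, features), e.g.
#'   from [collapse_replicates()]; all values positive where present.
#' @param missing_policy `"half_min"` (default) or `"drop_feature"`.
#'
#' @return A tibble `subject_id`, `group`, autoscaled features, with
#'   attributes `log_data` (the imputed log-scale tibble, used by the
#'   univariate battery), `centers`, `scales` and `dropped`.
#' @export
log_autoscale <- function(data, missing_policy = c("half_min", "drop_feature")) {
  missing_policy <- match.arg(missing_policy)
  if ("replicate" %in% names(data)) {
    abort("Collapse replicates before log_autoscale().",
          class = "voclearn_error_input")
  }
  X <- .feature_matrix(data)
  if (any(X <= 0, na.rm = TRUE)) {
    abort("All abundances must be positive for the log transform.",
          class = "voclearn_error_input")
  }
  dropped <- character(0)

  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    dropped <- colnames(X)[all_na]
    warn(paste0("Dropping features missing in all subjects: ",
                paste(dropped, collapse = ", ")))
    X <- X[, !all_na, drop = FALSE]
  }
  has_na <- colSums(is.na(X)) > 0
  if (missing_policy == "drop_feature") {
    if (any(has_na)) {
      dropped <- c(dropped, colnames(X)[has_na])
      X <- X[, !has_na, drop = FALSE]
    }
  } else {
    for (j in which(has_na)) {
      X[is.na(X[, j]), j] <- min(X[, j], na.rm = TRUE) / 2
    }
  }
  L <- log(X)
  sds <- apply(L, 2, sd)
  const <- sds < 1e-12
  if (any(const)) {
    warn(paste0("Dropping constant features: ",
                paste(colnames(L)[const], collapse = ", ")))
    dropped <- c(dropped, colnames(L)[const])
    L <- L[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  centers <- colMeans(L)
  Z <- sweep(sweep(L, 2, centers), 2, sds, "/")

  out <- dplyr::bind_cols(
    data[c("subject_id", "group")],
    tibble::as_tibble(`dimnames<-`(Z, list(NULL, colnames(L))))
  )
  attr(out, "log_data") <- dplyr::bind_cols(
    data[c("subject_id", "group")],
    tibble::as_tibble(`dimnames<-`(L, list(NULL, colnames(L))))
  )
  attr(out, "centers") <- centers
  attr(out, "scales") <- sds
  attr(out, "dropped") <- dropped
  out
}

#' Kovats retention index
#'
#' Expresses a retention time on the Kovats scale, anchored at 100 times the
#' carbon number of the bracketing n-alkanes. `"linear"` (the van den Dool
#' form, appropriate for temperature-programmed runs and the default)
#' interpolates retention times directly; `"logarithmic"` (the isothermal
#' Kovats definition) interpolates their logarithms.
#'
#' @param rt Retention time(s), minutes.
#' @param alkane_rts Named numeric vector of alkane retention times; names
#'   are carbon numbers, contiguous within 8..20, times strictly increasing.
#' @param mode `"linear"` or `"logarithmic"`.
#' @return Numeric retention index (vectorised over `rt`), in \[800, 2000\].
#' @export
#' @examples
#' alk <- setNames(c(2, 5, 10, 20), 8:11)
#' kovats_index(7.5, alk)                        # midway C9-C10 -> 950
#' kovats_index(10 * sqrt(2), alk, "logarithmic") # log-midpoint C10-C11 -> 1050
kovats_index <- function(rt, alkane_rts, mode = c("linear", "logarithmic")) {
  mode <- match.arg(mode)
  carbons <- suppressWarnings(as.integer(names(alkane_rts)))
  if (anyNA(carbons) || length(carbons) < 2 ||
      !all(diff(carbons) == 1L) || min(carbons) < 8L || max(carbons) > 20L) {
    abort("`alkane_rts` names must be contiguous carbon numbers within 8..20.",
          class = "voclearn_error_input")
  }
  if (any(diff(alkane_rts) <= 0)) {
    abort("Alkane retention times must be strictly increasing.",
          class = "voclearn_error_input")
  }
  if (any(rt < alkane_rts[1] | rt > alkane_rts[length(alkane_rts)])) {
    abort("`rt` outside the alkane retention window.",
          class = "voclearn_error_range")
  }
  x <- if (mode == "linear") rt else log(rt)
  ax <- if (mode == "linear") alkane_rts else log(alkane_rts)
  i <- pmin(findInterval(rt, alkane_rts), length(alkane_rts) - 1L)
  unname(100 * (carbons[i] + (x - ax[i]) / (ax[i + 1] - ax[i])))
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = insulin (mU/L) x glucose (mmol/L) / 22.5`.
#'
#' @param insulin Fasting serum insulin, mU/L (> 0).
#' @param glucose Fasting blood glucose, mmol/L (> 0).
#' @return Numeric HOMA-IR index (vectorised).
#' @export
#' @examples
#' homa_ir(22.5, 1) # 1
homa_ir <- function(insulin, glucose) {
  if (any(!is.finite(insulin)) || any(!is.finite(glucose)) ||
      any(insulin <= 0) || any(glucose <= 0)) {
    abort("`insulin` and `glucose` must be positive and finite.",
          class = "voclearn_error_parameter")
  }
  insulin * glucose / 22.5
}

#' Welch's t-test from group summary statistics
#'
#' Two-sided Welch (unequal-variance) t-test computed from published
#' mean/SD/n summaries, with the Welch-Satterthwaite degrees of freedom.
#' Useful for checking printed cohort-characteristics tables.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A tibble with columns `t`, `df`, `p` (vectorised over inputs).
#' @export
#' @examples
#' welch_t_from_summary(12.9, 1.5, 28, 12.5, 1.1, 21)
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) {
    abort("Group sizes must be at least 2.", class = "voclearn_error_parameter")
  }
  if (any(sd1 < 0) || any(sd2 < 0)) {
    abort("SDs must be nonnegative.", class = "voclearn_error_parameter")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Path to a packaged fixture table
#'
#' The package ships transcriptions of the study-design tables used in
#' examples and tests: `"table1_cohort"` (cohort characteristics summary
#' statistics), `"table2_acid_vocs"` and `"table3_alkaline_vocs"` (VOC
#' identification tables for the two headspace pH conditions) and
#' `"table4_markers"` (the univariate statistics of the putative marker set).
#'
#' @param name Fixture name (see Details).
#' @return File path of the packaged TSV.
#' @export
voc_fixture <- function(name = c("table1_cohort", "table2_acid_vocs",
                                 "table3_alkaline_vocs", "table4_markers")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "voclearn",
                      mustWork = TRUE)
  path
}

#' Parse a VOC identification table
#'
#' Reads a tab-separated VOC identification table (UTF-8, header row; empty
#' cells and em-dashes are absent values) into one record per identified
#' compound: name, chemical class, main fragment ion m/z (slash-separated
#' values preserved and also split into an integer list-column), library
#' match percentage, experimental and literature Kovats retention indices,
#' identification method and per-group occurrence percentages.
#'
#' @param path Path to the TSV, e.g. from [voc_fixture()].
#' @param condition Optional condition label (e.g. `"acid"`, `"alkaline"`)
#'   added as a column.
#' @return A tibble with one row per VOC record.
#' @export
#' @examples
#' nrow(parse_voc_table(voc_fixture("table2_acid_vocs"), condition = "acid"))
parse_voc_table <- function(path, condition = NULL) {
  cols <- c("metabolite", "chemical_class", "mz", "match_percent", "ri_cal",
            "ri_lit", "id_method", "occurrence_nw", "occurrence_ow")
  tbl <- readr::read_tsv(
    path, na = c("", "—"), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      metabolite = readr::col_character(),
      chemical_class = readr::col_character(),
      mz = readr::col_character(),
      match_percent = readr::col_double(),
      ri_cal = readr::col_double(),
      ri_lit = readr::col_double(),
      id_method = readr::col_character(),
      occurrence_nw = readr::col_double(),
      occurrence_ow = readr::col_double()
    )
  )
  if (!all(cols %in% names(tbl))) {
    abort(paste0("Malformed VOC table, missing columns: ",
                 paste(setdiff(cols, names(tbl)), collapse = ", ")),
          class = "voclearn_error_parse")
  }
  bad <- which(
    is.na(tbl$metabolite) | is.na(tbl$id_method) |
      !grepl("^(RI|MS|S)(/(RI|MS|S))*$", tbl$id_method) |
      (!is.na(tbl$occurrence_nw) & (tbl$occurrence_nw < 0 | tbl$occurrence_nw > 100)) |
      (!is.na(tbl$occurrence_ow) & (tbl$occurrence_ow < 0 | tbl$occurrence_ow > 100)) |
      (!is.na(tbl$mz) & !grepl("^[0-9]+(/[0-9]+)*$", tbl$mz))
  )
  if (length(bad)) {
    abort(sprintf("Malformed VOC table row(s) at line(s): %s (1-based, excluding header).",
                  paste(bad, collapse = ", ")),
          class = "voclearn_error_parse")
  }
  tbl$mz_values <- lapply(strsplit(tbl$mz, "/", fixed = TRUE), as.integer)
  if (!is.null(condition)) tbl$condition <- condition
  tbl
}
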