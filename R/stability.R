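#' Specify a Monte-Carlo stability-selection run
#'
#' @param n_subsamples Number of Monte-Carlo subsamples (default 300).
#' @param inclusion_prob Probability that a subject enters a subsample
#'   (default 0.70).
#' @param vip_threshold_grid Candidate VIP cutoffs; for each subsample the
#'   cutoff maximising cross-validated Q2 is used.
#' @param cv_folds Folds of the inner Q2 cross-validation (default 7).
#' @param frequency_cutoff Selection-frequency cutoff defining the selected
#'   set (default 0.5; the full frequency vector is always reported).
#' @param seed Integer seed.
#' @return An object of class `stability_spec`.
#' @export
stability_spec <- function(n_subsamples = 300, inclusion_prob = 0.70,
                           vip_threshold_grid = c(0.8, 0.9, 1.0, 1.1, 1.2, 1.5),
                           cv_folds = 7, frequency_cutoff = 0.5, seed = 1L) {
  n_subsamples <- .check_count(n_subsamples, "n_subsamples")
  .check_prob(inclusion_prob, "inclusion_prob")
  if (!length(vip_threshold_grid) || any(vip_threshold_grid < 0)) {
    abort("`vip_threshold_grid` must be a nonempty vector of nonnegative cutoffs.",
          class = "voclearn_error_parameter")
  }
  .check_prob(frequency_cutoff, "frequency_cutoff", open_left = FALSE)
  structure(
    list(n_subsamples = n_subsamples, inclusion_prob = inclusion_prob,
         vip_threshold_grid = sort(vip_threshold_grid),
         cv_folds = .check_count(cv_folds, "cv_folds", min = 2L),
         frequency_cutoff = frequency_cutoff, seed = as.integer(seed)),
    class = "stability_spec"
  )
}

#' Monte-Carlo stability selection around VIP-based PLS-DA
#'
#' For each of `n_subsamples` subsamples, subjects are drawn independently
#' with probability `inclusion_prob`; a PLS-DA model is fitted on the
#' subsample; the VIP cutoff maximising Q2 under `cv_folds`-fold
#' cross-validation (restricted to features at or above the cutoff) is
#' chosen from the grid; the surviving features are recorded; and a model
#' refitted on them predicts the *excluded* subjects, contributing one
#' out-of-subsample AUC when both classes are present among the excluded
#' (otherwise that subsample contributes no AUC). Selection frequency is
#' the per-feature fraction of subsamples in which it survived. A subsample
#' whose included set misses a class is redrawn.
#'
#' @param data Processed table (`subject_id`, `group`, autoscaled features).
#' @param spec A [stability_spec()].
#' @param A Number of PLS components per subsample model (truncated at the
#'   subsample rank when necessary).
#' @param positive Positive class label (default: second group level).
#' @return An object of class `voc_stability`: `selection_frequency`
#'   tibble (`feature`, `frequency`, `selected`), `auc_distribution`,
#'   `auc_median`, `auc_p5` (5th percentile), `selected` feature set, and
#'   the `spec`.
#' @export
stability_select <- function(data, spec = stability_spec(), A = 2,
                             positive = NULL) {
  if (!inherits(spec, "stability_spec")) {
    abort("`spec` must be created by stability_spec().",
          class = "voclearn_error_parameter")
  }
  X <- .feature_matrix(data)
  .check_two_groups(data$group)
  positive <- .positive_class(data$group, positive)
  y <- .encode_y(data$group, positive)
  n <- nrow(X)
  p <- ncol(X)
  grid <- spec$vip_threshold_grid

  counts <- numeric(p)
  aucs <- numeric(0)
  n_redrawn <- 0L
  n_no_auc <- 0L

  .with_seed(spec$seed, {
    for (b in seq_len(spec$n_subsamples)) {
      repeat {
        inc <- runif(n) <= spec$inclusion_prob
        if (length(unique(y[inc])) == 2 && sum(inc) > spec$cv_folds) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 1000L * spec$n_subsamples) {
          abort("Could not draw subsamples containing both classes.",
                class = "voclearn_error_degenerate")
        }
      }
      Xb <- X[inc, , drop = FALSE]
      yb <- y[inc]
      Ab <- min(A, sum(inc) - 1L, p)
      base <- .pls_nipals(Xb, yb, Ab)
      vip <- .vip(base)

      best_q2 <- -Inf
      best_feats <- NULL
      for (thr in grid) {
        feats <- which(vip >= thr)
        if (!length(feats)) next
        q2 <- tryCatch(
          .cv(Xb[, feats, drop = FALSE], yb, min(Ab, length(feats)),
              k = spec$cv_folds)$Q2,
          error = function(e) -Inf
        )
        if (q2 > best_q2) {
          best_q2 <- q2
          best_feats <- feats
        }
      }
      if (is.null(best_feats)) best_feats <- seq_len(p)
      counts[best_feats] <- counts[best_feats] + 1

      exc <- !inc
      if (any(exc) && length(unique(y[exc])) == 2) {
        refit <- .pls_nipals(Xb[, best_feats, drop = FALSE], yb,
                             min(Ab, length(best_feats)))
        pred <- .pls_predict(refit, X[exc, best_feats, drop = FALSE])
        aucs <- c(aucs, .auc_unoriented(pred, y[exc] > 0))
      } else {
        n_no_auc <- n_no_auc + 1L
      }
    }
  })

  if (n_no_auc > 0) {
    inform(sprintf(
      "%d subsample(s) contributed no out-of-subsample AUC (excluded set missing a class or empty).",
      n_no_auc))
  }
  freq <- counts / spec$n_subsamples
  sel_tbl <- tibble::tibble(
    feature = colnames(X),
    frequency = freq,
    selected = freq >= spec$frequency_cutoff
  )
  structure(
    list(
      selection_frequency = sel_tbl,
      auc_distribution = aucs,
      auc_median = if (length(aucs)) median(aucs) else NA_real_,
      auc_p5 = if (length(aucs)) unname(quantile(aucs, 0.05)) else NA_real_,
      selected = sel_tbl$feature[sel_tbl$selected],
      n_redrawn = n_redrawn,
      n_no_auc = n_no_auc,
      positive = positive,
      spec = spec
    ),
    class = "voc_stability"
  )
}

#' @export
print.voc_stability <- function(x, ...) {
  cat(sprintf(
    "<voc_stability> %d subsamples (prior %.2f): %d features at frequency >= %.2f; prediction AUC median %.3f, 5th pct %.3f\n",
    x$spec$n_subsamples, x$spec$inclusion_prob, length(x$selected),
    x$spec$frequency_cutoff, x$auc_median, x$auc_p5
  ))
  invisible(x)
}

#' @method tidy voc_stability
#' @export
tidy.voc_stability <- function(x, ...) x$selection_frequency

#' @method glance voc_stability
#' @export
glance.voc_stability <- function(x, ...) {
  tibble::tibble(
    n_subsamples = x$spec$n_subsamples,
    inclusion_prob = x$spec$inclusion_prob,
    n_selected = length(x$selected),
    auc_median = x$auc_median,
    auc_p5 = x$auc_p5
  )
}

#' Merge multivariate and univariate selections into a marker set
#'
#' The comprehensive-analysis merge rule: a feature is a putative marker if
#' it was selected by stability selection *or* passes the univariate gate
#' (`t_p < p_max` and `q < q_max` and `auc > auc_min`). Directions are taken
#' from the univariate battery.
#'
#' @param stab A [stability_select()] result.
#' @param uni A [univariate_stats()] tibble over the same feature universe.
#' @param p_max,q_max,auc_min Univariate gate thresholds (defaults 0.05,
#'   0.1, 0.50).
#' @return An object of class `voc_markers`: a `members` tibble
#'   (`feature`, `direction`, `in_multivariate`, `in_univariate`) and the
#'   thresholds.
#' @export
merge_selections <- function(stab, uni, p_max = 0.05, q_max = 0.1,
                             auc_min = 0.50) {
  if (!inherits(stab, "voc_stability")) {
    abort("`stab` must be a voc_stability object.",
          class = "voclearn_error_parameter")
  }
  stab_feats <- stab$selection_frequency$feature
  if (!setequal(stab_feats, uni$feature)) {
    abort("Stability and univariate results cover different feature sets.",
          class = "voclearn_error_input")
  }
  pass_uni <- uni$feature[uni$t_p < p_max & uni$q < q_max & uni$auc > auc_min]
  members <- union(stab$selected, pass_uni)
  members_tbl <- uni |>
    dplyr::filter(.data$feature %in% members) |>
    dplyr::transmute(
      feature = .data$feature,
      direction = .data$direction,
      in_multivariate = .data$feature %in% stab$selected,
      in_univariate = .data$feature %in% pass_uni
    )
  structure(
    list(members = members_tbl,
         from_multivariate = intersect(members, stab$selected),
         from_univariate = pass_uni,
         thresholds = c(p_max = p_max, q_max = q_max, auc_min = auc_min)),
    class = "voc_markers"
  )
}

#' @export
print.voc_markers <- function(x, ...) {
  cat(sprintf(
    "<voc_markers> %d putative markers (%d multivariate, %d univariate)\n",
    nrow(x$members), length(x$from_multivariate), length(x$from_univariate)
  ))
  invisible(x)
}

#' @method tidy voc_markers
#' @export
tidy.voc_markers <- function(x, ...) x$members
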