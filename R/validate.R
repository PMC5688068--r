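# Concordance AUC of continuous scores for the positive class, ties 1/2.
# NOT oriented: values below 0.5 mean anti-prediction (needed for honest
# out-of-sample distributions).
.auc_unoriented <- function(scores, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment: shuffle within class, then deal the
# concatenated classes round-robin so fold sizes stay balanced overall and
# k = n degenerates to leave-one-out.
.make_folds <- function(y, k) {
  fold <- integer(length(y))
  idx <- unlist(lapply(unique(y), function(cl) sample(which(y == cl))))
  fold[idx] <- rep_len(seq_len(k), length(idx))
  fold
}

# Core CV loop on a matrix; returns pooled-PRESS Q2, held-out AUC and the
# concatenated held-out predictions. RNG state of the caller is used for the
# fold draw (callers seed it).
.cv <- function(X, y, A, k = 7) {
  n <- nrow(X)
  if (k > n) {
    abort("`k` cannot exceed the number of subjects.",
          class = "voclearn_error_parameter")
  }
  fold <- .make_folds(y, k)
  pred <- numeric(n)
  for (f in sort(unique(fold))) {
    test <- fold == f
    if (length(unique(y[!test])) < 2) {
      abort("A training fold lost a class; reduce `k`.",
            class = "voclearn_error_degenerate")
    }
    fit <- .pls_nipals(X[!test, , drop = FALSE], y[!test], A)
    pred[test] <- .pls_predict(fit, X[test, , drop = FALSE])
  }
  q2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(Q2 = q2, cv_auc = .auc_unoriented(pred, y > 0), predictions = pred,
       folds = fold)
}

#' Cross-validated Q2 and AUC of a PLS-DA model
#'
#' Stratified k-fold cross-validation of the NIPALS PLS-DA fit. `Q2` is
#' computed SIMCA-style from a single pooled PRESS over the concatenated
#' held-out predictions, `Q2 = 1 - PRESS/TSS`; `cv_auc` is the concordance
#' AUC of those held-out continuous predictions against the true labels
#' (unoriented, so a useless model sits near 0.5 and may fall below it).
#'
#' @param data Processed table (`subject_id`, `group`, features).
#' @param A Number of PLS components.
#' @param k Number of folds (default 7).
#' @param positive Positive class label (default: second group level).
#' @param seed Seed for the stratified fold draw.
#' @return A list with `Q2`, `cv_auc`, per-subject `predictions` tibble and
#'   the fold assignment.
#' @export
cross_validate <- function(data, A = 2, k = 7, positive = NULL, seed = 1L) {
  X <- .feature_matrix(data)
  .check_two_groups(data$group)
  positive <- .positive_class(data$group, positive)
  y <- .encode_y(data$group, positive)
  res <- .with_seed(seed, .cv(X, y, A, k))
  res$predictions <- tibble::tibble(
    subject_id = data$subject_id, group = data$group,
    fold = res$folds, prediction = res$predictions
  )
  res$folds <- NULL
  res
}

#' Choose the number of PLS components by cross-validated Q2
#'
#' Computes Q2 for `A = 1..max_A` and returns the smallest `A` attaining the
#' maximum.
#'
#' @inheritParams cross_validate
#' @param max_A Largest number of components tried (default 5, capped at the
#'   rank bound).
#' @return A list with the chosen `A` and the tibble of Q2 per candidate.
#' @export
choose_ncomp <- function(data, max_A = 5, k = 7, positive = NULL, seed = 1L) {
  X <- .feature_matrix(data)
  positive <- .positive_class(data$group, positive)
  y <- .encode_y(data$group, positive)
  max_A <- min(max_A, nrow(X) - ceiling(nrow(X) / k) - 1L, ncol(X))
  q2 <- vapply(seq_len(max_A), function(a) {
    .with_seed(seed, .cv(X, y, a, k))$Q2
  }, numeric(1))
  list(A = which.max(q2), q2 = tibble::tibble(A = seq_len(max_A), Q2 = q2))
}

#' Permutation test of PLS-DA model validity
#'
#' Recomputes the cross-validated statistic (`cv_auc` by default, or `Q2`)
#' on label-permuted responses, rerunning the full CV pipeline inside every
#' permutation, and reports the exceedance p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @inheritParams cross_validate
#' @param n_perm Number of permutations (>= 99).
#' @param stat `"cv_auc"` (default) or `"Q2"`.
#' @return An object of class `voc_permutation` with `observed_stat`,
#'   `null_stats`, `n_permutations`, `p_value` and `stat`.
#' @export
permutation_test <- function(data, A = 2, n_perm = 1000,
                             stat = c("cv_auc", "Q2"), k = 7,
                             positive = NULL, seed = 1L) {
  stat <- match.arg(stat)
  if (n_perm < 99) {
    abort("`n_perm` must be at least 99.", class = "voclearn_error_parameter")
  }
  X <- .feature_matrix(data)
  .check_two_groups(data$group)
  positive <- .positive_class(data$group, positive)
  y <- .encode_y(data$group, positive)
  if (length(unique(y)) < 2) {
    abort("Degenerate class response.", class = "voclearn_error_degenerate")
  }
  res <- .with_seed(seed, {
    observed <- .cv(X, y, A, k)[[stat]]
    null_stats <- vapply(seq_len(n_perm), function(i) {
      .cv(X, sample(y), A, k)[[stat]]
    }, numeric(1))
    list(observed = observed, null_stats = null_stats)
  })
  structure(
    list(
      observed_stat = res$observed,
      null_stats = res$null_stats,
      n_permutations = n_perm,
      p_value = (1 + sum(res$null_stats >= res$observed)) / (1 + n_perm),
      stat = stat
    ),
    class = "voc_permutation"
  )
}

#' @export
print.voc_permutation <- function(x, ...) {
  cat(sprintf("<voc_permutation> %s = %.3f, p = %.4g (%d permutations)\n",
              x$stat, x$observed_stat, x$p_value, x$n_permutations))
  invisible(x)
}

#' @method tidy voc_permutation
#' @export
tidy.voc_permutation <- function(x, ...) {
  tibble::tibble(null_stat = x$null_stats)
}

#' @method glance voc_permutation
#' @export
glance.voc_permutation <- function(x, ...) {
  tibble::tibble(
    stat = x$stat,
    observed = x$observed_stat,
    p_value = x$p_value,
    n_permutations = x$n_permutations
  )
}
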