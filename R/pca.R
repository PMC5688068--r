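#' Principal component analysis of a processed feature table
#'
#' SVD-based PCA used for exploratory inspection and outlier screening of the
#' autoscaled data. Columns are centred (they already are after
#' [log_autoscale()]); no further scaling is applied.
#'
#' @param data A processed table (`subject_id`, `group`, numeric features)
#'   or a numeric matrix.
#' @param n_components Number of components to retain; capped at the matrix
#'   rank with a warning.
#' @return An object of class `voc_pca` with orthonormal `loadings`
#'   \[feature x component\], `scores` \[subject x component\],
#'   `eigenvalues` (score variances, non-increasing), the retained
#'   `n_components`, the centred data matrix `X` and the `residuals` of the
#'   truncated reconstruction.
#' @export
fit_pca <- function(data, n_components = 2) {
  X <- if (is.matrix(data)) data else .feature_matrix(data)
  if (!all(is.finite(X))) {
    abort("PCA input must be finite (impute/drop missing values first).",
          class = "voclearn_error_input")
  }
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  n_components <- .check_count(n_components, "n_components")
  if (n_components > rank) {
    warn(sprintf("Requested %d components but rank is %d; truncating.",
                 n_components, rank))
    n_components <- rank
  }
  A <- n_components
  scores <- sv$u[, seq_len(A), drop = FALSE] %*% diag(sv$d[seq_len(A)], A)
  loadings <- sv$v[, seq_len(A), drop = FALSE]
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(A))
  structure(
    list(
      loadings = loadings,
      scores = scores,
      eigenvalues = sv$d^2 / (n - 1),
      n_components = A,
      X = Xc,
      residuals = Xc - scores %*% t(loadings),
      group = if (!is.matrix(data) && "group" %in% names(data)) data$group,
      subject_ids = rownames(X)
    ),
    class = "voc_pca"
  )
}

#' @export
print.voc_pca <- function(x, ...) {
  ev <- x$eigenvalues[seq_len(x$n_components)]
  cat(sprintf("<voc_pca> %d components; variance explained %s\n",
              x$n_components,
              paste(sprintf("%.1f%%", 100 * ev / sum(x$eigenvalues)),
                    collapse = ", ")))
  invisible(x)
}

#' @method tidy voc_pca
#' @export
tidy.voc_pca <- function(x, ...) {
  tibble::tibble(
    component = rep(seq_len(x$n_components), each = nrow(x$loadings)),
    feature = rep(rownames(x$loadings), x$n_components),
    loading = as.vector(x$loadings)
  )
}

#' @method glance voc_pca
#' @export
glance.voc_pca <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    prop_variance = sum(x$eigenvalues[seq_len(x$n_components)]) /
      sum(x$eigenvalues)
  )
}

#' PCA outlier screening by Hotelling's T2 and DModX
#'
#' Flags subjects that are extreme within the PCA model plane (Hotelling's
#' T2 on the scores) or far from it (DModX, the normalised residual SD).
#' Limits at confidence `level`:
#' * T2_i = sum_a t_ia^2 / lambda_a, with limit
#'   `A (n^2 - 1) / (n (n - A)) * qf(level, A, n - A)`;
#' * DModX_i = s_i / s0 where `s_i = sqrt(sum_j e_ij^2 / (p - A))` and
#'   `s0 = sqrt(sum_ij e_ij^2 / ((n - A - 1) (p - A)))`, with limit
#'   `sqrt(qf(level, p - A, (n - A - 1) (p - A)))`.
#'
#' The exact DModX degrees-of-freedom convention differs between software
#' lineages; this one behaves close to nominal on multivariate-normal data.
#'
#' @param model A fitted [fit_pca()] model.
#' @param level Confidence level of the control limits (default 0.95).
#' @return An object of class `voc_outliers`: per-subject tibble
#'   (`subject_id`, `t2`, `dmodx`, `flag_t2`, `flag_dmodx`, `flagged`),
#'   the two limits and the level. `flagged` is exceedance of either limit.
#' @export
outlier_screen <- function(model, level = 0.95) {
  if (!inherits(model, "voc_pca")) {
    abort("`model` must be a voc_pca object.", class = "voclearn_error_parameter")
  }
  n <- nrow(model$scores)
  p <- ncol(model$X)
  A <- model$n_components
  if (n < 3) abort("At least 3 subjects required.", class = "voclearn_error_input")
  .check_prob(level, "level", open_left = TRUE, open_right = TRUE)

  lambda <- model$eigenvalues[seq_len(A)]
  t2 <- rowSums(sweep(model$scores^2, 2, lambda, "/"))
  t2_limit <- A * (n^2 - 1) / (n * (n - A)) * qf(level, A, n - A)

  E <- model$residuals
  s_i <- sqrt(rowSums(E^2) / (p - A))
  s0 <- sqrt(sum(E^2) / ((n - A - 1) * (p - A)))
  dmodx <- s_i / s0
  dmodx_limit <- sqrt(qf(level, p - A, (n - A - 1) * (p - A)))

  report <- tibble::tibble(
    subject_id = model$subject_ids %||% as.character(seq_len(n)),
    t2 = t2,
    dmodx = dmodx,
    flag_t2 = t2 > t2_limit,
    flag_dmodx = dmodx > dmodx_limit,
    flagged = t2 > t2_limit | dmodx > dmodx_limit
  )
  structure(
    list(report = report, t2_limit = t2_limit, dmodx_limit = dmodx_limit,
         level = level, n_components = A),
    class = "voc_outliers"
  )
}

#' @export
print.voc_outliers <- function(x, ...) {
  cat(sprintf(
    "<voc_outliers> level %.2f: %d/%d flagged (T2 limit %.2f, DModX limit %.2f)\n",
    x$level, sum(x$report$flagged), nrow(x$report), x$t2_limit, x$dmodx_limit
  ))
  invisible(x)
}

#' @method tidy voc_outliers
#' @export
tidy.voc_outliers <- function(x, ...) x$report

#' @method glance voc_outliers
#' @export
glance.voc_outliers <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    t2_limit = x$t2_limit,
    dmodx_limit = x$dmodx_limit,
    n_flagged = sum(x$report$flagged)
  )
}
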