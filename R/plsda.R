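# NIPALS PLS1 engine. X rows = subjects, columns = features; y numeric
# (class-coded -1/+1). Kept free of data-frame overhead: it runs hundreds of
# thousands of times inside cross-validation, permutation and stability loops.
.pls_nipals <- function(X, y, A, tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- X - rep(x_center, each = n)
  yc <- y - y_center

  A_max <- min(A, n - 1L, p)
  W <- matrix(0, p, A_max)
  P <- matrix(0, p, A_max)
  Tm <- matrix(0, n, A_max)
  cvec <- numeric(A_max)
  dvec <- numeric(A_max)
  a_used <- 0L
  for (a in seq_len(A_max)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < tol) break
    w <- w / wn
    t <- Xc %*% w
    d <- sum(t^2)
    if (d < tol) break
    pa <- crossprod(Xc, t) / d
    ca <- sum(yc * t) / d
    W[, a] <- w
    P[, a] <- pa
    Tm[, a] <- t
    cvec[a] <- ca
    dvec[a] <- d
    Xc <- Xc - t %*% t(pa)
    a_used <- a
  }
  if (a_used == 0L) {
    abort("PLS could not extract any component (X'y is null).",
          class = "voclearn_error_degenerate")
  }
  keep <- seq_len(a_used)
  W <- W[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]
  cvec <- cvec[keep]
  dvec <- dvec[keep]
  B <- W %*% solve(crossprod(P, W), cvec)
  fitted <- Tm %*% cvec + y_center
  list(
    W = W, P = P, T = Tm, c = cvec, d = dvec, A = a_used, B = B,
    x_center = x_center, y_center = y_center,
    fitted = as.vector(fitted),
    R2Y = 1 - sum((yc - Tm %*% cvec)^2) / sum(yc^2)
  )
}

.pls_predict <- function(fit, Xnew) {
  as.vector((Xnew - rep(fit$x_center, each = nrow(Xnew))) %*% fit$B +
              fit$y_center)
}

#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis by NIPALS PLS1 against the
#' centred class response (control = -1, positive class = +1). Components
#' are extracted with X-deflation; the regression vector is
#' `B = W (P'W)^{-1} c`. VIP scores are computed at fit time.
#'
#' @param data A processed table (`subject_id`, `group`, autoscaled numeric
#'   features), e.g. from [log_autoscale()].
#' @param A Number of latent components (truncated at the rank with a
#'   warning).
#' @param positive Positive class label; default: the second group level.
#' @return An object of class `voc_plsda`: weights `W`, x-loadings `P`,
#'   scores `T`, y-loadings `c`, regression vector `B`, `R2Y`, `vip`,
#'   `post_transformed` flag, plus centring info and training metadata.
#' @seealso [vip_scores()], [post_transform()], [cross_validate()]
#' @export
fit_plsda <- function(data, A = 2, positive = NULL) {
  X <- .feature_matrix(data)
  .check_two_groups(data$group)
  positive <- .positive_class(data$group, positive)
  y <- .encode_y(data$group, positive)
  A <- .check_count(A, "A")
  A_max <- min(nrow(X) - 1L, ncol(X))
  if (A > A_max) {
    warn(sprintf("A = %d exceeds the rank bound %d; truncating.", A, A_max))
    A <- A_max
  }
  fit <- .pls_nipals(X, y, A)
  if (fit$A < A) {
    warn(sprintf("Only %d component(s) could be extracted.", fit$A))
  }
  fit$feature_ids <- colnames(X)
  fit$subject_ids <- data$subject_id
  fit$group <- data$group
  fit$positive <- positive
  fit$y <- y
  fit$vip <- .vip(fit)
  fit$post_transformed <- FALSE
  class(fit) <- "voc_plsda"
  fit
}

#' @export
print.voc_plsda <- function(x, ...) {
  cat(sprintf("<voc_plsda> %d component(s)%s, R2Y = %.3f, positive class '%s'\n",
              x$A, if (x$post_transformed) " (post-transformed)" else "",
              x$R2Y, x$positive))
  invisible(x)
}

#' Predict continuous class scores from a PLS-DA model
#'
#' @param object A [fit_plsda()] model.
#' @param newdata Processed table or numeric matrix with the training
#'   features.
#' @param type `"score"` for the continuous prediction (default) or
#'   `"class"` for thresholding at the training class midpoint (0).
#' @param ... Unused.
#' @return Numeric scores, or a factor of class labels.
#' @export
predict.voc_plsda <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else .feature_matrix(newdata)
  X <- X[, object$feature_ids, drop = FALSE]
  s <- .pls_predict(object, X)
  if (type == "score") return(s)
  lv <- c(setdiff(levels(factor(object$group)), object$positive), object$positive)
  factor(ifelse(s > 0, object$positive, lv[1]), levels = lv)
}

# VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a ),
# SSY_a = c_a^2 t_a't_a (y-variance captured by component a). NIPALS weights
# are unit-norm already. mean(VIP^2) = 1 by construction.
.vip <- function(fit) {
  ssy <- fit$c^2 * fit$d
  if (sum(ssy) <= 0) {
    abort("Model explains no class variance; VIP undefined.",
          class = "voclearn_error_degenerate")
  }
  p <- nrow(fit$W)
  as.vector(sqrt(p * (fit$W^2 %*% ssy) / sum(ssy)))
}

#' VIP (Variable Influence on Projection) scores
#'
#' The standard PLS VIP: each feature's weighted contribution to the
#' y-variance explained across components,
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja/||w_a||)^2 / sum_a SSY_a)`, where
#' `SSY_a` is the class-response variance captured by component `a`. Squared
#' VIPs average to 1, so 1 is the natural "average influence" reference.
#'
#' @param model A [fit_plsda()] model.
#' @return Named numeric vector of VIP scores (one per feature).
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "voc_plsda")) {
    abort("`model` must be a voc_plsda object.",
          class = "voclearn_error_parameter")
  }
  setNames(.vip(model), model$feature_ids)
}

#' Post-transform a PLS-DA model to one predictive component
#'
#' Rotates the fitted score space by an orthogonal matrix so that a single
#' component (`T_pred`) carries all covariance with the class response and
#' the remaining components (`T_orth`) are exactly y-orthogonal. The first
#' rotation direction is `T'y / ||T'y||`; because NIPALS scores are mutually
#' orthogonal, every completed direction then has zero covariance with `y`.
#' Predictions, `B` and fitted values are untouched: the rotation only
#' re-expresses the latent space for interpretation (predictive vs
#' within-class orthogonal variation).
#'
#' @param model A [fit_plsda()] model with `A >= 2` (an `A = 1` model is
#'   returned unchanged with a message: it is already single-predictive).
#' @return The model with `T_pred`, `T_orth`, rotated `W_rot`/`P_rot`, the
#'   rotation matrix `G`, and `post_transformed = TRUE`.
#' @export
post_transform <- function(model) {
  if (!inherits(model, "voc_plsda")) {
    abort("`model` must be a voc_plsda object.",
          class = "voclearn_error_parameter")
  }
  yc <- model$y - model$y_center
  if (model$A == 1) {
    inform("A = 1: model is already single-predictive; returned unchanged.")
    model$T_pred <- model$T[, 1]
    model$T_orth <- matrix(0, nrow(model$T), 0)
    model$G <- matrix(1, 1, 1)
    model$post_transformed <- TRUE
    return(model)
  }
  M <- as.vector(crossprod(model$T, yc))
  g1 <- M / sqrt(sum(M^2))
  G <- qr.Q(qr(cbind(g1, diag(length(g1)))))[, seq_along(g1), drop = FALSE]
  if (sum(G[, 1] * g1) < 0) G[, 1] <- -G[, 1]
  T_rot <- model$T %*% G
  model$G <- G
  model$T_pred <- T_rot[, 1]
  model$T_orth <- T_rot[, -1, drop = FALSE]
  model$W_rot <- model$W %*% G
  model$P_rot <- model$P %*% G
  model$post_transformed <- TRUE
  model
}

#' @method tidy voc_plsda
#' @export
tidy.voc_plsda <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_ids,
    vip = x$vip,
    coefficient = as.vector(x$B)
  )
}

#' @method glance voc_plsda
#' @export
glance.voc_plsda <- function(x, ...) {
  tibble::tibble(
    A = x$A,
    R2Y = x$R2Y,
    positive = x$positive,
    post_transformed = x$post_transformed
  )
}
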