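#' Single-feature ROC AUC with direction
#'
#' Concordance-probability (Mann-Whitney) AUC with ties counted one half,
#' oriented so the reported AUC is at least 0.5; `direction` records which
#' class has the higher values. Missing values are dropped.
#'
#' @param values Numeric feature values.
#' @param labels Two-level group labels (factor or character).
#' @param positive Positive class label (default: second level).
#' @return A list with `auc` (>= 0.5) and `direction`, a string like
#'   `"OW/Ob > NW"`.
#' @export
#' @examples
#' feature_auc(c(1, 2, 3, 10, 11, 12), rep(c("NW", "OW/Ob"), each = 3))
feature_auc <- function(values, labels, positive = NULL) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  lv <- .check_two_groups(labels)
  positive <- .positive_class(factor(labels, levels = sort(lv)), positive)
  is_pos <- as.character(labels) == positive
  if (!any(is_pos) || all(is_pos)) {
    abort("Both classes must be present.", class = "voclearn_error_input")
  }
  a <- .auc_unoriented(values, is_pos)
  negative <- setdiff(unique(as.character(labels)), positive)
  if (a >= 0.5) {
    list(auc = a, direction = paste(positive, ">", negative))
  } else {
    list(auc = 1 - a, direction = paste(negative, ">", positive))
  }
}

#' Confidence interval for a single-feature AUC
#'
#' DeLong variance-based interval (default) or seeded percentile bootstrap,
#' clipped to \[0, 1\]. If the DeLong variance is degenerate (e.g. complete
#' separation) the interval collapses against the clip boundary.
#'
#' @inheritParams feature_auc
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap draw.
#' @return Named numeric vector `c(low, high)`.
#' @export
auc_ci <- function(values, labels, level = 0.95,
                   method = c("delong", "bootstrap"), n_boot = 2000,
                   seed = 1L) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels[keep])
  if (min(table(labels)) < 3) {
    abort("At least 3 observations per class are required.",
          class = "voclearn_error_input")
  }
  roc <- suppressMessages(pROC::roc(labels, values, quiet = TRUE,
                                    direction = "auto"))
  ci <- .with_seed(seed, {
    if (method == "delong") {
      suppressWarnings(pROC::ci.auc(roc, conf.level = level, method = "delong"))
    } else {
      pROC::ci.auc(roc, conf.level = level, method = "bootstrap",
                   boot.n = n_boot)
    }
  })
  c(low = max(0, ci[1]), high = min(1, ci[3]))
}

#' Sensitivity and specificity at the Youden-optimal cutpoint
#'
#' Scans the observed values as candidate cutpoints (classification rule:
#' predicted positive when the value is on the positive-class side of the
#' cut) and returns the operating point maximising Youden's
#' `J = sens + spec - 1`. Ties are broken toward higher specificity.
#'
#' @inheritParams feature_auc
#' @return A list with `sens`, `spec` and `cutpoint`.
#' @export
sens_spec_at_youden <- function(values, labels, positive = NULL) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- labels[keep]
  lv <- .check_two_groups(labels)
  positive <- .positive_class(factor(labels, levels = sort(lv)), positive)
  is_pos <- as.character(labels) == positive
  # orient so positive class tends high
  if (.auc_unoriented(values, is_pos) < 0.5) values <- -values
  cuts <- c(sort(unique(values)), Inf)
  best <- NULL
  for (cut in cuts) {
    pred_pos <- values >= cut
    sens <- sum(pred_pos & is_pos) / sum(is_pos)
    spec <- sum(!pred_pos & !is_pos) / sum(!is_pos)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(sens = sens, spec = spec, cutpoint = cut, j = j)
    }
  }
  best$j <- NULL
  best
}

#' False-discovery-rate q-values
#'
#' Storey q-values with the smoother estimate of the null proportion pi0
#' (default), or Benjamini-Hochberg adjusted p-values. Output is monotone
#' non-decreasing in p.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param method `"storey"` or `"bh"`.
#' @return Vector of q-values, same order as `p`.
#' @export
#' @examples
#' q_values(c(0.01, 0.02, 0.03, 0.04), method = "bh")
q_values <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].", class = "voclearn_error_parameter")
  }
  if (method == "bh") return(p.adjust(p, method = "BH"))
  m <- length(p)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- tryCatch({
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    predict(fit, x = max(lambda))$y
  }, error = function(e) min(pi0_l))
  pi0 <- min(max(pi0, 1 / m), 1) # clamp; tiny m or all-small p can misbehave
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o])
  pmin(q, 1)
}

#' Post-hoc power of the two-sample Welch t-test
#'
#' Power for detecting the observed mean difference at significance level
#' `alpha`, using the noncentral-t formulation with Welch-Satterthwaite
#' degrees of freedom and noncentrality
#' `(mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)`.
#'
#' @inheritParams welch_t_from_summary
#' @param alpha Significance level (two-sided), default 0.05.
#' @return Power in \[0, 1\] (vectorised).
#' @export
power_t <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  if (any(n1 < 2) || any(n2 < 2)) {
    abort("Group sizes must be at least 2.", class = "voclearn_error_parameter")
  }
  if (any(sd1 <= 0 & sd2 <= 0)) {
    abort("Pooled SD is zero; power undefined.",
          class = "voclearn_error_parameter")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  ncp <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tcrit <- qt(1 - alpha / 2, df)
  # pt() warns about its last-digit precision at large ncp; irrelevant here
  suppressWarnings(pt(-tcrit, df, ncp = ncp) + 1 - pt(tcrit, df, ncp = ncp))
}

#' Post-hoc power of the AUC test against 0.5
#'
#' Power of the two-sided test of `H0: AUC = 0.5` at the observed AUC,
#' using the Hanley-McNeil variance approximation
#' `V(A) = (A(1-A) + (n1-1)(Q1 - A^2) + (n2-1)(Q2 - A^2)) / (n1 n2)` with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`. Monotone increasing in the AUC and in
#' the group sizes.
#'
#' @param auc Observed AUC in (0.5, 1\].
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Significance level, default 0.05.
#' @return Power in \[0, 1\]. An AUC at or below 0.5 returns `alpha` with a
#'   warning.
#' @export
power_roc <- function(auc, n1, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) {
    abort("Group sizes must be at least 2.", class = "voclearn_error_parameter")
  }
  if (auc > 1) {
    abort("`auc` cannot exceed 1.", class = "voclearn_error_parameter")
  }
  if (auc <= 0.5) {
    warn("AUC <= 0.5: power equals the significance level.")
    return(alpha)
  }
  hm_var <- function(A) {
    q1 <- A / (2 - A)
    q2 <- 2 * A^2 / (1 + A)
    (A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n2 - 1) * (q2 - A^2)) / (n1 * n2)
  }
  v0 <- hm_var(0.5)
  va <- hm_var(auc)
  z <- qnorm(1 - alpha / 2)
  delta <- auc - 0.5
  pnorm((delta - z * sqrt(v0)) / sqrt(va)) +
    pnorm((-delta - z * sqrt(v0)) / sqrt(va))
}

#' Univariate t-test / FDR / ROC battery
#'
#' Per-feature two-group statistics on log-scale values: Welch t-test
#' p-value, FDR q-value across features, oriented AUC with confidence
#' interval, sensitivity/specificity at the Youden cutpoint, post-hoc powers
#' for the observed mean difference and the observed AUC, and the direction
#' of the difference. The t statistic is invariant to the per-feature affine
#' autoscaling and the AUC to any monotone transform, so running the battery
#' on log or autoscaled data gives the same p, q and AUC.
#'
#' @param data Per-subject table (`subject_id`, `group`, features) on the
#'   log scale, e.g. `attr(log_autoscale(x), "log_data")`.
#' @param positive Positive class label (default: second group level).
#' @param q_method FDR method, `"storey"` (default) or `"bh"`.
#' @param ci_method AUC interval method, `"delong"` (default) or
#'   `"bootstrap"`.
#' @param alpha Significance level for the power calculations.
#' @return A tibble with one row per feature: `feature`, `t`, `t_p`, `q`,
#'   `auc`, `auc_ci_low`, `auc_ci_high`, `sens`, `spec`, `power_roc`,
#'   `power_t`, `direction`.
#' @export
univariate_stats <- function(data, positive = NULL, q_method = "storey",
                             ci_method = "delong", alpha = 0.05) {
  feats <- .feature_cols(data)
  .check_two_groups(data$group)
  positive <- .positive_class(data$group, positive)
  grp <- as.character(data$group)
  n1 <- sum(grp != positive)
  n2 <- sum(grp == positive)

  rows <- purrr::map(feats, function(f) {
    v <- data[[f]]
    tt <- t.test(v[grp == positive], v[grp != positive])
    ra <- feature_auc(v, grp, positive = positive)
    ci <- auc_ci(v, grp, method = ci_method)
    ys <- sens_spec_at_youden(v, grp, positive = positive)
    g1 <- v[grp != positive]
    g2 <- v[grp == positive]
    tibble::tibble(
      feature = f,
      t = unname(tt$statistic),
      t_p = tt$p.value,
      auc = ra$auc,
      auc_ci_low = unname(ci["low"]),
      auc_ci_high = unname(ci["high"]),
      sens = ys$sens,
      spec = ys$spec,
      power_roc = if (ra$auc > 0.5) power_roc(ra$auc, n1, n2, alpha) else alpha,
      power_t = power_t(mean(g1, na.rm = TRUE), sd(g1, na.rm = TRUE),
                        sum(!is.na(g1)), mean(g2, na.rm = TRUE),
                        sd(g2, na.rm = TRUE), sum(!is.na(g2)), alpha),
      direction = ra$direction
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- q_values(out$t_p, method = q_method)
  dplyr::relocate(out, "q", .after = "t_p")
}
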