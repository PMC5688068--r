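#' Plot PLS-DA scores
#'
#' Score scatter of the first two components; for a post-transformed model,
#' the predictive component against the first orthogonal one, so the class
#' separation lies along the x axis.
#'
#' @param object A [fit_plsda()] model.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot voc_plsda
#' @export
autoplot.voc_plsda <- function(object, ...) {
  if (object$post_transformed && ncol(object$T_orth) >= 1) {
    df <- tibble::tibble(x = object$T_pred, y = object$T_orth[, 1],
                         group = object$group)
    labs <- c("predictive score", "orthogonal score 1")
  } else {
    df <- tibble::tibble(x = object$T[, 1],
                         y = if (object$A >= 2) object$T[, 2] else 0,
                         group = object$group)
    labs <- c("t1", if (object$A >= 2) "t2" else "")
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = labs[1], y = labs[2], colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot PCA scores with outlier flags
#'
#' @param object A [fit_pca()] model.
#' @param outliers Optional [outlier_screen()] result; flagged subjects are
#'   highlighted.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot voc_pca
#' @export
autoplot.voc_pca <- function(object, outliers = NULL, ...) {
  df <- tibble::tibble(
    PC1 = object$scores[, 1],
    PC2 = if (object$n_components >= 2) object$scores[, 2] else 0,
    group = object$group %||% factor("all"),
    flagged = if (is.null(outliers)) FALSE else outliers$report$flagged
  )
  pct <- 100 * object$eigenvalues / sum(object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$group,
                                   shape = .data$flagged)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = if (object$n_components >= 2) {
                    sprintf("PC2 (%.1f%%)", pct[2])
                  } else "") +
    ggplot2::theme_minimal()
}

#' Plot stability-selection frequencies
#'
#' Selection frequency per feature with the frequency cutoff, most stable
#' features first.
#'
#' @param object A [stability_select()] result.
#' @param top Show only the `top` most frequently selected features
#'   (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot voc_stability
#' @export
autoplot.voc_stability <- function(object, top = 30, ...) {
  df <- object$selection_frequency |>
    dplyr::arrange(dplyr::desc(.data$frequency)) |>
    head(top) |>
    dplyr::mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$feature,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$spec$frequency_cutoff,
                        linetype = 2) +
    ggplot2::labs(x = "selection frequency", y = NULL, fill = "selected") +
    ggplot2::theme_minimal()
}

#' Plot a permutation-test null distribution
#'
#' Histogram of the permuted statistics with the observed value marked.
#'
#' @param object A [permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot voc_permutation
#' @export
autoplot.voc_permutation <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$null_stats),
                  ggplot2::aes(.data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_stat, colour = "red") +
    ggplot2::labs(x = object$stat,
                  title = sprintf("Permutation test: p = %.4g",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}
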