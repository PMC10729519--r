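#' Score plot for a PCA model
#'
#' Scatter of two score components, optionally coloured by class with a
#' per-class 95% Hotelling confidence ellipse.
#'
#' @param object A `pca_model`.
#' @param components Length-2 integer vector of components to plot.
#' @param groups Optional class label per sample (for colour and per-class
#'   ellipses).
#' @param ellipses Draw per-class Hotelling ellipses (needs `groups` and
#'   >= 4 samples per class).
#' @param alpha Ellipse significance level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_model
#' @export
autoplot.pca_model <- function(object, components = c(1, 2), groups = NULL,
                               ellipses = !is.null(groups), alpha = 0.05,
                               ...) {
  sc <- object$scores[, components, drop = FALSE]
  df <- tibble::tibble(x = sc[, 1], y = sc[, 2])
  pct <- 100 * object$eigenvalues / object$total_variance
  labs_xy <- sprintf("PC%d (%.1f%%)", components, pct[components])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(groups)) {
    df$group <- as.character(groups)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$group))
    if (ellipses) {
      for (cls in unique(df$group)) {
        pts <- as.matrix(df[df$group == cls, c("x", "y")])
        if (nrow(pts) >= 4) {
          out <- ellipse_outline(hotelling_ellipse(pts, alpha))
          out$group <- cls
          p <- p + ggplot2::geom_path(
            data = out, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group),
            inherit.aes = FALSE, linetype = 2
          )
        }
      }
    }
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = labs_xy[1], y = labs_xy[2]) +
    ggplot2::theme_minimal()
}

#' Super-score plot for a SUM-PCA model
#'
#' @inheritParams autoplot.pca_model
#' @param object A `sum_pca_model`.
#' @return A ggplot object.
#' @method autoplot sum_pca_model
#' @export
autoplot.sum_pca_model <- function(object, components = c(1, 2),
                                   groups = NULL,
                                   ellipses = !is.null(groups),
                                   alpha = 0.05, ...) {
  autoplot.pca_model(object$pca, components = components, groups = groups,
                     ellipses = ellipses, alpha = alpha, ...)
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (%s vs rest), AUROC = %.2f",
                      object$positive, object$auroc)
    ) +
    ggplot2::theme_minimal()
}

#' Top-VIP bar plot
#'
#' @param object A `vip_result` from [vip_scores()].
#' @param top Number of features shown (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vip_result
#' @export
autoplot.vip_result <- function(object, top = 20, ...) {
  df <- object[object$rank <= top, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vip,
                                   y = stats::reorder(.data$feature,
                                                      .data$vip))) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "VIP score", y = NULL,
                  title = sprintf("Top %d VIP features", top)) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param object A `class_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot class_metrics
#' @export
autoplot.class_metrics <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Accuracy %.2f%%", object$accuracy),
                  fill = "count") +
    ggplot2::theme_minimal()
}
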