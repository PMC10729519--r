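#' Tidy a PCA model
#'
#' @param x A `pca_model`.
#' @param matrix `"scores"` (one row per sample and component) or
#'   `"loadings"` (one row per feature and component).
#' @param ... Unused.
#' @return A tibble in long format.
#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  m <- x[[matrix]]
  id_col <- if (matrix == "scores") "sample_id" else "feature"
  tibble::as_tibble(m, rownames = id_col) |>
    tidyr::pivot_longer(-dplyr::all_of(id_col), names_to = "component",
                        values_to = "value")
}

#' @method glance pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    total_variance = x$total_variance,
    prop_variance_explained = sum(x$eigenvalues) / x$total_variance
  )
}

#' Tidy a SUM-PCA model
#'
#' @param x A `sum_pca_model`.
#' @param matrix `"scores"` (super scores) or `"loadings"` (super loadings,
#'   annotated with the source block).
#' @param ... Unused.
#' @return A tibble in long format.
#' @method tidy sum_pca_model
#' @export
tidy.sum_pca_model <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    tibble::as_tibble(x$super_scores, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "component",
                          values_to = "value")
  } else {
    tibble::as_tibble(x$super_loadings, rownames = "feature") |>
      dplyr::mutate(block = x$block_index) |>
      tidyr::pivot_longer(-c("feature", "block"), names_to = "component",
                          values_to = "value")
  }
}

#' @method glance sum_pca_model
#' @export
glance.sum_pca_model <- function(x, ...) {
  tibble::tibble(
    n_blocks = length(x$block_weights),
    n_components = x$n_components,
    total_variance = x$total_variance,
    prop_variance_explained = sum(x$eigenvalues) / x$total_variance
  )
}

#' Tidy a PLS-DA model
#'
#' @param x A `plsda_model`.
#' @param ... Unused.
#' @return Tibble of regression coefficients: `feature`, `class`,
#'   `estimate`.
#' @method tidy plsda_model
#' @export
tidy.plsda_model <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "class",
                        values_to = "estimate")
}

#' @method glance plsda_model
#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(
    n_lv = x$n_lv,
    n_classes = length(x$classes),
    n_features = length(x$features),
    prop_y_variance_explained = sum(x$ss_y) / x$ss_y_total
  )
}

#' Tidy a SIMCA model
#'
#' @param x A `simca_model`.
#' @param ... Unused.
#' @return Tibble with one row per class submodel: sample size, PCs and
#'   critical limits.
#' @method tidy simca_model
#' @export
tidy.simca_model <- function(x, ...) {
  purrr::imap_dfr(x$submodels, function(sm, cls) {
    tibble::tibble(class = cls, n = sm$n, n_pcs = sm$n_pcs,
                   t2_crit = sm$t2_crit, q_crit = sm$q_crit)
  })
}

#' @method glance simca_model
#' @export
glance.simca_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), alpha = x$alpha,
                 n_features = length(x$features))
}

#' Tidy a classification metrics object
#'
#' @param x A `class_metrics` object.
#' @param ... Unused.
#' @return The per-class tibble of counts, sensitivity and specificity.
#' @method tidy class_metrics
#' @export
tidy.class_metrics <- function(x, ...) x$by_class

#' @method glance class_metrics
#' @export
glance.class_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n)
}

#' Tidy a ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return The curve tibble (`threshold`, `fpr`, `tpr`).
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auroc = x$auroc, positive = x$positive,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}
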