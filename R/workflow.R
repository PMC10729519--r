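#' Run the full classification workflow on a two-block cohort
#'
#' End-to-end pipeline on a metabolomics + lipidomics cohort: block-wise
#' preprocessing (total-ion-sum / internal-standard normalization), the
#' shared per-class Kennard-Stone split on SUM-PCA super scores, per-block
#' PLS-DA with leave-one-out component selection (and SIMCA when
#' requested), VIP scoring, the VIP-reduced refits, and the AFP
#' threshold-rule benchmark on the same split.
#'
#' @param cohort Named list with [feature_table]s `metabolomics` and
#'   `lipidomics` (e.g. from [generate_cohort()]).
#' @param fused_components Super-score dimensions for the Kennard-Stone
#'   distances.
#' @param fraction Per-class training fraction.
#' @param max_components Bound for leave-one-out component selection.
#' @param scaling `"fit_on_train"` learns autoscaling parameters on the
#'   training partition and applies them to the test partition (no
#'   leakage); `"global"` autoscales the full study matrix before
#'   splitting, reproducing the original workflow exactly.
#' @param with_simca Also fit per-block SIMCA models (slower).
#' @param afp_threshold AFP positivity cut-off (ng/mL).
#' @return List of class `lipometab_workflow`: preprocessed `blocks`,
#'   `split`, per-block `models` (PLS-DA fit, VIPs, metrics, reduced
#'   refits, optional SIMCA), `afp` benchmark, and the `comparison` table
#'   of HCC-classification accuracies.
#' @export
run_workflow <- function(cohort, fused_components = 3L, fraction = 0.7,
                         max_components = 10L,
                         scaling = c("fit_on_train", "global"),
                         with_simca = FALSE, afp_threshold = 20) {
  scaling <- match.arg(scaling)
  stopifnot(all(c("metabolomics", "lipidomics") %in% names(cohort)))

  blocks <- list(
    metabolomics = preprocess(cohort$metabolomics, "total_ion_sum"),
    lipidomics = preprocess(cohort$lipidomics, "internal_standard")
  )
  split <- split_per_class(blocks, fused_components = fused_components,
                           fraction = fraction)

  models <- purrr::imap(blocks, function(ft, name) {
    ft <- ft_study_only(ft)
    m <- ft_matrix(ft)
    sp <- split[match(rownames(m), split$sample_id), ]
    train <- sp$split == "train"
    y_train <- sp$group[train]

    n_lv <- select_components_loo(m[train, , drop = FALSE], y_train,
                                  "plsda", max_components = max_components)
    cv_mis <- attr(n_lv, "misclassified")

    if (scaling == "global") {
      ms <- autoscale(m)
      x_train <- ms[train, , drop = FALSE]
      attr(x_train, "center") <- attr(ms, "center")
      attr(x_train, "scale") <- attr(ms, "scale")
    } else {
      x_train <- autoscale(m[train, , drop = FALSE], quiet = TRUE)
    }
    model <- fit_plsda(x_train, y_train, n_lv = n_lv)
    pred_train <- predict(model, m[train, , drop = FALSE])
    pred_test <- predict(model, m[!train, , drop = FALSE])
    metrics_train <- class_metrics(y_train, pred_train$.pred_class)
    metrics_test <- class_metrics(sp$group[!train], pred_test$.pred_class)
    vips <- vip_scores(model)

    hcc_acc <- function(truth, pred) {
      round(100 * mean(pred[truth == "HCC"] == "HCC"), 2)
    }
    res <- list(
      plsda = model, n_lv = as.integer(n_lv), vips = vips,
      metrics_train = metrics_train, metrics_test = metrics_test,
      roc_test = roc_curve(pred_test[["HCC"]], sp$group[!train], "HCC"),
      reduced_top20 = refit_reduced(ft, split,
                                    subset = vips$feature[vips$rank <= 20],
                                    max_components = max_components),
      reduced_vip1 = refit_reduced(ft, split,
                                   subset = vips$feature[vips$vip > 1],
                                   max_components = max_components),
      accuracy_training = hcc_acc(y_train, pred_train$.pred_class),
      accuracy_cv = if (!is.null(cv_mis)) {
        round(100 * mean(!cv_mis[y_train == "HCC"]), 2)
      } else NA_real_,
      accuracy_test = hcc_acc(sp$group[!train], pred_test$.pred_class)
    )
    if (with_simca) {
      n_pcs <- select_components_loo(m[train, , drop = FALSE], y_train,
                                     "simca", max_components = max_components)
      sim <- fit_simca(x_train, y_train, n_pcs = as.integer(n_pcs))
      sim_pred <- predict(sim, m[!train, , drop = FALSE],
                          mode = "discriminant")
      res$simca <- sim
      res$simca_n_pcs <- as.integer(n_pcs)
      res$simca_metrics_test <- class_metrics(sp$group[!train],
                                              sim_pred$.pred_class)
    }
    res
  })

  samples <- ft_study_only(blocks$metabolomics)$samples
  afp <- afp_benchmark(samples, split, threshold = afp_threshold)
  comparison <- compare_methods(split, purrr::map(models, function(r) {
    r[c("n_lv", "accuracy_training", "accuracy_cv", "accuracy_test")]
  }), afp)

  structure(
    list(blocks = blocks, split = split, models = models, afp = afp,
         comparison = comparison, scaling = scaling),
    class = "lipometab_workflow"
  )
}

#' @export
print.lipometab_workflow <- function(x, ...) {
  cat("<lipometab_workflow>\n")
  cat("  split:", sum(x$split$split == "train"), "train /",
      sum(x$split$split == "test"), "test\n")
  for (b in names(x$models)) {
    m <- x$models[[b]]
    cat(sprintf("  %s: %d LV, test accuracy %.2f%%\n", b, m$n_lv,
                m$metrics_test$accuracy))
  }
  cat("  HCC-classification accuracy comparison:\n")
  print(as.data.frame(x$comparison), row.names = FALSE)
  invisible(x)
}
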