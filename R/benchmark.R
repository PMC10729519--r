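#' Pearson chi-square test on an r x c contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1),
#' upper-tail p-value.
#'
#' @param tab Matrix of counts, at least 2 x 2, no zero row/column margin.
#' @return Object of class `contingency_result`: `observed`, `test`,
#'   `statistic`, `df`, `p_value`.
#' @export
chi_square_rxc <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("table must be at least 2 x 2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(observed = tab, test = "chi_square",
         statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value),
    class = "contingency_result"
  )
}

#' Two-sided Fisher exact test on a 2 x 2 table
#'
#' Two-sided p-value as the sum of the probabilities of all tables with
#' the same margins that are no more probable than the observed one.
#'
#' @param tab 2 x 2 matrix of non-negative counts with positive margins.
#' @return Object of class `contingency_result` (statistic and df `NA`;
#'   the test is exact).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2 x 2")
  if (any(tab < 0)) stop("counts must be non-negative")
  res <- stats::fisher.test(tab)
  structure(
    list(observed = tab, test = "fisher_exact",
         statistic = NA_real_, df = NA_integer_, p_value = res$p.value),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> %s: p = %.4g", x$test, x$p_value))
  if (is.finite(x$statistic)) {
    cat(sprintf(" (statistic = %.4f, df = %d)", x$statistic, as.integer(x$df)))
  }
  cat("\n")
  print(x$observed)
  invisible(x)
}

#' Classify samples by the AFP threshold rule
#'
#' A sample is called HCC-positive iff its AFP strictly exceeds the
#' threshold; the boundary value itself is negative, matching the clinical
#' "<= 20 ng/mL" bin. Missing AFP yields `NA` (those samples are excluded
#' from accuracy summaries).
#'
#' @param afp Numeric AFP values (ng/mL); `NA` for not determined.
#' @param threshold Positivity threshold (default 20 ng/mL).
#' @return Logical vector: `TRUE` = called HCC-positive, `NA` = no AFP.
#' @export
afp_classify <- function(afp, threshold = 20) {
  afp > threshold
}

#' AFP-rule accuracy over HCC samples, per split partition
#'
#' Uses the shared Kennard-Stone split: within each partition, the AFP
#' accuracy is the percentage of HCC samples (with measured AFP) called
#' positive by [afp_classify()] — HCC samples at or below the threshold
#' count as misclassified.
#'
#' @param samples Sample metadata tibble with `sample_id`, `group`, `afp`.
#' @param split A split assignment from [split_per_class()].
#' @param threshold AFP positivity threshold (default 20 ng/mL).
#' @return Tibble of class `afp_benchmark`: `split`, `n_hcc`,
#'   `n_correct`, `accuracy`.
#' @export
afp_benchmark <- function(samples, split, threshold = 20) {
  df <- dplyr::inner_join(samples, split[, c("sample_id", "split")],
                          by = "sample_id") |>
    dplyr::filter(.data$group == "HCC", !is.na(.data$afp))
  out <- df |>
    dplyr::group_by(split = .data$split) |>
    dplyr::summarise(
      n_hcc = dplyr::n(),
      n_correct = sum(afp_classify(.data$afp, threshold)),
      accuracy = round(100 * .data$n_correct / .data$n_hcc, 2),
      .groups = "drop"
    )
  class(out) <- c("afp_benchmark", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Compare omics PLS-DA models with the AFP rule for HCC classification
#'
#' Assembles, on one shared split, the per-method HCC-classification
#' accuracies (training, cross-validation where available, test) for the
#' omics PLS-DA models next to the AFP threshold rule.
#'
#' @param split The shared split assignment.
#' @param omics Named list (per block); each element a list with
#'   `accuracy_training`, `accuracy_cv` (may be `NA`), `accuracy_test`,
#'   and optionally `n_lv`.
#' @param afp An [afp_benchmark()] result computed on the same split.
#' @return Tibble: `method`, `n_lv`, `accuracy_training`, `accuracy_cv`,
#'   `accuracy_test`.
#' @export
compare_methods <- function(split, omics, afp) {
  stopifnot(inherits(afp, "afp_benchmark"))
  rows <- purrr::imap_dfr(omics, function(res, name) {
    tibble::tibble(
      method = paste0("PLS-DA ", name),
      n_lv = res$n_lv %||% NA_integer_,
      accuracy_training = res$accuracy_training,
      accuracy_cv = res$accuracy_cv %||% NA_real_,
      accuracy_test = res$accuracy_test
    )
  })
  get_acc <- function(part) {
    v <- afp$accuracy[afp$split == part]
    if (length(v)) v else NA_real_
  }
  dplyr::bind_rows(rows, tibble::tibble(
    method = "AFP", n_lv = NA_integer_,
    accuracy_training = get_acc("train"),
    accuracy_cv = NA_real_,
    accuracy_test = get_acc("test")
  ))
}

#' Evaluate PLS-DA on AFP-negative HCC test samples
#'
#' Fits the PLS-DA model on the training partition, reduces the feature
#' space to the influential variables (VIP > 1, or the top-20 VIPs), and
#' evaluates on a test set in which the HCC samples are restricted to the
#' AFP-negative ones (AFP <= threshold) — the patients the AFP rule cannot
#' catch. Reports the confusion matrix and the HCC-vs-rest ROC.
#'
#' @param ft A preprocessed [feature_table].
#' @param split The shared split assignment.
#' @param subset_mode `"all_vip"` (VIP > 1) or `"top20_vip"` (20 highest
#'   VIPs).
#' @param n_lv Latent variables for the reduced model; LOO-selected when
#'   `NULL`.
#' @param max_components Bound for LOO selection.
#' @param threshold AFP threshold (default 20 ng/mL).
#' @return List: `metrics` (`class_metrics`), `roc` (`roc_result`),
#'   `subset` (features used), `n_lv`.
#' @export
afp_negative_eval <- function(ft, split,
                              subset_mode = c("all_vip", "top20_vip"),
                              n_lv = NULL, max_components = 10L,
                              threshold = 20) {
  subset_mode <- match.arg(subset_mode)
  ft <- ft_study_only(ft)
  sp <- split[match(ft$samples$sample_id, split$sample_id), ]
  train <- sp$split == "train"

  # full-model VIPs on the training partition drive the reduction
  x_train <- autoscale(ft_matrix(ft)[train, , drop = FALSE], quiet = TRUE)
  full_lv <- n_lv %||% select_components_loo(ft_matrix(ft)[train, , drop = FALSE],
                                             sp$group[train], "plsda",
                                             max_components = max_components)
  full <- fit_plsda(x_train, sp$group[train], n_lv = full_lv)
  vips <- vip_scores(full)
  subset <- switch(subset_mode,
    all_vip = vips$feature[vips$vip > 1],
    top20_vip = vips$feature[vips$rank <= 20]
  )
  if (!length(subset)) stop("no feature passes the VIP criterion")

  reduced <- refit_reduced(ft, split, subset = subset, n_lv = n_lv,
                           max_components = max_components)

  test_idx <- which(!train)
  afp <- ft$samples$afp[test_idx]
  grp <- sp$group[test_idx]
  keep <- grp != "HCC" | (!is.na(afp) & afp <= threshold)
  if (!any(grp[keep] == "HCC")) {
    stop("no AFP-negative HCC sample in the test partition")
  }
  x_eval <- ft_matrix(ft_select_features(ft, subset))[test_idx[keep], ,
                                                      drop = FALSE]
  pred <- predict(reduced$model, x_eval)
  metrics <- class_metrics(grp[keep], pred$.pred_class)
  roc <- roc_curve(pred[["HCC"]], grp[keep], "HCC")
  list(metrics = metrics, roc = roc, subset = subset, n_lv = reduced$n_lv)
}

#' Cohort summary with group-comparison statistics
#'
#' Builds the clinical summary of the study table: for each binary
#' characteristic, per-class counts and a group-comparison p-value —
#' Pearson chi-square when all three classes are observed, two-sided
#' Fisher exact for 2 x 2 comparisons (classes with no determination
#' dropped).
#'
#' @param samples Sample metadata tibble (`group`, `sample_type`, `afp`,
#'   `age`, `gender`).
#' @param afp_threshold,age_cut Binning cut points (20 ng/mL, 65 years).
#' @return Tibble: `variable`, per-class `<class>_yes`/`<class>_no`
#'   counts, `test`, `p_value`.
#' @export
cohort_summary <- function(samples, afp_threshold = 20, age_cut = 65) {
  s <- samples[samples$sample_type == "study", ]
  vars <- list(
    `age > 65` = s$age > age_cut,
    `male` = s$gender == "M",
    `AFP > 20` = s$afp > afp_threshold
  )
  purrr::imap_dfr(vars, function(flag, name) {
    ok <- !is.na(flag)
    tab <- table(factor(flag[ok], c(TRUE, FALSE)), s$group[ok])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    res <- if (ncol(tab) >= 3) chi_square_rxc(tab) else fisher_exact_2x2(tab)
    counts <- as.vector(tab)
    names(counts) <- paste0(rep(colnames(tab), each = 2),
                            c("_yes", "_no"))
    dplyr::bind_cols(
      tibble::tibble(variable = name),
      tibble::as_tibble_row(as.list(counts)),
      tibble::tibble(test = res$test, p_value = res$p_value)
    )
  })
}
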