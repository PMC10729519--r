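#' Per-feature one-way ANOVA across classes
#'
#' Runs a fixed-effects one-way ANOVA for every feature on the (typically
#' preprocessed) abundances. Degenerate features with zero within-group
#' variance get `p = 1` when all group means are equal (no evidence) and
#' `p = 0` when they differ (infinite F), with a flag.
#'
#' @param x A [feature_table] (study samples and their `group` are used) or
#'   a numeric matrix.
#' @param groups Class label per row (required when `x` is a matrix).
#' @return Tibble: `feature`, `f_statistic`, `p_value`, `degenerate`.
#' @export
univariate_anova <- function(x, groups = NULL) {
  if (inherits(x, "feature_table")) {
    x <- ft_study_only(x)
    groups <- x$samples$group
    x <- ft_matrix(x)
  }
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  purrr::map_dfr(colnames(x) %||% seq_len(ncol(x)), function(j) {
    v <- x[, j]
    res <- suppressWarnings(
      tryCatch(stats::oneway.test(v ~ groups, var.equal = TRUE),
               error = function(e) NULL)
    )
    f <- if (is.null(res)) NaN else unname(res$statistic)
    p <- if (is.null(res)) NaN else res$p.value
    degenerate <- !is.finite(f) || !is.finite(p)
    if (degenerate) {
      mu <- tapply(v, groups, mean)
      if (max(mu) - min(mu) < 1e-12) {
        f <- 0
        p <- 1
      } else {
        f <- Inf
        p <- 0
      }
    }
    tibble::tibble(feature = as.character(j), f_statistic = f,
                   p_value = p, degenerate = degenerate)
  })
}

#' Pearson correlation of features with age
#'
#' Audits whether model-relevant features merely track age: for each
#' feature, the Pearson correlation with age and its two-sided t-test
#' p-value are reported. Zero-variance features are flagged (`NA`
#' correlation).
#'
#' @param x A [feature_table] (study samples, `age` from the metadata) or a
#'   numeric matrix.
#' @param ages Age per row (required when `x` is a matrix).
#' @return Tibble: `feature`, `r`, `p_value`, `degenerate`.
#' @export
age_correlation <- function(x, ages = NULL) {
  if (inherits(x, "feature_table")) {
    x <- ft_study_only(x)
    ages <- x$samples$age
    x <- ft_matrix(x)
  }
  x <- as.matrix(x)
  if (length(ages) != nrow(x)) stop("ages must match rows of x")
  if (nrow(x) < 3) stop("need at least 3 samples")
  purrr::map_dfr(colnames(x) %||% seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (stats::sd(v) == 0 || stats::sd(ages) == 0) {
      return(tibble::tibble(feature = as.character(j), r = NA_real_,
                            p_value = NA_real_, degenerate = TRUE))
    }
    ct <- stats::cor.test(v, ages, method = "pearson")
    tibble::tibble(feature = as.character(j), r = unname(ct$estimate),
                   p_value = ct$p.value, degenerate = FALSE)
  })
}

#' Over-representation analysis by the hypergeometric test
#'
#' For each annotation set, the upper-tail hypergeometric probability of
#' the observed overlap with the selected features, and the enrichment
#' ratio (observed / expected overlap). Sets are intersected with the
#' universe first.
#'
#' @param selected Character vector of selected feature ids (must be a
#'   subset of `universe`).
#' @param annotation_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector: all features eligible for selection.
#' @return Tibble: `set`, `set_size`, `overlap`, `expected`,
#'   `enrichment_ratio`, `p_value`.
#' @export
over_representation <- function(selected, annotation_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stop("selected features outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  selected <- unique(selected)
  k <- length(selected)
  N <- length(universe)
  purrr::imap_dfr(annotation_sets, function(members, set_name) {
    m <- length(intersect(members, universe))
    ov <- length(intersect(members, selected))
    expected <- k * m / N
    tibble::tibble(
      set = set_name, set_size = m, overlap = ov, expected = expected,
      enrichment_ratio = if (expected > 0) ov / expected else NA_real_,
      p_value = stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    )
  })
}

#' Read a GMT-style annotation set file
#'
#' Tab-separated lines: set name, description, then member ids.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Refit a PLS-DA model on a reduced feature subset
#'
#' Reruns the modelling pipeline from autoscaling onward on a feature
#' subset (e.g. the VIP > 1 features or the top-20 VIPs), using the shared
#' train/test split: autoscaling parameters are learned on the training
#' partition, the model is fit on it, and metrics plus the one-vs-rest ROC
#' for the positive class are computed on the test partition.
#'
#' @param ft A preprocessed [feature_table].
#' @param split A split assignment from [split_per_class()].
#' @param subset Character vector of feature ids (non-empty, present in
#'   `ft`); defaults to all features.
#' @param n_lv Number of latent variables; selected by leave-one-out
#'   cross-validation on the training partition when `NULL`.
#' @param max_components Upper bound for the LOO selection.
#' @param positive Positive class for the ROC (default `"HCC"`).
#' @return List: `model` (`plsda_model`), `metrics` (`class_metrics` on the
#'   test partition), `roc` (`roc_result`), `n_lv`.
#' @export
refit_reduced <- function(ft, split, subset = NULL, n_lv = NULL,
                          max_components = 10L, positive = "HCC") {
  ft <- ft_study_only(ft)
  if (is.null(subset)) subset <- ft$features$feature_id
  if (!length(subset)) stop("feature subset is empty")
  ft <- ft_select_features(ft, subset)
  m <- ft_matrix(ft)
  sp <- split[match(rownames(m), split$sample_id), ]
  if (anyNA(sp$split)) stop("split does not cover all study samples")
  train <- sp$split == "train"
  x_train_raw <- m[train, , drop = FALSE]
  x_train <- autoscale(x_train_raw)
  if (ncol(x_train) == 0) {
    stop("no feature in the subset survives autoscaling (all constant)")
  }
  y_train <- sp$group[train]
  if (is.null(n_lv)) {
    n_lv <- select_components_loo(x_train_raw, y_train, "plsda",
                                  max_components = max_components)
  }
  model <- fit_plsda(x_train, y_train, n_lv = n_lv)
  x_test <- m[!train, , drop = FALSE]
  pred <- predict(model, x_test)
  metrics <- class_metrics(sp$group[!train], pred$.pred_class)
  roc <- roc_curve(pred[[positive]], sp$group[!train], positive)
  list(model = model, metrics = metrics, roc = roc, n_lv = as.integer(n_lv))
}
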