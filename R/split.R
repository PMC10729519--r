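#' Kennard-Stone maximin sample selection
#'
#' The classic deterministic algorithm for picking a representative subset:
#' start from the two points with the largest Euclidean distance, then
#' repeatedly add the candidate whose minimum distance to the already
#' selected set is maximal. All ties are broken by the lowest sample index,
#' so the selection is fully deterministic (duplicate points allowed).
#'
#' @param points Numeric matrix (samples x dimensions).
#' @param k Number of samples to select, `2 <= k <= nrow(points)`.
#' @return Integer vector of length `k`: row indices in selection order.
#' @export
kennard_stone <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of samples")
  d <- as.matrix(stats::dist(points))
  # farthest pair; ties resolved to the lexicographically smallest (i, j)
  up <- which(upper.tri(d), arr.ind = TRUE)
  up <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  best <- up[which.max(d[up]), ]
  selected <- c(best[[1]], best[[2]])
  remaining <- setdiff(seq_len(n), selected)
  min_d <- pmin(d[, selected[1]], d[, selected[2]])
  while (length(selected) < k) {
    cand <- remaining[which.max(min_d[remaining])] # which.max -> lowest index
    selected <- c(selected, cand)
    remaining <- setdiff(remaining, cand)
    min_d <- pmin(min_d, d[, cand])
  }
  selected
}

#' Per-class Kennard-Stone train/test split on SUM-PCA super scores
#'
#' For each class independently: autoscale that class's block matrices, fit
#' SUM-PCA, take the leading super-score columns, and run Kennard-Stone to
#' select `ceil(fraction * n_class)` training samples; the remainder form
#' the test set. The split is shared by all blocks (and by the AFP
#' benchmark), and rerunning on the same tables reproduces it exactly.
#'
#' @param blocks A [feature_table] or named list of preprocessed
#'   [feature_table]s sharing the same samples. QC samples are excluded.
#' @param fused_components Super-score dimensions used for Kennard-Stone
#'   distances (default 3).
#' @param fraction Training fraction per class (default 0.7; the training
#'   size is `ceiling(fraction * n_class)`).
#' @return Tibble of class `split_assignment`: `sample_id`, `group`,
#'   `split` (`"train"`/`"test"`), `ks_rank` (selection order within the
#'   class, `NA` for test samples).
#' @export
split_per_class <- function(blocks, fused_components = 3L, fraction = 0.7) {
  if (inherits(blocks, "feature_table")) blocks <- list(block = blocks)
  blocks <- purrr::map(blocks, ft_study_only)
  samples <- blocks[[1]]$samples
  for (b in blocks) {
    if (!identical(b$samples$sample_id, samples$sample_id)) {
      stop("blocks do not share the same study samples")
    }
  }
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  classes <- unique(samples$group)
  out <- purrr::map_dfr(classes, function(cls) {
    idx <- which(samples$group == cls)
    n_cls <- length(idx)
    if (n_cls < 3) stop("class ", cls, " has fewer than 3 samples")
    mats <- purrr::map(blocks, function(b) {
      m <- ft_matrix(b)[idx, , drop = FALSE]
      autoscale(m, quiet = TRUE)
    })
    mats <- purrr::keep(mats, ~ ncol(.x) > 0)
    if (!length(mats)) {
      scores <- matrix(0, n_cls, 1) # all-constant class: ties decide by index
    } else {
      k <- min(fused_components, n_cls - 1L,
               sum(vapply(mats, ncol, integer(1))))
      fit <- suppressWarnings(sum_pca(mats, n_components = k))
      scores <- fit$super_scores
    }
    n_train <- ceiling(fraction * n_cls)
    if (n_train >= n_cls) {
      sel <- seq_len(n_cls)
    } else if (n_train < 2) {
      stop("training fraction leaves fewer than 2 samples in class ", cls)
    } else {
      sel <- kennard_stone(scores, n_train)
    }
    rank <- rep(NA_integer_, n_cls)
    rank[sel] <- seq_along(sel)
    tibble::tibble(
      sample_id = samples$sample_id[idx],
      group = cls,
      split = ifelse(seq_len(n_cls) %in% sel, "train", "test"),
      ks_rank = rank
    )
  })
  out <- out[match(samples$sample_id, out$sample_id), ]
  class(out) <- c("split_assignment", class(out))
  attr(out, "fused_components") <- fused_components
  attr(out, "fraction") <- fraction
  out
}
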