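#' Principal component analysis by singular value decomposition
#'
#' Fits PCA on an already autoscaled (or at least column-centered) matrix.
#' Scores are `U %*% S`, eigenvalues are `S^2 / (n - 1)` in descending
#' order, and a deterministic sign convention is applied: the
#' largest-magnitude element of each loading column is positive, so scores
#' are reproducible across platforms.
#'
#' @param x Numeric matrix, samples in rows. If `x` carries `center`/`scale`
#'   attributes (from [autoscale()]) they are stored for projection.
#' @param n_components Number of components to retain (truncated to the
#'   matrix rank, with a warning).
#' @return Object of class `pca_model` with elements `loadings`, `scores`,
#'   `eigenvalues`, `center`, `scale`, `n_components`, `total_variance`.
#' @export
fit_pca <- function(x, n_components = min(dim(x)) - 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 rows")
  ctr <- attr(x, "center")
  scl <- attr(x, "scale")
  sv <- svd(x)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (n_components > rank) {
    warning("n_components (", n_components, ") exceeds rank (", rank,
            "); truncated")
    n_components <- rank
  }
  k <- n_components
  # sign convention: largest-|loading| element of each column positive
  flip <- vapply(seq_len(k), function(a) {
    v <- sv$v[, a]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  rownames(loadings) <- colnames(x)
  rownames(scores) <- rownames(x)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(loadings = loadings, scores = scores,
         eigenvalues = sv$d[seq_len(k)]^2 / (nrow(x) - 1),
         center = ctr, scale = scl, n_components = k,
         total_variance = sum(sv$d^2) / (nrow(x) - 1)),
    class = "pca_model"
  )
}

#' Project new samples onto a fitted PCA
#'
#' @param object A `pca_model`.
#' @param newdata Matrix with the training feature columns; autoscaled with
#'   the stored center/scale when the model carries them, otherwise assumed
#'   pre-scaled.
#' @param ... Unused.
#' @return Score matrix (samples x components).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$center)) {
    newdata <- autoscale(newdata[, names(object$center), drop = FALSE],
                         center = object$center, scale = object$scale)
  }
  newdata %*% object$loadings
}

#' Multiblock SUM-PCA (low-level data fusion)
#'
#' Scales each autoscaled block so that all blocks contribute equal total
#' variance (default: divide block b by `sqrt(p_b)`, its number of
#' variables), concatenates the blocks column-wise, and fits a single PCA
#' on the fused matrix. The fused scores are the super scores (T_sup) that
#' summarize all blocks jointly.
#'
#' @param blocks Named list of autoscaled matrices sharing the same sample
#'   order (checked via rownames when present).
#' @param n_components Number of super components.
#' @param weighting Block weighting: `"sqrt_nvar"` (1/sqrt(p_b), equal total
#'   sum of squares after autoscaling), `"sqrt_eigen"` (1/sqrt(first
#'   eigenvalue of the block PCA)), or `"none"`.
#' @return Object of class `sum_pca_model`: `super_scores`,
#'   `super_loadings`, `eigenvalues`, `block_weights`, `block_index` (block
#'   of each fused column), and the underlying `pca` model.
#' @export
sum_pca <- function(blocks, n_components = 3L,
                    weighting = c("sqrt_nvar", "sqrt_eigen", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  rn <- lapply(blocks, rownames)
  if (!is.null(rn[[1]])) {
    for (b in seq_along(blocks)[-1]) {
      if (!identical(rn[[1]], rn[[b]])) {
        diff <- c(setdiff(rn[[1]], rn[[b]]), setdiff(rn[[b]], rn[[1]]))
        stop("blocks do not share the same samples/order; differing: ",
             paste(utils::head(diff, 5), collapse = ", "))
      }
    }
  }
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1) stop("blocks have differing numbers of rows")

  w <- vapply(names(blocks), function(b) {
    x <- blocks[[b]]
    switch(weighting,
      sqrt_nvar = 1 / sqrt(ncol(x)),
      sqrt_eigen = 1 / sqrt(fit_pca(x, 1L)$eigenvalues[1]),
      none = 1
    )
  }, numeric(1))
  fused <- do.call(cbind, purrr::imap(blocks, function(x, b) {
    x <- as.matrix(x)
    colnames(x) <- paste0(b, ".", colnames(x))
    x * w[[b]]
  }))
  block_index <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  pca <- fit_pca(fused, n_components)
  structure(
    list(super_scores = pca$scores, super_loadings = pca$loadings,
         eigenvalues = pca$eigenvalues, block_weights = w,
         block_index = block_index, n_components = pca$n_components,
         total_variance = pca$total_variance, pca = pca),
    class = "sum_pca_model"
  )
}

#' Hotelling T-squared confidence ellipse for a 2-D score plot
#'
#' The critical value is `T2 = 2 (n - 1) / (n - 2) * F(1 - alpha; 2, n - 2)`;
#' the ellipse axes come from the eigendecomposition of the score
#' covariance scaled by the critical value.
#'
#' @param scores Matrix with exactly 2 columns (a score pair), >= 4 rows.
#' @param alpha Significance level (default 0.05 for a 95% ellipse).
#' @return Object of class `hotelling_ellipse`: `center`, `semi_axes`,
#'   `angle` (radians, orientation of the major axis), `t2_crit`, `cov`,
#'   `n`, `alpha`.
#' @export
hotelling_ellipse <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("Hotelling ellipse is defined for 2-D scores")
  n <- nrow(scores)
  if (n < 4) stop("need at least 4 samples")
  S <- stats::cov(scores)
  if (!is.finite(determinant(S)$modulus) || det(S) <= 0) {
    stop("singular score covariance")
  }
  t2_crit <- 2 * (n - 1) / (n - 2) * stats::qf(1 - alpha, 2, n - 2)
  eig <- eigen(S, symmetric = TRUE)
  structure(
    list(center = colMeans(scores),
         semi_axes = sqrt(eig$values * t2_crit),
         angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
         t2_crit = t2_crit, cov = S, n = n, alpha = alpha),
    class = "hotelling_ellipse"
  )
}

#' Test points for inclusion in a Hotelling ellipse
#'
#' @param ellipse A [hotelling_ellipse()].
#' @param scores Matrix with 2 columns.
#' @return Logical vector: `TRUE` when the point's T-squared distance is at
#'   most the critical value.
#' @export
in_ellipse <- function(ellipse, scores) {
  d2 <- stats::mahalanobis(as.matrix(scores), ellipse$center, ellipse$cov)
  d2 <= ellipse$t2_crit
}

#' Outline of a Hotelling ellipse for plotting
#'
#' @param ellipse A [hotelling_ellipse()].
#' @param n_points Number of outline points.
#' @return Tibble with columns `x`, `y` tracing the ellipse boundary.
#' @export
ellipse_outline <- function(ellipse, n_points = 181) {
  th <- seq(0, 2 * pi, length.out = n_points)
  a <- ellipse$semi_axes[1]
  b <- ellipse$semi_axes[2]
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  xy <- cbind(a * cos(th), b * sin(th)) %*% t(rot)
  tibble::tibble(x = xy[, 1] + ellipse$center[1],
                 y = xy[, 2] + ellipse$center[2])
}
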