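#' Fit a PLS-DA classifier (NIPALS PLS2)
#'
#' Codes the class labels as a one-hot response matrix (columns centered),
#' then runs the NIPALS PLS2 algorithm with X- and Y-deflation. The fitted
#' object stores the weights `W`, X-loadings `P`, Y-loadings `Q`, scores
#' `T`, regression coefficients `B`, and the Y sum of squares explained per
#' component (`ss_y`, used by [vip_scores()]). With as many latent
#' variables as the rank of `X`, the fit coincides with multivariate least
#' squares on the one-hot response.
#'
#' @param x Training matrix (samples x features), autoscaled via
#'   [autoscale()] (its `center`/`scale` attributes, when present, are
#'   stored and applied at prediction time).
#' @param labels Class label per row (>= 2 distinct classes).
#' @param n_lv Number of latent variables.
#' @param tol,max_iter NIPALS inner-loop convergence controls.
#' @return Object of class `plsda_model`.
#' @export
fit_plsda <- function(x, labels, n_lv, tol = 1e-10, max_iter = 500) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("PLS-DA needs at least 2 classes")
  if (n_lv < 1) stop("n_lv must be >= 1")
  n <- nrow(x)
  p <- ncol(x)
  ctr <- attr(x, "center")
  scl <- attr(x, "scale")

  Y <- 1 * outer(labels, classes, "==")
  colnames(Y) <- classes
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  ss_y_total <- sum(Yc^2)

  Xd <- x
  Yd <- Yc
  W <- P <- matrix(0, p, n_lv)
  Q <- matrix(0, length(classes), n_lv)
  Tt <- matrix(0, n, n_lv)
  ss_y <- numeric(n_lv)
  a <- 0L
  while (a < n_lv) {
    if (sum(Xd^2) < 1e-12 * max(1, sum(x^2)) || sum(Yd^2) < 1e-12) {
      warning("X/Y residual exhausted after ", a, " components; truncating")
      break
    }
    a <- a + 1L
    u <- Yd[, which.max(colSums(Yd^2))]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tsc <- Xd %*% w
      q <- crossprod(Yd, tsc)[, 1] / sum(tsc^2)
      u <- (Yd %*% q) / sum(q^2)
      if (sum((w - w_old)^2) < tol^2) break
      w_old <- w
    }
    pl <- crossprod(Xd, tsc)[, 1] / sum(tsc^2)
    Xd <- Xd - tsc %*% t(pl)
    Yd <- Yd - tsc %*% t(q)
    W[, a] <- w
    P[, a] <- pl
    Q[, a] <- q
    Tt[, a] <- tsc
    ss_y[a] <- sum(tsc^2) * sum(q^2)
  }
  keep <- seq_len(a)
  W <- W[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]
  Q <- Q[, keep, drop = FALSE]
  Tt <- Tt[, keep, drop = FALSE]
  ss_y <- ss_y[keep]
  rownames(W) <- rownames(P) <- colnames(x)
  rownames(Q) <- classes
  B <- W %*% solve(crossprod(P, W), t(Q))
  rownames(B) <- colnames(x)
  colnames(B) <- classes

  structure(
    list(weights = W, x_loadings = P, y_loadings = Q, scores = Tt,
         coefficients = B, n_lv = a, classes = classes,
         y_means = y_means, center = ctr, scale = scl,
         ss_y = ss_y, ss_y_total = ss_y_total,
         features = colnames(x), labels = labels),
    class = "plsda_model"
  )
}

# scale new data with the stored training parameters (if any) and check
# feature alignment
plsda_prepare_newdata <- function(object, newdata) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) {
    stop("newdata lacks training feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  newdata <- newdata[, object$features, drop = FALSE]
  if (!is.null(object$center)) {
    newdata <- autoscale(newdata, center = object$center, scale = object$scale)
  }
  newdata
}

#' Predict classes from a fitted PLS-DA model
#'
#' Continuous per-class scores are the predicted (centered-one-hot)
#' responses plus the training class means; the label is the class with
#' the largest score, ties going deterministically to the
#' first class in sorted order.
#'
#' @param object A `plsda_model`.
#' @param newdata Matrix with the training features (raw scale when the
#'   model stores autoscaling parameters).
#' @param ... Unused.
#' @return Tibble with `.pred_class` and one numeric score column per class.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- plsda_prepare_newdata(object, newdata)
  scores <- newdata %*% object$coefficients
  scores <- sweep(scores, 2, object$y_means, "+")
  pred <- object$classes[apply(scores, 1, which.max)] # which.max: lowest index on ties
  out <- tibble::as_tibble(as.data.frame(scores))
  dplyr::bind_cols(tibble::tibble(.pred_class = pred), out)
}

#' Variable importance in projection (VIP) scores
#'
#' For a PLS2 model, `VIP_j = sqrt(p * sum_a(SS_a * w_aj^2) / sum_a(SS_a))`
#' with normalized weight vectors `w_a` and `SS_a` the Y sum of squares
#' explained by component `a`. Squared VIPs average to 1, so features with
#' VIP > 1 are conventionally regarded as influential.
#'
#' @param model A fitted `plsda_model`.
#' @return Tibble of class `vip_result`: `feature`, `vip`, `rank` (ties in
#'   `vip` broken by feature id).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  ss <- model$ss_y
  if (sum(ss) <= 0) stop("model explains zero Y sum of squares")
  W <- model$weights
  w2 <- sweep(W^2, 2, colSums(W^2), "/") # guard: W columns are unit norm
  p <- nrow(W)
  vip <- sqrt(p * as.numeric(w2 %*% ss) / sum(ss))
  out <- tibble::tibble(feature = rownames(W), vip = vip) |>
    dplyr::arrange(dplyr::desc(vip), feature) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("vip_result", class(out))
  out
}

#' Select the number of components by leave-one-out cross-validation
#'
#' For each candidate component count `k`, every sample is left out in
#' turn, the model is refit on the remainder and the left-out sample
#' classified; the chosen count is the smallest `k` attaining the minimum
#' misclassification count (ties broken toward parsimony).
#'
#' @param x Training matrix (raw scale; autoscaling is refit inside every
#'   leave-one-out fold to avoid leakage).
#' @param labels Class label per row.
#' @param fitter `"plsda"` (latent variables) or `"simca"` (per-class
#'   principal components, the same count for every class, discriminant
#'   prediction).
#' @param max_components Largest component count tried.
#' @param alpha SIMCA limit level (ignored for PLS-DA).
#' @return Integer: the chosen component count, with attribute `errors`
#'   (LOO misclassification count per candidate `k`).
#' @export
select_components_loo <- function(x, labels,
                                  fitter = c("plsda", "simca"),
                                  max_components = 10L, alpha = 0.05) {
  fitter <- match.arg(fitter)
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (max_components < 1) stop("max_components must be >= 1")
  if (fitter == "simca") {
    # leaving one sample out shrinks the smallest class by one, and each
    # class needs more than k + 1 rows to fit k PCs
    max_components <- min(max_components, min(table(labels)) - 3L)
    max_components <- max(max_components, 1L)
  }
  errs <- matrix(FALSE, n, max_components)
  for (i in seq_len(n)) {
    xt <- autoscale(x[-i, , drop = FALSE], quiet = TRUE)
    xi <- x[i, colnames(xt), drop = FALSE]
    if (fitter == "plsda") {
      fit <- fit_plsda(xt, labels[-i], n_lv = max_components)
      xi_s <- autoscale(xi, center = attr(xt, "center"),
                        scale = attr(xt, "scale"))
      # nested NIPALS models: evaluate every k from the single fit
      for (k in seq_len(max_components)) {
        kk <- min(k, fit$n_lv)
        Bk <- fit$weights[, 1:kk, drop = FALSE] %*%
          solve(crossprod(fit$x_loadings[, 1:kk, drop = FALSE],
                          fit$weights[, 1:kk, drop = FALSE]),
                t(fit$y_loadings[, 1:kk, drop = FALSE]))
        sc <- xi_s %*% Bk + fit$y_means
        errs[i, k] <- fit$classes[which.max(sc)] != labels[i]
      }
    } else {
      for (k in seq_len(max_components)) {
        fit <- fit_simca(xt, labels[-i], n_pcs = k, alpha = alpha)
        pred <- predict(fit, xi, mode = "discriminant")
        errs[i, k] <- pred$.pred_class != labels[i]
      }
    }
  }
  total <- colSums(errs)
  k <- which.min(total) # smallest k attaining the minimum
  structure(as.integer(k), errors = total, misclassified = errs[, k])
}
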