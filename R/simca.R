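#' Fit a SIMCA class model
#'
#' Soft Independent Modelling of Class Analogy: each class gets its own
#' autoscaled PCA submodel fit only on that class's training rows. Class
#' membership of new samples is judged against two critical limits at level
#' `alpha`: the Hotelling T-squared limit in the retained-score space
#' (`T2_crit = k (n - 1) / (n - k) * F(1 - alpha; k, n - k)`) and the
#' squared-residual limit `Q_crit` from Box's scaled chi-square
#' approximation using the moments of the discarded eigenvalues
#' (`g = theta2 / theta1`, `h = theta1^2 / theta2`,
#' `Q_crit = g * qchisq(1 - alpha, h)`).
#'
#' @param x Training matrix (samples x features).
#' @param labels Class label per row.
#' @param n_pcs Principal components per class: a single count or a named
#'   vector (one entry per class). Each class needs more than
#'   `n_pcs + 1` training samples.
#' @param alpha Level of the critical limits (default 0.05).
#' @return Object of class `simca_model`: per-class submodels with center,
#'   scale, loadings, score variances, `t2_crit`, `q_crit`.
#' @export
fit_simca <- function(x, labels, n_pcs, alpha = 0.05) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(n_pcs) == 1) {
    n_pcs <- stats::setNames(rep(n_pcs, length(classes)), classes)
  }
  if (!all(classes %in% names(n_pcs))) {
    stop("n_pcs must be named per class when not scalar")
  }
  submodels <- lapply(classes, function(cls) {
    rows <- labels == cls
    n <- sum(rows)
    k <- n_pcs[[cls]]
    if (n <= k + 1) {
      stop("class ", cls, " has ", n, " training samples; needs more than ",
           k + 1, " for ", k, " PCs")
    }
    xs <- autoscale(x[rows, , drop = FALSE], quiet = TRUE)
    sv <- svd(xs)
    eig <- sv$d^2 / (n - 1)
    if (k > sum(eig > 1e-12)) {
      stop("class ", cls, " has rank below the requested ", k, " PCs")
    }
    loadings <- sv$v[, seq_len(k), drop = FALSE]
    rownames(loadings) <- colnames(xs)
    resid_eig <- eig[-seq_len(k)]
    resid_eig <- resid_eig[resid_eig > 1e-12]
    if (length(resid_eig)) {
      theta1 <- sum(resid_eig)
      theta2 <- sum(resid_eig^2)
      g <- theta2 / theta1
      h <- theta1^2 / theta2
      q_crit <- g * stats::qchisq(1 - alpha, h)
    } else {
      q_crit <- Inf # model spans the class subspace; no residual distance
    }
    t2_crit <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
    list(center = attr(xs, "center"), scale = attr(xs, "scale"),
         loadings = loadings, score_var = eig[seq_len(k)],
         n = n, n_pcs = k, t2_crit = t2_crit, q_crit = q_crit)
  })
  names(submodels) <- classes
  structure(
    list(submodels = submodels, classes = classes, alpha = alpha,
         features = colnames(x)),
    class = "simca_model"
  )
}

# per-class T2 and Q statistics of new samples
simca_distances <- function(model, newdata) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(model$features, colnames(newdata))
  if (length(missing)) {
    stop("newdata lacks training feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  purrr::map(model$submodels, function(sm) {
    z <- autoscale(newdata[, names(sm$center), drop = FALSE],
                   center = sm$center, scale = sm$scale)
    tt <- z %*% sm$loadings
    t2 <- as.numeric((tt^2) %*% (1 / sm$score_var))
    q <- rowSums(z^2) - rowSums(tt^2)
    q <- pmax(q, 0)
    # reduced distance combining both criteria; within-limits samples fall
    # inside the sqrt(2) acceptance radius
    qq <- if (is.finite(sm$q_crit)) q / sm$q_crit else 0
    d <- sqrt((t2 / sm$t2_crit)^2 + qq^2)
    list(t2 = t2, q = q, d = d)
  })
}

#' Per-class SIMCA distance statistics
#'
#' Returns, for every sample and class submodel, the Hotelling T-squared
#' in the retained-score space, the squared residual Q, their critical
#' limits, and the combined reduced distance
#' `d = sqrt((T2/T2_crit)^2 + (Q/Q_crit)^2)`.
#'
#' @param model A `simca_model`.
#' @param newdata Matrix with the training features.
#' @return Tibble: `sample`, `class`, `t2`, `q`, `t2_crit`, `q_crit`, `d`.
#' @export
simca_distance_table <- function(model, newdata) {
  dist <- simca_distances(model, newdata)
  n <- length(dist[[1]]$t2)
  ids <- rownames(as.matrix(newdata)) %||% as.character(seq_len(n))
  purrr::imap_dfr(dist, function(ds, cls) {
    sm <- model$submodels[[cls]]
    tibble::tibble(sample = ids, class = cls, t2 = ds$t2, q = ds$q,
                   t2_crit = sm$t2_crit, q_crit = sm$q_crit, d = ds$d)
  })
}

#' Predict from a SIMCA model
#'
#' Each class reports a reduced distance
#' `d_c = sqrt((T2_c / T2_crit_c)^2 + (Q_c / Q_crit_c)^2)`. In
#' `class_modelling` mode a sample is accepted by class `c` iff
#' `d_c <= sqrt(2)` (it may belong to several classes or to none — outlier
#' status is expressible). In `discriminant` mode every sample is assigned
#' to the class with the smallest distance (ties to the first class in
#' sorted order).
#'
#' @param object A `simca_model`.
#' @param newdata Matrix with the training features.
#' @param mode `"discriminant"` or `"class_modelling"`.
#' @param ... Unused.
#' @return Tibble: per-class distance columns `d_<class>`, plus
#'   `.pred_class` (discriminant) or logical acceptance columns
#'   `accept_<class>` (class modelling).
#' @export
predict.simca_model <- function(object, newdata,
                                mode = c("discriminant", "class_modelling"),
                                ...) {
  mode <- match.arg(mode)
  dist <- simca_distances(object, newdata)
  d <- do.call(cbind, purrr::map(dist, "d"))
  colnames(d) <- object$classes
  out <- tibble::as_tibble(as.data.frame(d)) |>
    rlang::set_names(paste0("d_", object$classes))
  if (mode == "discriminant") {
    pred <- object$classes[apply(d, 1, which.min)]
    dplyr::bind_cols(tibble::tibble(.pred_class = pred), out)
  } else {
    acc <- tibble::as_tibble(as.data.frame(d <= sqrt(2))) |>
      rlang::set_names(paste0("accept_", object$classes))
    dplyr::bind_cols(acc, out)
  }
}
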