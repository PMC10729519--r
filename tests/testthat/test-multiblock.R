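test_that("PCA satisfies the SVD identities and sign convention", {
  set.seed(31)
  x <- autoscale(matrix(rnorm(300), 30, 10,
                        dimnames = list(NULL, paste0("v", 1:10))))
  fit <- fit_pca(x, n_components = 10)
  # loadings orthonormal, scores orthogonal
  expect_equal(crossprod(fit$loadings), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  off <- crossprod(fit$scores) - diag(diag(crossprod(fit$scores)))
  expect_lt(max(abs(off)), 1e-8)
  # eigenvalue sum equals total variance at full rank
  expect_equal(sum(fit$eigenvalues), fit$total_variance, tolerance = 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  # full reconstruction
  expect_equal(fit$scores %*% t(fit$loadings), unclass(x)[, ],
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: dominant loading entry positive
  expect_true(all(apply(fit$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("duplicated and collinear variables behave symmetrically", {
  set.seed(32)
  base <- rnorm(20)
  x <- autoscale(cbind(a = base, b = base))
  fit <- fit_pca(x, 1)
  expect_equal(abs(fit$loadings["a", 1]), abs(fit$loadings["b", 1]),
               tolerance = 1e-10)
  # rank-1 input: second eigenvalue zero, components truncated with warning
  x2 <- autoscale(cbind(a = c(0, 1, 2), b = c(0, 1, 2)))
  expect_warning(fit2 <- fit_pca(x2, 2), "rank")
  expect_equal(fit2$n_components, 1L)
})

test_that("projection reproduces training scores", {
  set.seed(33)
  raw <- matrix(rexp(200), 20, 10, dimnames = list(NULL, paste0("v", 1:10)))
  xs <- autoscale(raw)
  fit <- fit_pca(xs, 3)
  expect_equal(predict(fit, raw), fit$scores, tolerance = 1e-10)
})

test_that("SUM-PCA weights blocks to equal total sum of squares", {
  set.seed(34)
  b1 <- autoscale(matrix(rnorm(40 * 12), 40, 12,
                         dimnames = list(paste0("s", 1:40), paste0("m", 1:12))))
  b2 <- autoscale(matrix(rnorm(40 * 30), 40, 30,
                         dimnames = list(paste0("s", 1:40), paste0("l", 1:30))))
  fit <- sum_pca(list(met = b1, lip = b2), n_components = 3)
  ss1 <- sum((b1 * fit$block_weights[["met"]])^2)
  ss2 <- sum((b2 * fit$block_weights[["lip"]])^2)
  expect_equal(ss1, ss2, tolerance = 1e-8)
  # eigenvalue sum equals the weighted total variance of the fused matrix
  full <- sum_pca(list(met = b1, lip = b2), n_components = 39)
  expect_equal(sum(full$eigenvalues), (ss1 + ss2) / (40 - 1),
               tolerance = 1e-8)
})

test_that("single-block SUM-PCA equals plain PCA up to column sign", {
  set.seed(35)
  b <- autoscale(matrix(rnorm(25 * 8), 25, 8,
                        dimnames = list(NULL, paste0("v", 1:8))))
  pca <- fit_pca(b, 3)
  fused <- sum_pca(list(only = b), n_components = 3)
  # scores proportional column-wise with the 1/sqrt(p) weight
  ratio <- abs(fused$super_scores / pca$scores)
  expect_equal(unname(ratio), matrix(1 / sqrt(8), 25, 3), tolerance = 1e-8)
  for (k in 1:3) {
    cor_k <- cor(fused$super_scores[, k], pca$scores[, k])
    expect_equal(abs(cor_k), 1, tolerance = 1e-8)
  }
  # duplicating the block preserves proportionality to the single-block scores
  twin <- sum_pca(list(a = b, b = b), n_components = 3)
  expect_equal(unname(twin$block_weights[1]), unname(twin$block_weights[2]))
  for (k in 1:3) {
    expect_equal(abs(cor(twin$super_scores[, k], pca$scores[, k])), 1,
                 tolerance = 1e-8)
  }
})

test_that("mismatched block samples are rejected", {
  b1 <- autoscale(matrix(rnorm(20), 10, 2,
                         dimnames = list(paste0("s", 1:10), c("a", "b"))))
  b2 <- autoscale(matrix(rnorm(20), 10, 2,
                         dimnames = list(paste0("t", 1:10), c("c", "d"))))
  expect_error(sum_pca(list(b1, b2)), "differing")
})

test_that("Hotelling ellipse geometry responds to alpha and isotropy", {
  set.seed(36)
  sc <- matrix(rnorm(400), ncol = 2)
  el95 <- hotelling_ellipse(sc, alpha = 0.05)
  # isotropic scores: nearly circular
  expect_lt(abs(el95$semi_axes[1] / el95$semi_axes[2] - 1), 0.35)
  # alpha -> 1 shrinks the ellipse toward zero area
  el_tiny <- hotelling_ellipse(sc, alpha = 0.9999)
  expect_lt(prod(el_tiny$semi_axes), 1e-3 * prod(el95$semi_axes))
  expect_error(hotelling_ellipse(sc[1:3, ]), "at least 4")
  expect_error(hotelling_ellipse(cbind(1:10, 1:10)), "singular")
  # outline points sit exactly on the critical contour
  out <- ellipse_outline(el95, 50)
  d2 <- stats::mahalanobis(as.matrix(out), el95$center, el95$cov)
  expect_equal(d2, rep(el95$t2_crit, 50), tolerance = 1e-8)
})
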