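test_that("PCA matches an SVD oracle and obeys its invariants", {
  set.seed(10)
  # rank-1 matrix: one component explains everything
  u <- rnorm(8); v <- rnorm(5)
  r1 <- fit_pca(outer(u, v) , 1)
  expect_equal(r1$explained[1], 1, tolerance = 1e-10)
  for (dims in list(c(6, 4), c(20, 50))) {
    X <- matrix(rnorm(prod(dims)), dims[1])
    A <- min(dims[1] - 1, dims[2])
    fit <- fit_pca(X, A)
    Xc <- sweep(X, 2, colMeans(X))
    sv <- svd(Xc)
    # loadings agree with right singular vectors up to sign
    for (a in seq_len(min(5, A))) {
      expect_equal(abs(sum(fit$loadings[, a] * sv$v[, a])), 1,
                   tolerance = 1e-6)
    }
    # full-rank reconstruction
    expect_equal(fit$scores %*% t(fit$loadings), Xc, tolerance = 1e-8)
    expect_equal(crossprod(fit$loadings), diag(A), tolerance = 1e-8)
    expect_true(all(diff(fit$explained) <= 1e-8))
    expect_equal(sum(fit$explained), 1, tolerance = 1e-8)
    # sign convention: largest-magnitude loading entry positive
    expect_true(all(apply(fit$loadings, 2,
                          function(l) l[which.max(abs(l))] > 0)))
  }
  expect_error(fit_pca(matrix(rnorm(20), 4), 0), "A must be")
  expect_error(fit_pca(matrix(rnorm(20), 4), 4), "exceeds")
})

test_that("PCA projection returns scores, S-distance and leverage", {
  set.seed(11)
  X <- matrix(rnorm(12 * 6), 12)
  fit <- fit_pca(X, 3)
  proj <- pca_project(fit, X)
  expect_equal(proj$scores, fit$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  centre <- matrix(fit$mean, 1)
  pc <- pca_project(fit, centre)
  expect_equal(unname(pc$scores[1, ]), rep(0, 3), tolerance = 1e-10)
  expect_equal(pc$leverage, 1 / 12, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pc$s_distance, 0, tolerance = 1e-10, ignore_attr = TRUE)
  on_model <- matrix(fit$mean + fit$loadings[, 1], 1)
  pm <- pca_project(fit, on_model)
  expect_equal(unname(pm$scores[1, ]), c(1, 0, 0), tolerance = 1e-8)
  expect_lt(pm$s_distance, 1e-8)
  expect_error(pca_project(fit, matrix(0, 1, 5)), "does not match")
})

test_that("PLS recovers exact single-direction responses and the OLS limit", {
  set.seed(12)
  X <- matrix(rnorm(15 * 6), 15)
  v <- rnorm(6)
  y <- X %*% v
  f1 <- fit_pls(X, y, 1)
  # single latent variable cannot be exact in general, but full rank is OLS
  ffull <- fit_pls(X, y, 6)
  expect_lt(max(abs(pls_predict(ffull, X) - y)), 1e-8)
  # noisy small full-rank system equals least squares
  yn <- y + rnorm(15)
  fit <- fit_pls(X, yn, 6)
  ols <- stats::lm.fit(cbind(1, X), yn)
  Xnew <- matrix(rnorm(4 * 6), 4)
  expect_equal(pls_predict(fit, Xnew)[, 1],
               cbind(1, Xnew) %*% ols$coefficients[, drop = FALSE],
               tolerance = 1e-6, ignore_attr = TRUE)
  # exact one-component case: X built from a single score direction
  t1 <- rnorm(15); p1 <- rnorm(6)
  X1 <- outer(t1, p1)
  y1 <- 2 * t1
  g <- fit_pls(X1, y1, 1)
  expect_lt(max(abs(pls_predict(g, X1) - y1)), 1e-8)
  expect_error(fit_pls(X, rep(1, 15), 2), "zero-variance")
})

test_that("PLS predictions centre correctly and scores are orthogonal", {
  set.seed(13)
  X <- matrix(rnorm(20 * 10), 20)
  y <- rnorm(20)
  fit <- fit_pls(X, y, 5)
  expect_equal(pls_predict(fit, matrix(fit$x_mean, 1))[1, 1],
               unname(fit$y_mean), tolerance = 1e-10)
  G <- crossprod(fit$Tmat)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  p4 <- pls_predict(fit, X, 4)
  p5 <- pls_predict(fit, X, 5)
  expect_gt(max(abs(p4 - p5)), 1e-10)
  expect_error(pls_predict(fit, X, 6), "must lie in")
})

test_that("leave-one-out CV equals brute-force refits and ranks noiseless fits", {
  set.seed(14)
  X <- matrix(rnorm(5 * 4), 5)
  y <- rnorm(5)
  cv <- loo_cv(X, y, 2)
  for (i in 1:5) {
    fit <- fit_pls(X[-i, ], y[-i], 2)
    for (a in 1:2) {
      expect_equal(cv$pred[i, a], pls_predict(fit, X[i, , drop = FALSE],
                                              a)[1, 1], tolerance = 1e-10)
    }
  }
  # noiseless single-direction data: first component nails it
  t1 <- rnorm(12); p1 <- rnorm(6)
  cv1 <- loo_cv(outer(t1, p1), 3 * t1, 2)
  expect_lt(cv1$rmsecv[1], 1e-8)
  expect_gt(cv1$one_minus_vr[1], 1 - 1e-8)
  # permutation invariance of per-sample CV predictions
  perm <- sample(5)
  cvp <- loo_cv(X[perm, ], y[perm], 2)
  expect_equal(cvp$pred, cv$pred[perm, ], tolerance = 1e-10)
  expect_error(loo_cv(X, y, 4), "A_max exceeds")
})

test_that("uninformative responses give non-positive cross-validated skill", {
  set.seed(15)
  vr <- replicate(50, {
    X <- matrix(rnorm(12 * 8), 12)
    y <- rnorm(12)
    loo_cv(X, y, 2)$one_minus_vr[2]
  })
  expect_lt(mean(vr), 0.1)
})

test_that("component selection follows the SECV tolerance rule", {
  expect_equal(select_components(c(0.9, 0.5, 0.498, 0.497), tol = 0.02), 2)
  expect_equal(select_components(c(0.3, 0.4, 0.5)), 1)
  expect_equal(select_components(0.7), 1)
  # monotone: larger tolerance never selects more components
  set.seed(16)
  for (r in 1:20) {
    curve <- cumsum(abs(rnorm(8, sd = 0.1))) |> rev()
    curve <- curve + runif(8, 0, 0.05)
    a1 <- select_components(curve, tol = 0.01)
    a2 <- select_components(curve, tol = 0.10)
    expect_lte(a2, a1)
  }
  expect_error(select_components(numeric(0)), "empty")
})
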