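# Three well-separated Gaussian classes in a modest-dimensional space.
make_gauss_classes <- function(n_per = 20, p = 12, sep = 10, seed = 30,
                               sd = 1) {
  set.seed(seed)
  centres <- rbind(Black = c(sep, rep(0, p - 1)),
                   Red = c(0, sep, rep(0, p - 2)),
                   White = c(0, 0, sep, rep(0, p - 3)))
  X <- do.call(rbind, lapply(rownames(centres), function(k)
    matrix(rnorm(n_per * p, sd = sd), n_per) +
      matrix(centres[k, ], n_per, p, byrow = TRUE)))
  list(X = X, labels = rep(rownames(centres), each = n_per))
}

test_that("dummy encoding is one-hot in declared class order", {
  m <- encode_dummy(c("Black", "Red", "White"))
  expect_equal(unname(m), rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  allb <- encode_dummy(rep("Black", 4))
  expect_equal(unname(allb[, 1]), rep(1, 4))
  expect_true(all(rowSums(m) == 1))
  expect_error(encode_dummy("Green"), "unknown label")
})

test_that("PLS-DA separates well-separated classes and respects relabeling", {
  d <- make_gauss_classes(sep = 8)
  fit <- fit_plsda(d$X, d$labels, A = 4)
  asg <- predict_plsda(fit, d$X)
  expect_true(all(asg$predicted == d$labels))
  met <- classification_metrics(d$labels, asg)
  expect_true(all(met$SE == 100) && all(met$SP == 100))
  # permuting the label alphabet permutes predictions identically
  swap <- c(Black = "White", Red = "Red", White = "Black")
  fit2 <- fit_plsda(d$X, unname(swap[d$labels]), A = 4)
  asg2 <- predict_plsda(fit2, d$X)
  expect_true(all(asg2$predicted == unname(swap[asg$predicted])))
  expect_error(fit_plsda(d$X[1:20, ], rep("Black", 20), 2), "two classes")
})

test_that("ties in the continuous prediction fall to declared order with a flag", {
  sc <- rbind(c(0.5, 0.5, 0.2), c(0.8, 0.3, 0.1))
  asg <- nircured:::argmax_assign(sc, category_levels())
  expect_equal(asg$predicted, c("Black", "Black"))
  expect_equal(asg$ambiguous, c(TRUE, FALSE))
})

test_that("SIMCA memberships follow the class envelopes", {
  d <- make_gauss_classes(n_per = 25, sep = 30, seed = 31)
  fit <- fit_simca(d$X, d$labels, per_class_A = 2)
  asg <- classify_simca(fit, d$X)
  member <- attr(asg, "membership")
  expect_gte(mean(member[cbind(seq_along(d$labels),
                               match(d$labels, colnames(member)))]), 0.95)
  expect_true(all(asg$predicted[asg$predicted != "none"] ==
                    d$labels[asg$predicted != "none"]))
  # a sample at a class centre is a member with leverage near 1/n_k
  centre <- matrix(colMeans(d$X[d$labels == "Black", ]), 1)
  proj <- pca_project(fit$sub$Black$pca, centre)
  expect_lt(proj$leverage, 3 / 25)
  ac <- classify_simca(fit, centre)
  expect_true(attr(ac, "membership")[1, "Black"])
  # a sample far off every model belongs nowhere
  far <- matrix(100, 1, ncol(d$X))
  expect_equal(classify_simca(fit, far)$predicted, "none")
})

test_that("SIMCA sensitivity approaches 100% as alpha shrinks", {
  d <- make_gauss_classes(n_per = 30, sep = 6, seed = 32, sd = 1.5)
  ses <- sapply(c(0.2, 0.05, 1e-6), function(a) {
    fit <- fit_simca(d$X, d$labels, per_class_A = 2, alpha = a,
                     leverage_multiplier = 1e6)
    member <- attr(classify_simca(fit, d$X), "membership")
    mean(member[cbind(seq_along(d$labels),
                      match(d$labels, colnames(member)))])
  })
  expect_true(all(diff(ses) >= 0))
  expect_equal(ses[3], 1)
})

test_that("LDA on PCA scores matches the Mahalanobis rule and MASS oracle", {
  skip_if_not_installed("MASS")
  d <- make_gauss_classes(n_per = 20, p = 10, sep = 3, seed = 33)
  fit <- fit_lda(d$X, d$labels, variance_threshold = 0.99)
  mine <- classify_lda(fit, d$X)
  scores <- pca_project(fit$pca, d$X, fit$A)$scores
  oracle <- MASS::lda(scores, grouping = d$labels,
                      prior = rep(1 / 3, 3))
  opred <- as.character(predict(oracle, scores)$class)
  expect_gte(mean(mine$predicted == opred), 0.99)
  # far-separated classes are classified near-perfectly
  dd <- make_gauss_classes(n_per = 20, p = 10, sep = 10, seed = 34)
  f2 <- fit_lda(dd$X, dd$labels)
  expect_gte(mean(classify_lda(f2, dd$X)$predicted == dd$labels), 0.99)
})

test_that("LDA assigns a probe at a class mean to that class", {
  d <- make_gauss_classes(n_per = 15, p = 8, sep = 4, seed = 35)
  fit <- fit_lda(d$X, d$labels)
  for (k in rownames(fit$means)) {
    centre_scores <- fit$means[k, , drop = FALSE]
    # reconstruct a spectrum-level probe from the class mean scores
    probe <- matrix(fit$pca$mean, 1) +
      centre_scores %*% t(fit$pca$loadings[, seq_len(fit$A)])
    expect_equal(classify_lda(fit, probe)$predicted, k)
  }
})
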