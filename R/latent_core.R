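#' Principal component analysis (NIPALS)
#'
#' Mean-centred PCA by the NIPALS algorithm. Components are extracted one at
#' a time by deflation, which matches how chemometric software builds
#' spectral PCA models and extends naturally to the class-wise models used
#' for SIMCA. Sign convention: within each loading vector the entry of
#' largest magnitude is positive.
#'
#' @param X Numeric matrix (samples x variables).
#' @param A Number of components, `1 <= A <= min(n - 1, p)`.
#' @param tol NIPALS convergence tolerance on the score vector.
#' @param max_iter Iteration cap per component.
#' @return An object of class `pca_model` with elements `mean`, `loadings`
#'   (p x A, orthonormal), `scores` (n x A), `explained` (variance share per
#'   component), `total_var`, `A`, `n_train`.
#' @export
fit_pca <- function(X, A, tol = 1e-9, max_iter = 500) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (A < 1) stop("A must be >= 1")
  if (A > min(n - 1, p))
    stop("A = ", A, " exceeds min(n - 1, p) = ", min(n - 1, p))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2) / (n - 1)
  scores <- matrix(0, n, A)
  loadings <- matrix(0, p, A)
  expl <- numeric(A)
  kept <- 0L
  for (a in seq_len(A)) {
    t_vec <- Xc[, which.max(colSums(Xc^2))]
    if (sum(t_vec^2) < 1e-300) break
    for (it in seq_len(max_iter)) {
      p_vec <- crossprod(Xc, t_vec) / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- Xc %*% p_vec
      if (sqrt(sum((t_new - t_vec)^2)) < tol * sqrt(sum(t_new^2))) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
    }
    if (p_vec[which.max(abs(p_vec))] < 0) {
      p_vec <- -p_vec
      t_vec <- -t_vec
    }
    kept <- a
    scores[, a] <- t_vec
    loadings[, a] <- p_vec
    expl[a] <- sum(t_vec^2) / (n - 1)
    Xc <- Xc - tcrossprod(t_vec, p_vec)
  }
  if (kept < A) {
    warning("rank deficiency: only ", kept, " components extracted")
    scores <- scores[, seq_len(kept), drop = FALSE]
    loadings <- loadings[, seq_len(kept), drop = FALSE]
    expl <- expl[seq_len(kept)]
  }
  structure(list(mean = mu, loadings = loadings, scores = scores,
                 explained = if (total_var > 0) expl / total_var else expl,
                 total_var = total_var, A = kept, n_train = n),
            class = "pca_model")
}

#' Project samples onto a PCA model
#'
#' Returns the scores, the orthogonal residual distance of each sample to
#' the model plane (the S-distance: root sum of squared reconstruction
#' residuals) and its leverage, `1/n_train + sum_a t_a^2 / (training score
#' column sum of squares)`.
#'
#' @param model A `pca_model`.
#' @param X Matrix with the model's column count.
#' @param A Number of components to use (default all).
#' @return List with `scores`, `s_distance`, `leverage`.
#' @export
pca_project <- function(model, X, A = model$A) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean))
    stop("column count ", ncol(X), " does not match model (",
         length(model$mean), ")")
  if (A > model$A) stop("A exceeds fitted components")
  L <- model$loadings[, seq_len(A), drop = FALSE]
  Xc <- sweep(X, 2, model$mean)
  scores <- Xc %*% L
  resid <- Xc - tcrossprod(scores, L)
  s_distance <- sqrt(rowSums(resid^2))
  css <- colSums(model$scores[, seq_len(A), drop = FALSE]^2)
  leverage <- 1 / model$n_train +
    rowSums(sweep(scores^2, 2, css, `/`))
  list(scores = scores, s_distance = s_distance, leverage = leverage)
}

#' Partial least squares regression (NIPALS)
#'
#' PLS on mean-centred X and Y: the non-iterative PLS1 algorithm when Y has
#' one column, iterative PLS2 otherwise (the form needed for the dummy
#' response matrix of PLS-DA). Regression coefficients are recoverable for
#' every truncation `a <= A`.
#'
#' @param X Predictor matrix (n x p).
#' @param Y Response vector or matrix (n x m).
#' @param A Number of latent variables, `1 <= A <= min(n - 1, p)`.
#' @param tol,max_iter PLS2 inner-loop convergence controls.
#' @return An object of class `pls_model` with weights `W`, X loadings `P`,
#'   Y loadings `C` (m x A, inner-relation scaled), scores `Tmat`, centres
#'   `x_mean`, `y_mean`, and `A`.
#' @export
fit_pls <- function(X, Y, A, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (n < 3) stop("need at least 3 samples")
  if (nrow(Y) != n) stop("X and Y row counts differ")
  if (A < 1 || A > min(n - 1, p))
    stop("A must lie in [1, min(n - 1, p)]")
  y_sd <- apply(Y, 2, stats::sd)
  if (any(y_sd == 0)) stop("zero-variance response column")
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  E <- sweep(X, 2, x_mean); F_ <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  C <- matrix(0, m, A); Tmat <- matrix(0, n, A)
  for (a in seq_len(A)) {
    if (m == 1) {
      w <- crossprod(E, F_)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) { A <- a - 1L; break }
      w <- w / nw
      t_vec <- E %*% w
    } else {
      u <- F_[, which.max(colSums(F_^2))]
      t_vec <- NULL
      for (it in seq_len(max_iter)) {
        w <- crossprod(E, u)[, 1]
        nw <- sqrt(sum(w^2))
        if (nw < 1e-300) break
        w <- w / nw
        t_new <- E %*% w
        q <- crossprod(F_, t_new)[, 1] / sum(t_new^2)
        u <- F_ %*% q / sum(q^2)
        if (!is.null(t_vec) &&
            sqrt(sum((t_new - t_vec)^2)) < tol * sqrt(sum(t_new^2))) {
          t_vec <- t_new
          break
        }
        t_vec <- t_new
      }
      if (is.null(t_vec) || sum(t_vec^2) < 1e-300) { A <- a - 1L; break }
    }
    tt <- sum(t_vec^2)
    p_vec <- crossprod(E, t_vec)[, 1] / tt
    c_vec <- crossprod(F_, t_vec)[, 1] / tt
    W[, a] <- w; P[, a] <- p_vec; C[, a] <- c_vec; Tmat[, a] <- t_vec
    E <- E - tcrossprod(t_vec, p_vec)
    F_ <- F_ - tcrossprod(t_vec, c_vec)
  }
  if (A < 1) stop("no latent variables could be extracted")
  keep <- seq_len(A)
  structure(list(W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
                 C = C[, keep, drop = FALSE], Tmat = Tmat[, keep, drop = FALSE],
                 x_mean = x_mean, y_mean = y_mean, A = A),
            class = "pls_model")
}

#' Regression coefficients of a PLS model
#'
#' `B_a = W (P'W)^-1 C'` using the first `a` latent variables, on centred
#' scales.
#'
#' @param model A `pls_model`.
#' @param a Number of latent variables to use.
#' @return p x m coefficient matrix.
#' @export
pls_coefficients <- function(model, a = model$A) {
  if (a < 1 || a > model$A) stop("a must lie in [1, ", model$A, "]")
  idx <- seq_len(a)
  W <- model$W[, idx, drop = FALSE]
  P <- model$P[, idx, drop = FALSE]
  C <- model$C[, idx, drop = FALSE]
  ## P'W is unit upper triangular in exact arithmetic; solve is cheap
  W %*% solve(crossprod(P, W), t(C))
}

#' Predict from a PLS model
#'
#' @param model A `pls_model`.
#' @param X New predictor matrix.
#' @param a Number of latent variables (default all fitted).
#' @return n x m matrix of predictions on the original response scale.
#' @export
pls_predict <- function(model, X, a = model$A) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) stop("dimension mismatch")
  B <- pls_coefficients(model, a)
  sweep(sweep(X, 2, model$x_mean) %*% B, 2, model$y_mean, `+`)
}

#' Leave-one-out cross-validation of a PLS fit
#'
#' For each sample the model (including centring) is refit on the remaining
#' n - 1 samples and the held-out sample predicted with every latent
#' variable count up to `A_max`. Returns the error curves used for latent
#' variable selection: RMSECV(a), the cross-validated coefficient of
#' determination 1-VR(a), and SECV(a), the bias-corrected standard deviation
#' of the cross-validation residuals.
#'
#' @param X Predictor matrix.
#' @param Y Single response vector/column.
#' @param A_max Largest latent variable count, at most n - 2.
#' @param fitter Model fitter `function(X, Y, A)` (default [fit_pls()]).
#' @param predictor Predictor `function(model, X, a)` (default
#'   [pls_predict()]).
#' @return An object of class `cv_result` with `pred` (n x A_max CV
#'   predictions), `rmsecv`, `one_minus_vr`, `secv`.
#' @export
loo_cv <- function(X, Y, A_max, fitter = fit_pls, predictor = pls_predict) {
  X <- as.matrix(X); y <- as.numeric(as.matrix(Y)[, 1])
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  if (A_max > n - 2) stop("A_max exceeds n - 2")
  pred <- matrix(NA_real_, n, A_max)
  for (i in seq_len(n)) {
    fit <- fitter(X[-i, , drop = FALSE], y[-i], A_max)
    for (a in seq_len(fit$A)) {
      pred[i, a] <- predictor(fit, X[i, , drop = FALSE], a)[1, 1]
    }
    if (fit$A < A_max)
      pred[i, (fit$A + 1):A_max] <- pred[i, fit$A]
  }
  resid <- pred - y
  rmsecv <- sqrt(colMeans(resid^2))
  sst <- sum((y - mean(y))^2)
  one_minus_vr <- 1 - colSums(resid^2) / sst
  secv <- apply(resid, 2, function(e) sqrt(sum((e - mean(e))^2) / (n - 1)))
  structure(list(pred = pred, rmsecv = rmsecv, one_minus_vr = one_minus_vr,
                 secv = secv, y = y),
            class = "cv_result")
}

#' Select the number of latent variables
#'
#' The working rule for "the error no longer decreases substantially": the
#' smallest a whose SECV is within `tol` (relative, default 2%) of the curve
#' minimum.
#'
#' @param cv A `cv_result`, or a numeric SECV curve.
#' @param tol Relative tolerance.
#' @return The selected component count.
#' @export
select_components <- function(cv, tol = 0.02) {
  curve <- if (inherits(cv, "cv_result")) cv$secv else as.numeric(cv)
  if (!length(curve)) stop("empty curve")
  which(curve <= (1 + tol) * min(curve))[1]
}
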