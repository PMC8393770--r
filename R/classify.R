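#' One-hot dummy matrix for class labels
#'
#' Each sample's row carries 1 in its class column and 0 elsewhere — the
#' response matrix that turns PLS regression into PLS-DA.
#'
#' @param labels Character vector of class labels.
#' @param classes Declared class order (default the Black/Red/White
#'   categories).
#' @return n x K 0/1 matrix with `classes` as column names.
#' @export
encode_dummy <- function(labels, classes = category_levels()) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}

## Shared container for classifier outputs.
class_assignment <- function(predicted, scores, ambiguous, classes) {
  structure(list(predicted = predicted, scores = scores,
                 ambiguous = ambiguous, classes = classes),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat("<class_assignment>", length(x$predicted), "samples over classes:",
      paste(x$classes, collapse = ", "), "\n")
  print(table(predicted = x$predicted))
  invisible(x)
}

## argmax with declared-order tie-break; ties set the ambiguity flag.
argmax_assign <- function(scores, classes) {
  pred <- character(nrow(scores))
  amb <- logical(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    mx <- max(scores[i, ])
    hits <- which(scores[i, ] == mx)
    pred[i] <- classes[hits[1]]
    amb[i] <- length(hits) > 1
  }
  class_assignment(pred, scores, amb, classes)
}

#' PLS-DA classifier
#'
#' Fits one PLS2 model of the spectra against the one-hot dummy matrix;
#' prediction assigns each sample to the class with the largest continuous
#' predicted response (ties broken by declared class order and flagged).
#'
#' @param X Predictor matrix.
#' @param labels Class labels.
#' @param A Number of latent variables.
#' @param classes Declared class order.
#' @return An object of class `plsda_model`.
#' @export
fit_plsda <- function(X, labels, A, classes = category_levels()) {
  labels <- as.character(labels)
  present <- intersect(classes, unique(labels))
  if (length(present) < 2) stop("need at least two classes in training data")
  Y <- encode_dummy(labels, classes = present)
  pls <- fit_pls(X, Y, A)
  structure(list(pls = pls, classes = present, A = A),
            class = "plsda_model")
}

#' @rdname fit_plsda
#' @param model A `plsda_model`.
#' @param a Latent variables to use for prediction (default all).
#' @return `predict_plsda`: a `class_assignment`; `scores` holds the
#'   continuous per-class predictions.
#' @export
predict_plsda <- function(model, X, a = model$A) {
  yhat <- pls_predict(model$pls, X, a)
  colnames(yhat) <- model$classes
  argmax_assign(yhat, model$classes)
}

#' SIMCA class modelling
#'
#' Fits one PCA model per class. A sample is a member of a class when its
#' orthogonal residual distance is below the class critical S-distance — a
#' moment-calibrated chi-square limit at level `alpha` on the squared
#' residual, with degrees of freedom estimated from the training residuals —
#' and its leverage does not exceed `leverage_multiplier` times the
#' class-model average leverage. Samples inside several class
#' envelopes are resolved to the class with the smallest combined
#' normalized distance `sqrt((s/s_crit)^2 + (h/h_limit)^2)`; samples inside
#' none get `"none"`.
#'
#' @param X Predictor matrix.
#' @param labels Class labels.
#' @param per_class_A Named (or recycled) vector of PCs per class.
#' @param alpha Level of the residual-distance test (default 0.01; smaller
#'   values widen every class envelope, raising sensitivity at the cost of
#'   specificity).
#' @param leverage_multiplier Leverage limit multiplier (default 3).
#' @param classes Declared class order.
#' @return An object of class `simca_model`.
#' @export
fit_simca <- function(X, labels, per_class_A, alpha = 0.01,
                      leverage_multiplier = 3, classes = category_levels()) {
  labels <- as.character(labels)
  present <- intersect(classes, unique(labels))
  if (length(per_class_A) == 1) per_class_A <- rep(per_class_A, length(present))
  if (is.null(names(per_class_A))) names(per_class_A) <- present
  X <- as.matrix(X)
  p <- ncol(X)
  sub <- list()
  for (k in present) {
    idx <- which(labels == k)
    A_k <- per_class_A[[k]]
    if (length(idx) < A_k + 2)
      stop("class ", k, " has ", length(idx), " samples; needs >= ", A_k + 2)
    pc <- fit_pca(X[idx, , drop = FALSE], A_k)
    proj <- pca_project(pc, X[idx, , drop = FALSE])
    ## critical S-distance: spectral residuals are strongly correlated
    ## across wavelengths, so the residual sum of squares behaves as a
    ## scaled chi-square with few effective degrees of freedom; estimate
    ## them from the training moments (standard data-driven SIMCA
    ## calibration) rather than assuming p - A independent channels
    v <- proj$s_distance^2
    v0 <- mean(v)
    nh <- max(1, min(250, 2 * (v0 / stats::sd(v))^2))
    s_crit <- sqrt(v0 * stats::qchisq(1 - alpha, nh) / nh)
    h_limit <- leverage_multiplier *
      average_leverage(length(idx), A_k, "standard")
    sub[[k]] <- list(pca = pc, A = A_k, s_crit = s_crit, h_limit = h_limit)
  }
  structure(list(classes = present, sub = sub, alpha = alpha),
            class = "simca_model")
}

#' @rdname fit_simca
#' @param model A `simca_model`.
#' @return `classify_simca`: a `class_assignment` whose `scores` are the
#'   combined normalized distances (smaller = closer); attribute
#'   `"membership"` carries the per-class logical membership matrix.
#' @export
classify_simca <- function(model, X) {
  X <- as.matrix(X)
  K <- length(model$classes)
  n <- nrow(X)
  dist <- matrix(NA_real_, n, K, dimnames = list(NULL, model$classes))
  member <- matrix(FALSE, n, K, dimnames = list(NULL, model$classes))
  for (k in model$classes) {
    sm <- model$sub[[k]]
    proj <- pca_project(sm$pca, X)
    member[, k] <- proj$s_distance <= sm$s_crit & proj$leverage <= sm$h_limit
    dist[, k] <- sqrt((proj$s_distance / sm$s_crit)^2 +
                        (proj$leverage / sm$h_limit)^2)
  }
  pred <- character(n)
  amb <- logical(n)
  for (i in seq_len(n)) {
    hits <- which(member[i, ])
    if (length(hits) == 0) {
      pred[i] <- "none"
    } else {
      pred[i] <- model$classes[hits[which.min(dist[i, hits])]]
      amb[i] <- length(hits) > 1
    }
  }
  out <- class_assignment(pred, -dist, amb, model$classes)
  attr(out, "membership") <- member
  out
}

#' Linear discriminant analysis on PCA scores
#'
#' Compresses the spectra to the smallest number of principal components
#' whose cumulative explained variance reaches `variance_threshold` (capped
#' at n - K - 1), then classifies by minimum Mahalanobis distance to the
#' class mean scores under the pooled within-class covariance, with equal
#' priors.
#'
#' @param X Predictor matrix.
#' @param labels Class labels.
#' @param variance_threshold Cumulative explained-variance target for the
#'   PCA compression (default 0.99).
#' @param classes Declared class order.
#' @return An object of class `lda_model`.
#' @export
fit_lda <- function(X, labels, variance_threshold = 0.99,
                    classes = category_levels()) {
  labels <- as.character(labels)
  present <- intersect(classes, unique(labels))
  if (length(present) < 2) stop("need at least two classes")
  X <- as.matrix(X)
  n <- nrow(X); K <- length(present)
  cap <- min(n - K - 1, n - 1, ncol(X))
  ## grow the PCA until the variance target is reached (or the cap)
  A_fit <- min(cap, 20L)
  repeat {
    pc <- fit_pca(X, A_fit)
    cum <- cumsum(pc$explained)
    if (max(cum) >= variance_threshold || A_fit >= cap || pc$A < A_fit) break
    A_fit <- min(cap, A_fit * 2L)
  }
  A <- which(cum >= variance_threshold)[1]
  if (is.na(A)) A <- pc$A
  repeat {
    scores <- pc$scores[, seq_len(A), drop = FALSE]
    means <- matrix(0, K, A, dimnames = list(present, NULL))
    Sw <- matrix(0, A, A)
    for (k in present) {
      idx <- which(labels == k)
      means[k, ] <- colMeans(scores[idx, , drop = FALSE])
      d <- sweep(scores[idx, , drop = FALSE], 2, means[k, ])
      Sw <- Sw + crossprod(d)
    }
    Sw <- Sw / (n - K)
    ok <- tryCatch({ chol(Sw); TRUE }, error = function(e) FALSE)
    if (ok) break
    if (A <= 1) stop("pooled covariance singular even at A = 1")
    warning("singular pooled covariance; reducing A to ", A - 1)
    A <- A - 1
  }
  structure(list(pca = pc, A = A, means = means, Sw = Sw, classes = present),
            class = "lda_model")
}

#' @rdname fit_lda
#' @param model An `lda_model`.
#' @return `classify_lda`: a `class_assignment`; `scores` are negated
#'   Mahalanobis distances (larger = closer).
#' @export
classify_lda <- function(model, X) {
  proj <- pca_project(model$pca, as.matrix(X), model$A)
  t_new <- proj$scores
  Sinv <- chol2inv(chol(model$Sw))
  K <- length(model$classes)
  d2 <- matrix(0, nrow(t_new), K, dimnames = list(NULL, model$classes))
  for (j in seq_len(K)) {
    diff <- sweep(t_new, 2, model$means[j, ])
    d2[, j] <- rowSums((diff %*% Sinv) * diff)
  }
  argmax_assign(-d2, model$classes)
}
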