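#' Outlier screening policy
#'
#' Parameters for PCA-based spectral outlier detection: samples are flagged
#' when their standardized residual distance exceeds
#' `residual_z_threshold`, or when their leverage exceeds
#' `leverage_multiplier` times the average leverage.
#'
#' @param residual_z_threshold Cut-off on the S-distance divided by the SD
#'   of S-distances (default 2).
#' @param leverage_multiplier Multiple of the average leverage (default 3).
#' @param leverage_formula `"standard"` uses the average hat leverage
#'   (1 + A)/n; `"as_printed"` uses the published variant 1/(n + A/n),
#'   retained verbatim for reproducibility.
#' @param A Number of PCs for screening; `NULL` picks the smallest count
#'   covering 95% of variance, capped at 10.
#' @param max_rounds Maximum removal rounds for the iterative screen.
#' @return An object of class `outlier_policy`.
#' @export
outlier_policy <- function(residual_z_threshold = 2, leverage_multiplier = 3,
                           leverage_formula = c("standard", "as_printed"),
                           A = NULL, max_rounds = 5) {
  stopifnot(residual_z_threshold > 0, leverage_multiplier > 0, max_rounds >= 1)
  structure(list(residual_z_threshold = residual_z_threshold,
                 leverage_multiplier = leverage_multiplier,
                 leverage_formula = match.arg(leverage_formula),
                 A = A, max_rounds = max_rounds),
            class = "outlier_policy")
}

#' Average leverage of a PCA model
#'
#' `"standard"` is the mean hat leverage of a centred A-component score
#' model, (1 + A)/n. `"as_printed"` is the published alternative
#' 1/(n + A/n), numerically close to 1/n.
#'
#' @param n Training set size (>= 2).
#' @param A Number of principal components (>= 1).
#' @param formula `"standard"` or `"as_printed"`.
#' @return The average leverage.
#' @export
average_leverage <- function(n, A, formula = c("standard", "as_printed")) {
  if (n < 2) stop("n must be >= 2")
  if (A < 1) stop("A must be >= 1")
  switch(match.arg(formula),
         standard = (1 + A) / n,
         as_printed = 1 / (n + A / n))
}

## PCs covering cover (default 95%) of variance, capped.
screening_components <- function(X, cover = 0.95, cap = 10) {
  A_max <- min(nrow(X) - 1, ncol(X), cap)
  pc <- fit_pca(X, A_max)
  cum <- cumsum(pc$explained)
  A <- which(cum >= cover)[1]
  if (is.na(A)) A <- pc$A
  list(model = pc, A = max(1L, A))
}

#' Flag spectral outliers (single round)
#'
#' Applies the two removal rules to one fitted PCA model: (1) centred
#' z-score of the residual S-distance above the
#' threshold; (2) leverage above the multiplier times the average leverage.
#'
#' @param model A `pca_model` fitted on `X`.
#' @param X The matrix the model was fitted on.
#' @param policy An [outlier_policy()].
#' @param ids Optional sample identifiers (defaults to rownames or indices).
#' @return Data frame `sample_id`, `reason` (residual/leverage/both) for
#'   flagged samples; attribute `"scores"` carries the diagnostics.
#' @export
flag_outliers <- function(model, X, policy = outlier_policy(), ids = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("need at least 3 samples")
  if (is.null(ids)) {
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  }
  A <- if (is.null(policy$A)) model$A else min(policy$A, model$A)
  proj <- pca_project(model, X, A)
  sd_s <- stats::sd(proj$s_distance)
  ## "residuals higher than 2" as a 2-sigma rule on the S-distance
  ## distribution: centred z-score of each sample's residual distance
  z <- if (sd_s > 0) (proj$s_distance - mean(proj$s_distance)) / sd_s
       else rep(0, nrow(X))
  h_bar <- average_leverage(model$n_train, A, policy$leverage_formula)
  res_flag <- z > policy$residual_z_threshold
  lev_flag <- proj$leverage > policy$leverage_multiplier * h_bar
  flagged <- res_flag | lev_flag
  reason <- ifelse(res_flag & lev_flag, "both",
                   ifelse(res_flag, "residual", "leverage"))
  out <- data.frame(sample_id = ids[flagged], reason = reason[flagged],
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- data.frame(sample_id = ids, residual_z = z,
                                    leverage = proj$leverage,
                                    stringsAsFactors = FALSE)
  out
}

#' Iterative PCA outlier removal
#'
#' Alternates PCA refits and removal rounds until no sample is flagged or
#' `max_rounds` is reached. The per-round flags and the retained ids are
#' returned alongside the cleaned matrix.
#'
#' @param X Sample-by-variable matrix (n >= 10).
#' @param policy An [outlier_policy()].
#' @param ids Optional sample identifiers.
#' @return List with `retained` (matrix), `retained_ids`, and `report`
#'   (data frame `sample_id`, `round`, `reason`).
#' @export
iterative_outlier_removal <- function(X, policy = outlier_policy(),
                                      ids = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("need at least 10 samples")
  if (is.null(ids)) {
    ids <- rownames(X)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  }
  report <- data.frame(sample_id = character(), round = integer(),
                       reason = character(), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(X))
  for (round in seq_len(policy$max_rounds)) {
    Xr <- X[keep, , drop = FALSE]
    scr <- if (is.null(policy$A)) screening_components(Xr) else
      list(model = fit_pca(Xr, min(policy$A, nrow(Xr) - 1, ncol(Xr))),
           A = policy$A)
    pol <- policy
    pol$A <- scr$A
    flags <- flag_outliers(scr$model, Xr, pol, ids = ids[keep])
    if (nrow(flags) == 0) break
    if (sum(keep) - nrow(flags) < 10)
      stop("removal would leave fewer than 10 samples")
    report <- rbind(report,
                    data.frame(sample_id = flags$sample_id, round = round,
                               reason = flags$reason,
                               stringsAsFactors = FALSE))
    keep[match(flags$sample_id, ids)] <- FALSE
  }
  list(retained = X[keep, , drop = FALSE], retained_ids = ids[keep],
       report = report)
}
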