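#' Fit a PLSR model for one quality trait
#'
#' Runs the full per-trait quantitative pipeline on a calibration set:
#' pre-treatment, PCA-based spectral outlier screening (which is why the
#' retained n differs between traits when screening follows the
#' trait-specific pre-treatment), leave-one-out cross-validation over
#' 1..A_max latent variables, selection of the working latent variable
#' count from the SECV curve, and a final fit at that count.
#'
#' @param cal Calibration [spectra_set()] carrying trait values.
#' @param trait Trait column name (see [trait_names()]).
#' @param preset Pre-treatment pipeline or preset name.
#' @param A_max Largest latent variable count examined (default 10).
#' @param policy [outlier_policy()] for the spectral screen; `NULL` skips
#'   screening.
#' @param tol Relative SECV tolerance for [select_components()].
#' @return List of class `trait_model` with the fitted `pls_model`, the
#'   selected `A`, the `cv_result`, the retained sample ids and a
#'   `result` row (trait, pre-treatment label, LV, n, 1-VR, RMSECV, SECV).
#' @export
fit_trait_model <- function(cal, trait, preset = "SNV-DE SG 1,4,4,1",
                            A_max = 10, policy = outlier_policy(),
                            tol = 0.02) {
  if (is.null(cal$traits) || !trait %in% names(cal$traits))
    stop("trait ", trait, " absent from calibration set")
  y_all <- cal$traits[[trait]]
  if (anyNA(y_all)) stop("missing trait values for ", trait)
  if (stats::sd(y_all) == 0) stop("degenerate (constant) trait ", trait)
  label <- if (is.character(preset)) preset else "custom"
  pre <- apply_pipeline(cal, preset)
  if (!is.null(policy)) {
    scr <- iterative_outlier_removal(pre$spectra, policy,
                                     ids = pre$meta$sample_id)
    keep_ids <- scr$retained_ids
    report <- scr$report
  } else {
    keep_ids <- pre$meta$sample_id
    report <- NULL
  }
  kept <- subset_samples(pre, keep_ids)
  X <- kept$spectra
  y <- kept$traits[[trait]]
  n <- nrow(X)
  A_max <- min(A_max, n - 2, ncol(X))
  cv <- loo_cv(X, y, A_max)
  A <- select_components(cv, tol = tol)
  fit <- fit_pls(X, y, A)
  res <- data.frame(trait = trait, pretreatment = label, LV = A, n = n,
                    one_minus_vr = cv$one_minus_vr[A], rmsecv = cv$rmsecv[A],
                    secv = cv$secv[A], stringsAsFactors = FALSE)
  structure(list(pls = fit, A = A, cv = cv, trait = trait,
                 pretreatment = preset, pretreatment_label = label,
                 retained_ids = keep_ids, outlier_report = report,
                 result = res),
            class = "trait_model")
}

#' External validation of a trait model
#'
#' Pre-treats the validation set with the calibration pipeline, predicts the
#' trait and reports R2v (squared Pearson correlation by default, or
#' 1 - SSE/SST when `r2_method = "explained"`), RMSEV, and the RPDv and
#' RERv indices computed from the validation set's own SD and range.
#'
#' @param model A `trait_model` from [fit_trait_model()].
#' @param val Validation [spectra_set()] with trait values.
#' @param r2_method `"correlation"` (default) or `"explained"`.
#' @return Data frame row `trait`, `n_val`, `r2_v`, `rmsev`, `rpd_v`,
#'   `rer_v`.
#' @export
external_validate <- function(model, val, r2_method = c("correlation",
                                                        "explained")) {
  r2_method <- match.arg(r2_method)
  if (is.null(val$traits) || !model$trait %in% names(val$traits))
    stop("trait ", model$trait, " absent from validation set")
  pre <- apply_pipeline(val, model$pretreatment)
  y <- pre$traits[[model$trait]]
  yhat <- pls_predict(model$pls, pre$spectra, model$A)[, 1]
  n <- length(y)
  rmsev <- sqrt(mean((y - yhat)^2))
  r2 <- if (r2_method == "correlation") {
    if (stats::sd(yhat) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(y, yhat)^2
  } else {
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
  idx <- rpd_rer(stats::sd(y), min(y), max(y), rmsev)
  data.frame(trait = model$trait, n_val = n, r2_v = r2, rmsev = rmsev,
             rpd_v = idx[["RPD"]], rer_v = idx[["RER"]],
             stringsAsFactors = FALSE)
}

#' Quantitative pipeline over all traits
#'
#' Applies [fit_trait_model()] and [external_validate()] to every trait in
#' `trait_presets`, collecting one result row per trait in the layout of the
#' quantitative report table.
#'
#' @param cal,val Calibration and validation [spectra_set()]s with traits.
#' @param trait_presets Named character vector mapping trait -> pre-treatment
#'   preset; default: each trait's reported best pre-treatment.
#' @param A_max,policy,tol Passed to [fit_trait_model()].
#' @return List with `table` (combined data frame) and `models`.
#' @export
quantify_all <- function(cal, val, trait_presets = default_trait_presets(),
                         A_max = 10, policy = outlier_policy(), tol = 0.02) {
  rows <- list(); models <- list()
  for (tr in names(trait_presets)) {
    m <- fit_trait_model(cal, tr, trait_presets[[tr]], A_max = A_max,
                         policy = policy, tol = tol)
    v <- external_validate(m, val)
    rows[[tr]] <- cbind(m$result, v[, c("n_val", "r2_v", "rmsev",
                                        "rpd_v", "rer_v")])
    models[[tr]] <- m
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       models = models)
}

#' Reported best pre-treatment per trait
#'
#' @return Named character vector trait -> preset name, from the shipped
#'   reference performance table.
#' @export
default_trait_presets <- function() {
  perf <- reference_model_performance()
  stats::setNames(perf$pretreatment, perf$trait)
}
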