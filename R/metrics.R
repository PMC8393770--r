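#' One-vs-rest confusion counts
#'
#' Counts true/false positives and negatives for one class against the
#' rest. A `"none"` prediction (possible under SIMCA) counts as a negative
#' prediction for every class.
#'
#' For a class-modelling result carrying a membership matrix (SIMCA), the
#' positive prediction for class k is membership in the class-k envelope —
#' a sample may then count as positive for several classes, which is what
#' lets every class show near-perfect sensitivity while specificity stays
#' poor when the class envelopes overlap.
#'
#' @param truth Character vector of true labels.
#' @param assignment A `class_assignment` or character vector of predicted
#'   labels.
#' @param class The class evaluated as "positive".
#' @return Named list `TP`, `FN`, `TN`, `FP`.
#' @export
build_confusion <- function(truth, assignment, class) {
  member <- if (inherits(assignment, "class_assignment"))
    attr(assignment, "membership") else NULL
  pred <- if (inherits(assignment, "class_assignment"))
    assignment$predicted else as.character(assignment)
  truth <- as.character(truth)
  if (length(truth) != length(pred))
    stop("truth and predictions have different lengths")
  pos <- truth == class
  hit <- if (!is.null(member)) member[, class] else pred == class
  list(TP = sum(pos & hit), FN = sum(pos & !hit),
       TN = sum(!pos & !hit), FP = sum(!pos & hit))
}

#' Sensitivity and specificity from confusion counts
#'
#' SE = TP/(TP + FN) and SP = TN/(TN + FP), as percentages. An empty
#' denominator yields `NA` with a warning.
#'
#' @param cm Confusion counts as returned by [build_confusion()].
#' @return Named numeric vector `c(SE = , SP = )` in percent.
#' @export
confusion_metrics <- function(cm) {
  se <- if (cm$TP + cm$FN > 0) 100 * cm$TP / (cm$TP + cm$FN) else {
    warning("no positive samples; SE undefined"); NA_real_ }
  sp <- if (cm$TN + cm$FP > 0) 100 * cm$TN / (cm$TN + cm$FP) else {
    warning("no negative samples; SP undefined"); NA_real_ }
  c(SE = se, SP = sp)
}

#' Per-class SE/SP table for a classification result
#'
#' @param truth True labels.
#' @param assignment A `class_assignment`.
#' @param classes Classes to evaluate (default those of the assignment).
#' @return Data frame `category`, `n`, `SE`, `SP`.
#' @export
classification_metrics <- function(truth, assignment,
                                   classes = NULL) {
  if (is.null(classes)) classes <- assignment$classes
  rows <- lapply(classes, function(k) {
    cm <- build_confusion(truth, assignment, k)
    ms <- confusion_metrics(cm)
    data.frame(category = k, n = cm$TP + cm$FN, SE = ms["SE"], SP = ms["SP"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' RPD and RER indices
#'
#' Residual prediction deviation RPD = SD/RMSE and range error ratio
#' RER = (Ymax - Ymin)/RMSE. RPD around 2-2.5 indicates approximate
#' quantitative prediction; RER above 10 indicates good practical utility.
#'
#' @param sd Standard deviation of the reference values.
#' @param y_min,y_max Reference range.
#' @param rmse Prediction error (must be > 0 for finite indices).
#' @return Named numeric vector `c(RPD = , RER = )`; `NA` when `rmse` is 0.
#' @export
rpd_rer <- function(sd, y_min, y_max, rmse) {
  stopifnot(y_max >= y_min)
  if (rmse <= 0) return(c(RPD = NA_real_, RER = NA_real_))
  c(RPD = sd / rmse, RER = (y_max - y_min) / rmse)
}

## 3-decimal statistic / 2-decimal percentage formatting used in rendered
## tables; undefined values print as the literal "NA".
fmt_stat <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 3))
fmt_pct  <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 2))

#' Render classification results as a TSV table
#'
#' One row per class with pre-treatment, model size, and calibration /
#' validation n, SE and SP — the layout used for reporting discriminant
#' models. Percentages are printed with 2 decimals.
#'
#' @param results Data frame with columns `category`, `pretreatment`,
#'   `components`, `n_cal`, `SE_cal`, `SP_cal`, `n_val`, `SE_val`, `SP_val`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
render_classification_table <- function(results, path) {
  out <- data.frame(
    category = results$category,
    pretreatment = results$pretreatment,
    components = results$components,
    n_cal = results$n_cal,
    SE_cal = fmt_pct(results$SE_cal),
    SP_cal = fmt_pct(results$SP_cal),
    n_val = results$n_val,
    SE_val = fmt_pct(results$SE_val),
    SP_val = fmt_pct(results$SP_val),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render quantitative (PLSR) results as a TSV table
#'
#' One row per trait: pre-treatment, latent variables, retained n,
#' calibration 1-VR and RMSECV, and validation R2v, RMSEV, RPDv, RERv.
#' Statistics are printed with 3 decimals; undefined cells as "NA".
#'
#' @param results Data frame with columns `trait`, `pretreatment`, `LV`,
#'   `n`, `one_minus_vr`, `rmsecv`, `r2_v`, `rmsev`, `rpd_v`, `rer_v`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
render_quantitative_table <- function(results, path) {
  out <- data.frame(
    trait = results$trait,
    pretreatment = results$pretreatment,
    LV = results$LV,
    n = results$n,
    one_minus_vr = fmt_stat(results$one_minus_vr),
    RMSECV = fmt_stat(results$rmsecv),
    R2_v = fmt_stat(results$r2_v),
    RMSEV = fmt_stat(results$rmsev),
    RPD_v = fmt_stat(results$rpd_v),
    RER_v = fmt_stat(results$rer_v),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Descriptive statistics of trait values
#'
#' @param traits Trait data frame (with `sample_id` column).
#' @return Data frame `trait`, `n`, `mean`, `min`, `max`, `sd`.
#' @export
describe_traits <- function(traits) {
  cols <- setdiff(names(traits), "sample_id")
  rows <- lapply(cols, function(cl) {
    v <- traits[[cl]]
    data.frame(trait = cl, n = sum(!is.na(v)), mean = mean(v, na.rm = TRUE),
               min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
               sd = stats::sd(v, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
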