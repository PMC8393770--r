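#' Leave-one-out cross-validation of a PLS-DA model
#'
#' Refits the PLS2 dummy-response model with each sample held out and
#' returns the per-class cross-validated 1-VR and RMSECV at the fitted
#' latent variable count, together with the CV class assignments.
#'
#' @param X Predictor matrix.
#' @param labels Class labels.
#' @param A Latent variables.
#' @param classes Declared class order.
#' @return List with `one_minus_vr`, `rmsecv` (named per class) and
#'   `assignment` (a `class_assignment` of CV predictions).
#' @export
plsda_cv <- function(X, labels, A, classes = category_levels()) {
  labels <- as.character(labels)
  present <- intersect(classes, unique(labels))
  Y <- encode_dummy(labels, classes = present)
  X <- as.matrix(X)
  n <- nrow(X)
  pred <- matrix(NA_real_, n, ncol(Y), dimnames = list(NULL, present))
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                   min(A, n - 2))
    pred[i, ] <- pls_predict(fit, X[i, , drop = FALSE],
                             min(A, fit$A))[1, ]
  }
  resid <- pred - Y
  rmsecv <- sqrt(colMeans(resid^2))
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  one_minus_vr <- 1 - colSums(resid^2) / sst
  list(one_minus_vr = one_minus_vr, rmsecv = rmsecv,
       assignment = argmax_assign(pred, present))
}

## SE/SP rows for one fitted classifier on cal and val sets.
classifier_rows <- function(truth_cal, asg_cal, truth_val, asg_val,
                            pretreatment, components) {
  mc <- classification_metrics(truth_cal, asg_cal)
  mv <- classification_metrics(truth_val, asg_val)
  data.frame(category = mc$category, pretreatment = pretreatment,
             components = components,
             n_cal = mc$n, SE_cal = mc$SE, SP_cal = mc$SP,
             n_val = mv$n, SE_val = mv$SE, SP_val = mv$SP,
             stringsAsFactors = FALSE)
}

#' Run the three classification approaches
#'
#' Pre-treats the data per method (PLS-DA on the derivative preset, SIMCA on
#' plain absorbance, LDA on SNV-detrend by default, matching the best
#' reported treatment for each approach), fits on the calibration subset and
#' evaluates SE/SP on both subsets.
#'
#' @param set A split [spectra_set()] (meta$set filled with cal/val).
#' @param presets Named list of pre-treatment presets per method.
#' @param plsda_A Latent variables for PLS-DA.
#' @param simca_A Per-class PCs for SIMCA.
#' @param alpha SIMCA residual-test level.
#' @param simca_leverage SIMCA leverage-limit multiplier.
#' @param variance_threshold LDA compression target.
#' @param cv Also compute PLS-DA leave-one-out CV statistics.
#' @return Named list of per-method result tables (`plsda`, `simca`, `lda`)
#'   plus `models` and, when `cv = TRUE`, `plsda_cv`.
#' @export
classify_all <- function(set,
                         presets = list(plsda = "SNV-DE SG 1,4,4,1",
                                        simca = "abs",
                                        lda = "SNV-DE"),
                         plsda_A = 8,
                         simca_A = c(Black = 2, Red = 1, White = 2),
                         alpha = 0.01, simca_leverage = 3,
                         variance_threshold = 0.99,
                         cv = FALSE) {
  out <- list(models = list())
  for (method in c("plsda", "simca", "lda")) {
    pre <- apply_pipeline(set, presets[[method]])
    cal <- calibration_set(pre); val <- validation_set(pre)
    if (method == "plsda") {
      m <- fit_plsda(cal$spectra, cal$meta$category, plsda_A)
      asg_c <- predict_plsda(m, cal$spectra)
      asg_v <- predict_plsda(m, val$spectra)
      comp <- plsda_A
      if (cv) {
        out$plsda_cv <- plsda_cv(cal$spectra, cal$meta$category, plsda_A)
      }
    } else if (method == "simca") {
      m <- fit_simca(cal$spectra, cal$meta$category, simca_A, alpha = alpha,
                     leverage_multiplier = simca_leverage)
      asg_c <- classify_simca(m, cal$spectra)
      asg_v <- classify_simca(m, val$spectra)
      comp <- paste(simca_A, collapse = "/")
    } else {
      m <- fit_lda(cal$spectra, cal$meta$category,
                   variance_threshold = variance_threshold)
      asg_c <- classify_lda(m, cal$spectra)
      asg_v <- classify_lda(m, val$spectra)
      comp <- m$A
    }
    out[[method]] <- classifier_rows(cal$meta$category, asg_c,
                                     val$meta$category, asg_v,
                                     presets[[method]], comp)
    out$models[[method]] <- m
  }
  out
}

#' Assemble a run configuration
#'
#' Single-config driver for end-to-end runs: simulate (or load) spectra,
#' restrict to the working wavelength range, split, classify and/or fit
#' the quantitative models, and write the TSV report bundle.
#'
#' @param input A [generator_config()], a calibration preset name
#'   (`"paper_like"`, `"separable"`, `"null"`), or a named list
#'   `list(spectra = , meta = , traits = )` of CSV paths.
#' @param analysis Subset of `c("plsda", "simca", "lda", "quantify")`, or
#'   `"all"`.
#' @param range Working wavelength range (nm), default 1000-1800.
#' @param split A [split_plan()]; default reproduces the reference
#'   allocation manifest.
#' @param seed Integer master seed (generator and split seeds derive from
#'   it unless set explicitly in their own configs).
#' @param out_dir Report directory, created if needed.
#' @param classify_args,quantify_args Extra arguments for [classify_all()]
#'   / [quantify_all()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = "paper_like", analysis = "all",
                       range = c(1000, 1800), split = NULL, seed = 1L,
                       out_dir = tempfile("nircured_run_"),
                       classify_args = list(), quantify_args = list()) {
  if (identical(analysis, "all"))
    analysis <- c("plsda", "simca", "lda", "quantify")
  bad <- setdiff(analysis, c("plsda", "simca", "lda", "quantify"))
  if (length(bad)) stop("unknown analysis: ", paste(bad, collapse = ", "))
  if (is.character(input))                  # validates preset name early
    stopifnot(input %in% c("paper_like", "separable", "null"))
  structure(list(input = input, analysis = analysis, range = range,
                 split = split, seed = as.integer(seed), out_dir = out_dir,
                 classify_args = classify_args,
                 quantify_args = quantify_args),
            class = "run_config")
}

#' Execute a configured run
#'
#' Stages run in order: simulate/load, wavelength-range restriction,
#' stratified split, classification (PLS-DA, SIMCA, LDA) and quantitative
#' PLSR. Reports are written as TSV files under `config$out_dir`
#' (`classification_<method>.tsv`, `quantitative.tsv`, `descriptive.tsv`,
#' `outliers.tsv`) together with a plain-text run manifest recording the
#' seed and configuration, so identical config + seed reproduce the bundle
#' byte for byte.
#'
#' @param config A [run_config()].
#' @return List with the in-memory results (`classification`,
#'   `quantitative`, `set`) and `paths` of the written reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ## stage: data
  if (is.character(config$input)) {
    gen <- generate_spectra(calibration_preset(config$input,
                                               seed = config$seed))
    set <- gen$set
  } else if (inherits(config$input, "generator_config")) {
    set <- generate_spectra(config$input)$set
  } else {
    set <- read_spectra_csv(config$input$spectra, config$input$meta,
                            config$input$traits)
  }
  ## stage: range + split
  set <- select_wavelength_range(set, config$range[1], config$range[2])
  plan <- config$split
  if (is.null(plan)) {
    alloc <- reference_allocation()
    manifest <- alloc[alloc$set == "cal",
                      c("category", "storage_time", "n")]
    names(manifest)[3] <- "n_cal"
    plan <- split_plan(manifest = manifest, seed = config$seed + 1L)
  }
  set <- stratified_split(set, plan)
  paths <- character()
  out <- list(set = set)
  ## stage: classification
  cls <- intersect(config$analysis, c("plsda", "simca", "lda"))
  if (length(cls)) {
    res <- do.call(classify_all, c(list(set), config$classify_args))
    out$classification <- res
    for (method in cls) {
      p <- file.path(config$out_dir,
                     paste0("classification_", method, ".tsv"))
      render_classification_table(res[[method]], p)
      paths <- c(paths, p)
    }
  }
  ## stage: quantitative
  if ("quantify" %in% config$analysis && !is.null(set$traits)) {
    q <- do.call(quantify_all,
                 c(list(calibration_set(set), validation_set(set)),
                   config$quantify_args))
    out$quantitative <- q
    p <- file.path(config$out_dir, "quantitative.tsv")
    render_quantitative_table(q$table, p)
    paths <- c(paths, p)
    d <- file.path(config$out_dir, "descriptive.tsv")
    desc <- describe_traits(calibration_set(set)$traits)
    desc[-1] <- lapply(desc[-1], function(v) round(v, 6))
    utils::write.table(desc, d, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, d)
    rep_rows <- do.call(rbind, lapply(q$models, function(m) m$outlier_report))
    o <- file.path(config$out_dir, "outliers.tsv")
    utils::write.table(rep_rows, o, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, o)
  }
  ## manifest
  mf <- file.path(config$out_dir, "run_manifest.txt")
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("analysis: %s", paste(config$analysis, collapse = ",")),
               sprintf("range: %g-%g nm", config$range[1], config$range[2]),
               sprintf("input: %s",
                       if (is.character(config$input)) config$input
                       else "custom"),
               utils::capture.output(utils::str(config$classify_args)),
               utils::capture.output(utils::str(config$quantify_args))),
             mf)
  out$paths <- c(paths, mf)
  out
}
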