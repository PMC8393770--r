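#' Reference design tables
#'
#' The study conditions the synthetic generator emulates are anchored to
#' three plain-text tables shipped with the package: the calibration /
#' validation sample allocation per commercial category and storage time,
#' the pooled descriptive statistics of the eleven quality traits, and the
#' reported performance of the best PLSR model per trait. They parameterise
#' the generator and support internal-consistency checks (for example that
#' RPD and RER follow algebraically from the tabulated SD, range and RMSEV).
#'
#' @name reference_tables
NULL

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "nircured")
  if (!nzchar(p)) stop("reference table not found: ", file)
  p
}

#' @rdname reference_tables
#' @return `reference_allocation()`: data frame `set`, `storage_time`,
#'   `category`, `n` (long form).
#' @export
reference_allocation <- function() {
  wide <- utils::read.csv(ref_path("sample_allocation.csv"),
                          stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(category_levels(), function(k)
    data.frame(set = wide$set, storage_time = wide$storage_time,
               category = k, n = wide[[k]], stringsAsFactors = FALSE)))
  long[order(long$set, long$category, long$storage_time), ]
}

#' @rdname reference_tables
#' @return `reference_trait_stats()`: data frame `trait`, `set`, `n`,
#'   `mean`, `min`, `max`, `sd`.
#' @export
reference_trait_stats <- function() {
  utils::read.csv(ref_path("trait_reference_stats.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @return `reference_model_performance()`: data frame with the per-trait
#'   reported PLSR statistics (LVs, retained n, 1-VR, RMSECV, R2v, RMSEV,
#'   RPDv, RERv).
#' @export
reference_model_performance <- function() {
  utils::read.csv(ref_path("reported_model_performance.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = "NA")
}
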