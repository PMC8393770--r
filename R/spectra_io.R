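#' Read a spectra collection from CSV files
#'
#' The spectral file is wide CSV: a `sample_id` column followed by one column
#' per wavelength, header names being wavelengths in nm. An optional first
#' line `# mode: <reflectance|absorbance|derivative>` records the measurement
#' mode; otherwise `mode` applies. The metadata file holds `sample_id`,
#' `category`, `storage_time` and `set`. A trait table keyed by `sample_id`
#' may be supplied as a third file.
#'
#' @param path Spectra CSV path.
#' @param meta_path Metadata CSV path.
#' @param traits_path Optional traits CSV path.
#' @param mode Fallback mode when the file carries no mode directive.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path, meta_path, traits_path = NULL,
                             mode = "reflectance") {
  head_lines <- readLines(path, n = 2L)
  skip <- 0L
  provenance <- character()
  for (ln in head_lines) {
    if (grepl("^#\\s*mode:", ln)) {
      mode <- trimws(sub("^#\\s*mode:", "", ln))
      skip <- skip + 1L
    } else if (grepl("^#\\s*provenance:", ln)) {
      pv <- trimws(sub("^#\\s*provenance:", "", ln))
      if (nzchar(pv)) provenance <- strsplit(pv, ";", fixed = TRUE)[[1]]
      skip <- skip + 1L
    }
  }
  tab <- utils::read.csv(path, check.names = FALSE, skip = skip,
                         stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("spectra file lacks a sample_id column")
  ids <- as.character(tab$sample_id)
  wl_names <- setdiff(names(tab), "sample_id")
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl)) stop("non-numeric wavelength header(s): ",
                      paste(wl_names[is.na(wl)], collapse = ", "))
  if (any(diff(wl) <= 0)) stop("grid not increasing")
  m <- as.matrix(tab[, wl_names, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in spectral matrix")
  dimnames(m) <- list(ids, NULL)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "category", "storage_time", "set")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(ids, meta$sample_id)
  if (length(absent))
    stop("sample id(s) in spectra absent from metadata: ",
         paste(absent, collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), need]
  traits <- NULL
  if (!is.null(traits_path)) {
    traits <- utils::read.csv(traits_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  }
  spectra_set(m, wl, mode = mode, meta = meta, traits = traits,
              provenance = provenance)
}

#' Write a spectra collection to CSV files
#'
#' Writes the wide spectral table (with a `# mode:` directive line), the
#' metadata table and, when present, the trait table. Numeric values are
#' written with 15 significant digits so a read/write round trip reproduces
#' the matrix to better than 1e-12 relative error.
#'
#' @param set A [spectra_set()].
#' @param stem Path stem; files `<stem>_spectra.csv`, `<stem>_meta.csv` and
#'   optionally `<stem>_traits.csv` are produced.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_spectra_csv <- function(set, stem) {
  validate_spectra_set(set)
  if (n_samples(set) == 0) stop("empty set")
  spath <- paste0(stem, "_spectra.csv")
  mpath <- paste0(stem, "_meta.csv")
  fmt <- function(v) sprintf("%.15g", v)
  header <- paste(c("sample_id", fmt(set$wavelengths)), collapse = ",")
  rows <- vapply(seq_len(n_samples(set)), function(i)
    paste(c(set$meta$sample_id[i], fmt(set$spectra[i, ])), collapse = ","),
    character(1))
  writeLines(c(paste0("# mode: ", set$mode),
               paste0("# provenance: ", paste(set$provenance, collapse = ";")),
               header, rows), spath)
  utils::write.csv(set$meta, mpath, row.names = FALSE, quote = FALSE)
  paths <- c(spectra = spath, meta = mpath)
  if (!is.null(set$traits)) {
    tpath <- paste0(stem, "_traits.csv")
    tr <- set$traits
    num <- vapply(tr, is.numeric, logical(1))
    tr[num] <- lapply(tr[num], fmt)
    utils::write.csv(tr, tpath, row.names = FALSE, quote = FALSE)
    paths <- c(paths, traits = tpath)
  }
  invisible(paths)
}

#' Restrict a spectra collection to a wavelength range
#'
#' Keeps the columns with `lo <= wavelength <= hi` (closed interval, so both
#' endpoints are retained when present on the grid).
#'
#' @param set A [spectra_set()].
#' @param lo,hi Range bounds in nm, `lo < hi`.
#' @return A `spectra_set` on the restricted grid, with provenance appended.
#' @export
select_wavelength_range <- function(set, lo, hi) {
  stopifnot(lo < hi)
  keep <- set$wavelengths >= lo & set$wavelengths <= hi
  if (!any(keep)) stop("no wavelengths in [", lo, ", ", hi, "]")
  replace_matrix(set, set$spectra[, keep, drop = FALSE],
                 wavelengths = set$wavelengths[keep],
                 step = sprintf("range %g-%g nm", lo, hi))
}

#' Plan a stratified calibration/validation split
#'
#' @param fraction_cal Proportion of each stratum assigned to calibration,
#'   in (0, 1].
#' @param seed Integer seed controlling the within-stratum random draw.
#' @param manifest Optional data frame `category`, `storage_time`, `n_cal`
#'   giving explicit calibration counts per stratum; these override the
#'   fractional apportionment (used to reproduce a published sample
#'   allocation exactly).
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(fraction_cal = 0.75, seed = 1L, manifest = NULL) {
  stopifnot(fraction_cal > 0, fraction_cal <= 1)
  structure(list(fraction_cal = fraction_cal, seed = as.integer(seed),
                 manifest = manifest),
            class = "split_plan")
}

#' Stratified calibration/validation split
#'
#' Within each (category x storage time) stratum, assigns
#' round-to-nearest(fraction x stratum size) samples to calibration by
#' largest-remainder apportionment and the rest to validation; which samples
#' go where is uniformly random under the plan's seed. Explicit manifest
#' counts, when given, override the apportionment per stratum.
#'
#' @param set A [spectra_set()] whose samples are unassigned (or
#'   `allow_reassign = TRUE`).
#' @param plan A [split_plan()].
#' @param allow_reassign Permit overwriting existing cal/val assignments.
#' @return The `spectra_set` with `meta$set` filled with "cal"/"val".
#' @export
stratified_split <- function(set, plan, allow_reassign = FALSE) {
  stopifnot(inherits(plan, "split_plan"))
  if (!allow_reassign && any(set$meta$set != "unassigned"))
    stop("samples already assigned; use allow_reassign = TRUE")
  meta <- set$meta
  strata <- interaction(meta$category, meta$storage_time, drop = TRUE)
  assignment <- rep("val", nrow(meta))
  rng <- local_rng(plan$seed)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    size <- length(idx)
    if (!is.null(plan$manifest)) {
      cat_s <- meta$category[idx[1]]
      st_s <- meta$storage_time[idx[1]]
      row <- which(plan$manifest$category == cat_s &
                     plan$manifest$storage_time == st_s)
      if (length(row) != 1)
        stop("manifest lacks stratum ", cat_s, "/", st_s)
      n_cal <- plan$manifest$n_cal[row]
      if (n_cal > size)
        stop("manifest count ", n_cal, " exceeds stratum size ", size,
             " for ", cat_s, "/", st_s)
    } else {
      n_cal <- largest_remainder_round(plan$fraction_cal, size)
    }
    take <- rng$sample(idx, n_cal)
    assignment[take] <- "cal"
  }
  meta$set <- assignment
  out <- set
  out$meta <- meta
  validate_spectra_set(out)
  out
}

## Largest-remainder apportionment of one stratum between cal and val:
## ideal share fraction*size, integer parts first, the leftover unit (at most
## one for a two-way split) goes to the cell with the larger remainder, ties
## favouring calibration.
largest_remainder_round <- function(fraction, size) {
  ideal <- c(cal = fraction * size, val = (1 - fraction) * size)
  base <- floor(ideal)
  left <- size - sum(base)
  if (left > 0) {
    rem <- ideal - base
    ord <- order(-rem, c(1, 2))   # tie -> cal first
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  unname(base["cal"])
}

## Seed-scoped RNG helper: draws happen in an isolated RNG stream so package
## functions never disturb the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  with_state <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
    })
    fn()
  }
  list(
    sample = function(x, size) with_state(function()
      x[sample.int(length(x), size)]),
    rnorm = function(n, mean = 0, sd = 1) with_state(function()
      stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) with_state(function()
      stats::runif(n, min, max))
  )
}

#' Extract calibration / validation subsets
#' @param set A split `spectra_set`.
#' @return The corresponding subset.
#' @export
calibration_set <- function(set) subset_samples(set, set$meta$set == "cal")

#' @rdname calibration_set
#' @export
validation_set <- function(set) subset_samples(set, set$meta$set == "val")
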