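#' @keywords internal
"_PACKAGE"

## Factor levels shared across the package.
category_levels <- function() c("Black", "Red", "White")
storage_levels  <- function() c("T0", "T4", "T8", "T12")
set_levels      <- function() c("cal", "val", "unassigned")

#' Names of the eleven quality traits
#'
#' Dry matter and chloride in g/100 g, tocopherols in ug/g, fatty acids in
#' g/100 g FAME, lipid oxidation in mg MDA/kg and protein oxidation in
#' nmol carbonyls/mg protein.
#'
#' @return Character vector of trait identifiers.
#' @export
trait_names <- function() {
  c("DM", "NaCl", "alpha_tocopherol", "gamma_tocopherol",
    "C16:0", "C18:0", "C18:1 n-9", "C18:2 n-6", "C18:3 n-3",
    "MDA", "carbonyls")
}

#' Construct a spectra collection
#'
#' Bundles a sample-by-wavelength matrix with its wavelength grid, the
#' measurement mode, per-sample metadata (commercial category, storage time,
#' calibration/validation assignment), optional reference trait values and a
#' provenance trail of applied pre-treatments.
#'
#' @param spectra Numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param wavelengths Strictly increasing numeric vector of wavelengths (nm),
#'   length equal to `ncol(spectra)`.
#' @param mode One of `"reflectance"`, `"absorbance"`, `"derivative"`.
#'   Reflectance values must lie in (0, 1].
#' @param meta Data frame with columns `sample_id`, `category`
#'   (Black/Red/White), `storage_time` (T0/T4/T8/T12) and `set`
#'   (cal/val/unassigned). Rows are matched to `spectra` by `sample_id` when
#'   the matrix has rownames, otherwise by position.
#' @param traits Optional data frame keyed by `sample_id` holding quality
#'   trait columns (see [trait_names()]).
#' @param provenance Character vector describing pre-treatments already
#'   applied, in order.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(spectra, wavelengths, mode = "reflectance",
                        meta = NULL, traits = NULL, provenance = character()) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (is.null(meta)) {
    ids <- rownames(spectra)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(spectra)))
    meta <- data.frame(sample_id = ids,
                       category = NA_character_,
                       storage_time = NA_character_,
                       set = "unassigned",
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!is.null(rownames(spectra)) && nrow(spectra) > 0) {
    idx <- match(meta$sample_id, rownames(spectra))
    if (anyNA(idx)) {
      missing <- meta$sample_id[is.na(idx)]
      stop("sample id(s) in metadata absent from spectra: ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(rownames(spectra), meta$sample_id)
    if (length(extra))
      stop("sample id(s) in spectra absent from metadata: ",
           paste(extra, collapse = ", "))
    spectra <- spectra[idx, , drop = FALSE]
  } else {
    rownames(spectra) <- meta$sample_id
  }
  if (!is.null(traits)) {
    traits <- as.data.frame(traits, stringsAsFactors = FALSE,
                            check.names = FALSE)
    idx <- match(meta$sample_id, traits$sample_id)
    if (anyNA(idx)) {
      stop("sample id(s) missing from trait table: ",
           paste(meta$sample_id[is.na(idx)], collapse = ", "))
    }
    traits <- traits[idx, , drop = FALSE]
    rownames(traits) <- NULL
  }
  obj <- structure(
    list(spectra = spectra, wavelengths = wavelengths, mode = mode,
         meta = meta, traits = traits, provenance = as.character(provenance)),
    class = "spectra_set")
  validate_spectra_set(obj)
  obj
}

#' Validate a spectra_set
#'
#' Checks the structural invariants: matching dimensions, a strictly
#' increasing finite wavelength grid, unique sample ids, a known mode,
#' reflectance values in (0, 1] and no missing spectral values.
#'
#' @param x A `spectra_set`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  p <- length(x$wavelengths)
  if (p < 2) stop("wavelength grid must have length >= 2")
  if (any(!is.finite(x$wavelengths))) stop("wavelengths must be finite")
  if (any(diff(x$wavelengths) <= 0)) stop("grid not increasing")
  if (ncol(x$spectra) != p)
    stop("spectra have ", ncol(x$spectra), " columns but grid has ", p)
  if (anyDuplicated(x$meta$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(x$meta$sample_id[duplicated(x$meta$sample_id)]),
               collapse = ", "))
  if (nrow(x$meta) != nrow(x$spectra))
    stop("metadata rows do not match spectra rows")
  if (anyNA(x$spectra)) stop("missing values in spectral matrix")
  if (!x$mode %in% c("reflectance", "absorbance", "derivative"))
    stop("unknown mode: ", x$mode)
  if (x$mode == "reflectance" && nrow(x$spectra) > 0 &&
      (any(x$spectra <= 0) || any(x$spectra > 1)))
    stop("reflectance values must lie in (0, 1]")
  ok_cat <- is.na(x$meta$category) | x$meta$category %in% category_levels()
  if (!all(ok_cat))
    stop("unknown category: ",
         paste(unique(x$meta$category[!ok_cat]), collapse = ", "))
  ok_set <- x$meta$set %in% set_levels()
  if (!all(ok_set))
    stop("unknown set label: ",
         paste(unique(x$meta$set[!ok_set]), collapse = ", "))
  invisible(x)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavelengths (%.0f-%.0f nm), mode=%s\n",
              nrow(x$spectra), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$mode))
  if (!all(is.na(x$meta$category)))
    cat("  categories:", paste(sprintf("%s=%d", names(table(x$meta$category)),
                                       table(x$meta$category)), collapse = " "), "\n")
  if (!is.null(x$traits))
    cat("  traits:", ncol(x$traits) - 1L, "columns\n")
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of samples / wavelengths
#' @param x A `spectra_set`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$spectra)

#' @rdname n_samples
#' @export
n_wavelengths <- function(x) length(x$wavelengths)

#' Subset samples of a spectra_set
#'
#' @param x A `spectra_set`.
#' @param which Logical/integer index vector or character vector of sample
#'   ids.
#' @return A `spectra_set` restricted to the selected samples, preserving
#'   order of selection.
#' @export
subset_samples <- function(x, which) {
  if (is.character(which)) {
    idx <- match(which, x$meta$sample_id)
    if (anyNA(idx))
      stop("unknown sample id(s): ", paste(which[is.na(idx)], collapse = ", "))
  } else {
    idx <- seq_len(n_samples(x))[which]
  }
  spectra_set(x$spectra[idx, , drop = FALSE], x$wavelengths, x$mode,
              meta = x$meta[idx, , drop = FALSE],
              traits = if (is.null(x$traits)) NULL else
                x$traits[idx, , drop = FALSE],
              provenance = x$provenance)
}

## Replace the spectral matrix, keeping everything else; used by
## pre-treatment steps.
replace_matrix <- function(x, m, mode = x$mode, wavelengths = x$wavelengths,
                           step = NULL) {
  rownames(m) <- x$meta$sample_id
  prov <- x$provenance
  if (!is.null(step)) prov <- c(prov, step)
  spectra_set(m, wavelengths, mode, meta = x$meta, traits = x$traits,
              provenance = prov)
}
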