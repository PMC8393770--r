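#' Reflectance to absorbance transform
#'
#' Converts reflectance R to apparent absorbance log10(1/R), the scale on
#' which chemometric models are built.
#'
#' @param set A reflectance-mode [spectra_set()] with all values > 0.
#' @return An absorbance-mode `spectra_set`.
#' @export
to_absorbance <- function(set) {
  if (set$mode != "reflectance")
    stop("to_absorbance requires reflectance input, got ", set$mode)
  bad <- which(set$spectra <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive reflectance at sample %s, wavelength %g nm",
                 set$meta$sample_id[bad[1, 1]],
                 set$wavelengths[bad[1, 2]]))
  }
  replace_matrix(set, -log10(set$spectra), mode = "absorbance",
                 step = "absorbance")
}

#' Standard normal variate
#'
#' Centres each spectrum on its own mean and scales it by its own standard
#' deviation (n-1 denominator), correcting multiplicative and additive
#' scatter. Each output row has mean 0 and sd 1.
#'
#' @param set A [spectra_set()].
#' @param eps Spectra with sd below this are rejected as degenerate.
#' @return The transformed `spectra_set`.
#' @export
snv <- function(set, eps = 1e-12) {
  m <- set$spectra
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  if (any(sd_ <= eps)) {
    stop("DegenerateSpectrum: near-constant spectrum for sample ",
         paste(set$meta$sample_id[sd_ <= eps], collapse = ", "))
  }
  replace_matrix(set, (m - mu) / sd_, step = "snv")
}

#' Polynomial detrend
#'
#' Subtracts from each spectrum its own least-squares polynomial fit of the
#' given degree in wavelength, correcting baseline curvature. The fit uses
#' the raw wavelengths in nm as regressors; degree 0 reduces to per-spectrum
#' mean centring.
#'
#' @param set A [spectra_set()].
#' @param degree Polynomial degree (default 2, second-order baseline).
#' @return The residual `spectra_set`.
#' @export
detrend <- function(set, degree = 2) {
  p <- n_wavelengths(set)
  if (degree >= p) stop("degree must be below the grid length")
  ## orthogonal polynomial basis for numerical stability; the fitted
  ## subspace (and hence the residual) is identical to a raw-power fit
  basis <- if (degree == 0) matrix(1, p, 1) else
    cbind(1, stats::poly(set$wavelengths, degree = degree))
  qr_b <- qr(basis)
  fitted <- t(qr.fitted(qr_b, t(set$spectra)))
  replace_matrix(set, set$spectra - fitted,
                 step = sprintf("detrend(%d)", degree))
}

## Savitzky-Golay convolution weights for the d-th derivative from a local
## polynomial fit of order q on offsets -l..r (l = r here): row d of the
## pseudo-inverse of the Vandermonde design, times d!.
sg_kernel <- function(d, l, r, q) {
  if (l != r) stop("kernel must be symmetric (left points = right points)")
  if (q < d) stop("polynomial order must be >= derivative order")
  w <- l + r + 1
  if (w <= q) stop("window must exceed polynomial order")
  x <- seq.int(-l, r)
  A <- outer(x, 0:q, `^`)
  Ct <- solve(crossprod(A), t(A))     # (q+1) x w
  Ct[d + 1, ] * factorial(d)
}

#' Savitzky-Golay derivative
#'
#' Computes the d-th derivative per nm by local polynomial fitting on a
#' symmetric window. Parameters follow the (d, l, r, q) convention:
#' derivative order, left points, right points, polynomial order — e.g.
#' (1,4,4,1) is a first derivative with a 9-point window and linear fit.
#' Edges are trimmed so every output point uses the full symmetric kernel;
#' the output grid drops l leading and r trailing wavelengths. The result is
#' scaled by the grid spacing^d, making it invariant to the sampling step.
#'
#' @param set A [spectra_set()] on a uniform grid.
#' @param d,l,r,q Derivative order, left/right half-window points and
#'   polynomial order.
#' @return A derivative-mode `spectra_set` on the trimmed grid.
#' @export
savgol_derivative <- function(set, d = 1, l = 4, r = 4, q = 1) {
  wl <- set$wavelengths
  h <- diff(wl)
  if (max(abs(h - h[1])) > 1e-6 * abs(h[1]))
    stop("grid must be uniformly spaced for Savitzky-Golay filtering")
  w <- l + r + 1
  p <- length(wl)
  if (p < w) stop("grid shorter than filter window")
  k <- sg_kernel(d, l, r, q)
  n <- n_samples(set)
  out_p <- p - l - r
  out <- matrix(0, n, out_p)
  ## convolution as a banded matrix product: column j of the output is the
  ## kernel applied to columns j..j+w-1
  for (offset in seq_len(w)) {
    out <- out + k[offset] * set$spectra[, offset:(offset + out_p - 1),
                                         drop = FALSE]
  }
  out <- out / h[1]^d
  replace_matrix(set, out, mode = "derivative",
                 wavelengths = wl[(l + 1):(p - r)],
                 step = sprintf("savgol(%d,%d,%d,%d)", d, l, r, q))
}

#' Build a pre-treatment pipeline
#'
#' A pipeline is an ordered list of steps, each
#' `list(kind = , params = list())` with kind one of `absorbance`, `snv`,
#' `detrend`, `savgol`. An absorbance step, if present, must come first; a
#' Savitzky-Golay step, if present, must come last.
#'
#' @param steps List of step descriptors, or a preset name accepted by
#'   [pipeline_preset()].
#' @return An object of class `pretreatment_pipeline`.
#' @export
pretreatment_pipeline <- function(steps = list()) {
  if (is.character(steps)) return(pipeline_preset(steps))
  kinds <- vapply(steps, `[[`, character(1), "kind")
  bad <- setdiff(kinds, c("absorbance", "snv", "detrend", "savgol"))
  if (length(bad)) stop("unknown step kind: ", paste(bad, collapse = ", "))
  if (sum(kinds == "absorbance") > 1) stop("at most one absorbance step")
  if (any(kinds == "absorbance") && kinds[1] != "absorbance")
    stop("absorbance step must come first")
  if (any(kinds == "savgol") && which(kinds == "savgol") != length(kinds))
    stop("savgol step must come last")
  structure(list(steps = steps), class = "pretreatment_pipeline")
}

#' Named pre-treatment presets
#'
#' The presets mirror the treatment labels used throughout the analysis:
#' `"none"`, `"abs"` (absorbance only), `"SNV-DE"` (absorbance, SNV, then
#' second-order detrend), `"SNV-DE SG 1,4,4,1"`, `"SNV-DE SG 2,5,5,2"` and
#' `"SG 1,4,4,1"` (absorbance then derivative).
#'
#' @param name Preset name.
#' @return A [pretreatment_pipeline()].
#' @export
pipeline_preset <- function(name) {
  ab <- list(kind = "absorbance", params = list())
  sn <- list(kind = "snv", params = list())
  de <- list(kind = "detrend", params = list(degree = 2))
  sg1 <- list(kind = "savgol", params = list(d = 1, l = 4, r = 4, q = 1))
  sg2 <- list(kind = "savgol", params = list(d = 2, l = 5, r = 5, q = 2))
  steps <- switch(name,
    "none" = list(),
    "abs" = list(ab),
    "SNV-DE" = list(ab, sn, de),
    "SNV-DE SG 1,4,4,1" = list(ab, sn, de, sg1),
    "SNV-DE SG 2,5,5,2" = list(ab, sn, de, sg2),
    "SG 1,4,4,1" = list(ab, sg1),
    stop("unknown pre-treatment preset: ", name))
  pretreatment_pipeline(steps)
}

#' Apply a pre-treatment pipeline
#'
#' Applies the steps in order, appending each to the set's provenance. An
#' absorbance step is skipped silently when the data are already in
#' absorbance mode (so presets can be reused on either input mode).
#'
#' @param set A [spectra_set()].
#' @param pipe A [pretreatment_pipeline()] or preset name.
#' @return The transformed `spectra_set`.
#' @export
apply_pipeline <- function(set, pipe) {
  if (is.character(pipe)) pipe <- pipeline_preset(pipe)
  stopifnot(inherits(pipe, "pretreatment_pipeline"))
  for (st in pipe$steps) {
    set <- switch(st$kind,
      absorbance = if (set$mode == "absorbance") set else to_absorbance(set),
      snv = snv(set),
      detrend = do.call(detrend, c(list(set), st$params)),
      savgol = do.call(savgol_derivative, c(list(set), st$params)))
  }
  set
}
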