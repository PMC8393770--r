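# Small in-code fixtures shared across the suite.

# n x p reflectance set with smooth random spectra on a unit grid.
make_toy_set <- function(n = 3, p = 5, seed = 42, lo = 1000) {
  set.seed(seed)
  wl <- seq(lo, lo + p - 1)
  base <- 0.3 + 0.1 * sin(wl / 40)
  m <- t(replicate(n, base + cumsum(rnorm(p, sd = 0.002))))
  m <- pmin(pmax(m, 0.01), 1)
  meta <- data.frame(sample_id = sprintf("T%02d", seq_len(n)),
                     category = rep(category_levels(), length.out = n),
                     storage_time = "T0", set = "unassigned",
                     stringsAsFactors = FALSE)
  spectra_set(m, wl, mode = "reflectance", meta = meta)
}

# Absorbance-mode set wrapping an arbitrary matrix (skips reflectance
# bounds), for preprocessing math checks.
make_abs_set <- function(m, wl = seq_len(ncol(m)) + 999) {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  spectra_set(m, wl, mode = "absorbance")
}

# Reference-allocation calibration manifest used for the standard split.
reference_manifest <- function() {
  alloc <- reference_allocation()
  manifest <- alloc[alloc$set == "cal", c("category", "storage_time", "n")]
  names(manifest)[3] <- "n_cal"
  manifest
}

# Standard small end-to-end input: generated set restricted to the working
# range and split with the reference manifest.
make_study_set <- function(preset = "paper_like", seed = 1, ...) {
  g <- generate_spectra(calibration_preset(preset, seed = seed, ...))
  s <- select_wavelength_range(g$set, 1000, 1800)
  stratified_split(s, split_plan(manifest = reference_manifest(),
                                 seed = seed + 1))
}
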