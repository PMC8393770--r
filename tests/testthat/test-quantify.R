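# Low-rank noiseless regression fixture wrapped as a spectra collection.
make_regression_set <- function(n = 24, seed = 50) {
  set.seed(seed)
  wl <- seq(1000, 1100)
  p <- length(wl)
  scores <- matrix(rnorm(n * 2, sd = 0.01), n)
  dirs <- rbind(sin(wl / 15), cos(wl / 23))
  m <- 0.5 + scores %*% dirs
  y <- 3 + 40 * scores[, 1]
  meta <- data.frame(sample_id = sprintf("Q%02d", 1:n),
                     category = rep(category_levels(), length.out = n),
                     storage_time = "T0", set = "unassigned")
  traits <- data.frame(sample_id = meta$sample_id, DM = y,
                       check.names = FALSE)
  spectra_set(m, wl, mode = "reflectance", meta = meta, traits = traits)
}

test_that("resubstitution on noiseless low-rank data is essentially exact", {
  s <- make_regression_set()
  tm <- fit_trait_model(s, "DM", preset = "none", A_max = 3, policy = NULL)
  expect_lte(tm$A, 3)
  expect_gt(tm$result$one_minus_vr, 0.999)
  v <- external_validate(tm, s)
  expect_gt(v$r2_v, 0.999)
  expect_lt(v$rmsev, 1e-3 * sd(s$traits$DM))
})

test_that("constant predictions yield an undefined R2v reported as NA", {
  s <- make_regression_set()
  tm <- fit_trait_model(s, "DM", preset = "none", A_max = 2, policy = NULL)
  flat <- s
  flat$spectra <- matrix(colMeans(s$spectra), nrow = n_samples(s),
                         ncol = n_wavelengths(s), byrow = TRUE)
  rownames(flat$spectra) <- s$meta$sample_id
  v <- external_validate(tm, flat)
  expect_true(is.na(v$r2_v))
  expect_false(is.na(v$rmsev))
})

test_that("validation metrics respect order invariance and affine rescaling", {
  s <- make_regression_set(seed = 51)
  noisy <- s
  set.seed(52)
  noisy$traits$DM <- noisy$traits$DM + rnorm(n_samples(s), sd = 0.1)
  tm <- fit_trait_model(noisy, "DM", preset = "none", A_max = 2,
                        policy = NULL)
  v1 <- external_validate(tm, noisy)
  perm <- subset_samples(noisy, sample(n_samples(noisy)))
  v2 <- external_validate(tm, perm)
  expect_equal(v1[-1], v2[-1], tolerance = 1e-10)
  # affine trait rescale: R2, RPD, RER unchanged; RMSE scales
  scaled <- noisy
  scaled$traits$DM <- 2 + 3 * scaled$traits$DM
  tms <- fit_trait_model(scaled, "DM", preset = "none", A_max = 2,
                         policy = NULL)
  vs <- external_validate(tms, scaled)
  expect_equal(vs$r2_v, v1$r2_v, tolerance = 1e-6)
  expect_equal(vs$rpd_v, v1$rpd_v, tolerance = 1e-6)
  expect_equal(vs$rer_v, v1$rer_v, tolerance = 1e-6)
  expect_equal(vs$rmsev, 3 * v1$rmsev, tolerance = 1e-6)
  expect_equal(v1$rer_v / v1$rpd_v,
               diff(range(noisy$traits$DM)) / sd(noisy$traits$DM),
               tolerance = 1e-10)
})

test_that("missing or degenerate traits are rejected", {
  s <- make_regression_set()
  expect_error(fit_trait_model(s, "NaCl", policy = NULL), "absent")
  s$traits$DM <- 1
  expect_error(fit_trait_model(s, "DM", policy = NULL), "degenerate")
})

test_that("the fitted coefficient vector recovers the generating direction", {
  cfg <- calibration_preset("null", seed = 60,
                            nuisance_sd = 5e-4, noise_sd = 1e-5,
                            scatter_mult_sd = 0, scatter_add_sd = 0)
  cfg$trait_table$coupling <- ifelse(cfg$trait_table$trait == "C18:3 n-3",
                                     0.014, 0)
  g <- generate_spectra(cfg)
  s <- select_wavelength_range(g$set, 1000, 1800)
  cal <- stratified_split(s, split_plan(manifest = reference_manifest(),
                                        seed = 61)) |> calibration_set()
  tm <- fit_trait_model(cal, "C18:3 n-3", preset = "abs", A_max = 4,
                        policy = NULL)
  B <- pls_coefficients(tm$pls, tm$A)[, 1]
  shape <- nircured:::trait_shape(cfg$grid, 1160)
  shape <- shape[cfg$grid >= 1000 & cfg$grid <= 1800]
  expect_gte(abs(cor(B, shape)), 0.9)
  expect_gt(tm$result$one_minus_vr, 0.8)
})
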