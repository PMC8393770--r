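test_that("absorbance transform is log10(1/R) and guards its domain", {
  m <- matrix(c(1, 0.1, 0.01, 0.5), 1)
  s <- spectra_set(m, 1000:1003, mode = "reflectance")
  a <- to_absorbance(s)
  expect_equal(a$spectra[1, ], c(0, 1, 2, -log10(0.5)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(a$mode, "absorbance")
  expect_error(to_absorbance(a), "requires reflectance")
  expect_error(spectra_set(matrix(c(0.5, 0, 0.5, 0.5), 1), 1000:1003,
                           mode = "reflectance"), "\\(0, 1\\]")
})

test_that("SNV centres and scales each spectrum with the n-1 deviation", {
  s <- make_abs_set(rbind(c(2, 4, 6), c(1, 1, 4)))
  out <- snv(s)
  expect_equal(out$spectra[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  set.seed(1)
  big <- make_abs_set(matrix(rnorm(5 * 801), 5))
  b <- snv(big)
  expect_lt(max(abs(rowMeans(b$spectra))), 1e-12)
  expect_lt(max(abs(apply(b$spectra, 1, sd) - 1)), 1e-12)
  expect_error(snv(make_abs_set(rbind(c(5, 5, 5, 5)))), "DegenerateSpectrum")
  # idempotence
  expect_equal(snv(b)$spectra, b$spectra, tolerance = 1e-10)
})

test_that("detrend removes its own polynomial and is a linear projection", {
  wl <- seq(1000, 1100, by = 1)
  quad <- 3 + 0.2 * wl + 0.01 * wl^2
  s <- make_abs_set(rbind(quad), wl)
  expect_lt(max(abs(detrend(s, 2)$spectra)), 1e-9)
  flat <- make_abs_set(rbind(quad), wl)
  expect_equal(detrend(flat, 0)$spectra[1, ],
               quad - mean(quad), tolerance = 1e-9, ignore_attr = TRUE)
  # quadratic + sinusoid: residual must match an independent least-squares
  # solve of the same degree
  y <- quad + sin(wl / 7)
  s2 <- make_abs_set(rbind(y), wl)
  oracle <- stats::residuals(stats::lm(y ~ wl + I(wl^2)))
  expect_equal(detrend(s2, 2)$spectra[1, ], unname(oracle),
               tolerance = 1e-9, ignore_attr = TRUE)
  # linearity
  set.seed(2)
  x1 <- rnorm(length(wl)); x2 <- rnorm(length(wl))
  lhs <- detrend(make_abs_set(rbind(2 * x1 - 3 * x2), wl), 2)$spectra
  rhs <- 2 * detrend(make_abs_set(rbind(x1), wl), 2)$spectra -
    3 * detrend(make_abs_set(rbind(x2), wl), 2)$spectra
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("Savitzky-Golay derivatives are exact on polynomials and trim edges", {
  wl <- seq(1000, 1800, by = 1)
  lin <- 0.7 + 0.003 * wl
  s <- make_abs_set(rbind(lin), wl)
  d1 <- savgol_derivative(s, 1, 4, 4, 1)
  expect_equal(n_wavelengths(d1), 793)
  expect_lt(max(abs(d1$spectra - 0.003)), 1e-10)
  expect_identical(d1$mode, "derivative")
  quad <- 1e-5 * wl^2
  d2 <- savgol_derivative(make_abs_set(rbind(quad), wl), 2, 5, 5, 2)
  expect_lt(max(abs(d2$spectra - 2e-5)), 1e-8)
  # smoothing (d = 0) preserves polynomials of order <= q exactly
  d0 <- savgol_derivative(make_abs_set(rbind(quad), wl), 0, 5, 5, 2)
  expect_equal(d0$spectra[1, ], quad[6:796], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(savgol_derivative(make_abs_set(rbind(c(1, 2, 4)),
                                              c(1, 2, 4))), "uniform")
  expect_error(sg_kernel <- nircured:::sg_kernel(1, 4, 3, 1), "symmetric")
})

test_that("Savitzky-Golay kernel matches the signal-package coefficients", {
  skip_if_not_installed("signal")
  for (prm in list(c(1, 4, 4, 1), c(2, 5, 5, 2), c(0, 3, 3, 2))) {
    k <- nircured:::sg_kernel(prm[1], prm[2], prm[3], prm[4])
    Fm <- signal::sgolay(p = prm[4], n = prm[2] + prm[3] + 1, m = prm[1])
    mid <- prm[2] + 1
    expect_equal(k, unclass(Fm)[mid, ], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("derivative scaling makes results grid-step invariant", {
  wl1 <- seq(1000, 1100, by = 1)
  wl2 <- seq(1000, 1100, by = 2)
  f <- function(w) 0.5 + 0.002 * w + 3e-6 * w^2
  d1 <- savgol_derivative(make_abs_set(rbind(f(wl1)), wl1), 1, 4, 4, 2)
  d2 <- savgol_derivative(make_abs_set(rbind(f(wl2)), wl2), 1, 4, 4, 2)
  expect_equal(d1$spectra[1, match(d2$wavelengths, d1$wavelengths)],
               d2$spectra[1, ], tolerance = 1e-9)
})

test_that("SNV then detrend removes per-sample affine scatter exactly", {
  set.seed(3)
  wl <- seq(1000, 1200)
  base <- 0.6 + 0.2 * sin(wl / 25) + 0.05 * cos(wl / 60)
  a <- c(1.4, 0.7, 1.0); b <- c(0.2, -0.1, 0.05)
  scattered <- t(sapply(1:3, function(i) a[i] * base + b[i]))
  clean <- rbind(base, base, base)
  pipe <- pretreatment_pipeline(list(list(kind = "snv", params = list()),
                                     list(kind = "detrend",
                                          params = list(degree = 2))))
  out_s <- apply_pipeline(make_abs_set(scattered, wl), pipe)
  out_c <- apply_pipeline(make_abs_set(clean, wl), pipe)
  expect_equal(out_s$spectra, out_c$spectra, tolerance = 1e-9)
})

test_that("pipeline presets compose the named steps in order", {
  set.seed(4)
  wl <- seq(1000, 1400)
  s <- make_abs_set(matrix(0.5 + abs(rnorm(3 * length(wl), sd = 0.05)),
                           3), wl)
  manual <- detrend(snv(s), 2)
  expect_equal(apply_pipeline(s, "SNV-DE")$spectra, manual$spectra,
               tolerance = 1e-12)
  expect_equal(apply_pipeline(s, pretreatment_pipeline())$spectra,
               s$spectra)
  # composite preset equals the stepwise application, including the trim
  stepwise <- savgol_derivative(manual, 1, 4, 4, 1)
  composite <- apply_pipeline(s, "SNV-DE SG 1,4,4,1")
  expect_equal(composite$spectra, stepwise$spectra, tolerance = 1e-12)
  expect_equal(n_wavelengths(composite), length(wl) - 8)
  expect_error(pipeline_preset("MSC"), "unknown pre-treatment")
  expect_error(pretreatment_pipeline(list(
    list(kind = "savgol", params = list()),
    list(kind = "snv", params = list()))), "savgol step must come last")
})
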