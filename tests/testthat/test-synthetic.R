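test_that("the default design emits 185 packages in the reference strata", {
  g <- generate_spectra(generator_config(seed = 70))
  s <- g$set
  expect_equal(n_samples(s), 185)
  expect_equal(unname(table(s$meta$category)), c(59, 63, 63),
               ignore_attr = TRUE)
  alloc <- reference_allocation()
  strata <- aggregate(n ~ category + storage_time, alloc, sum)
  got <- as.data.frame(table(s$meta$category, s$meta$storage_time),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(strata))) {
    expect_equal(got$Freq[got$Var1 == strata$category[i] &
                            got$Var2 == strata$storage_time[i]],
                 strata$n[i])
  }
  expect_true(all(s$spectra > 0 & s$spectra <= 1))
  expect_equal(ncol(s$traits) - 1, 11)
})

test_that("generation is deterministic under seed and varies across seeds", {
  a <- generate_spectra(generator_config(seed = 71))
  b <- generate_spectra(generator_config(seed = 71))
  c <- generate_spectra(generator_config(seed = 72))
  expect_identical(a$set$spectra, b$set$spectra)
  expect_identical(a$set$traits, b$set$traits)
  expect_false(identical(a$set$spectra, c$set$spectra))
  expect_equal(dim(a$set$spectra), dim(c$set$spectra))
})

test_that("switching off every variance source collapses spectra to one curve", {
  cfg <- generator_config(class_amp = 0, nuisance_sd = 0, noise_sd = 0,
                          scatter_mult_sd = 0, scatter_add_sd = 0,
                          trait_table = default_trait_table(0), seed = 73)
  cfg$trait_table$coupling <- 0
  g <- generate_spectra(cfg)
  expect_lt(max(apply(g$set$spectra, 2, function(col) diff(range(col)))), 1e-12)
})

test_that("trait emissions track the reference statistics", {
  tt <- default_trait_table()
  dm <- tt[tt$trait == "DM", ]
  expect_equal(unique(dm$global_mean), 73.13)
  expect_equal(unique(dm$global_sd), 1.36)
  # pooled statistics of a large draw approach the configured values
  big_alloc <- data.frame(set = "cal", storage_time = "T0",
                          category = category_levels(),
                          n = c(1595, 1703, 1702))
  cfg <- generator_config(allocation = big_alloc,
                          grid = seq(1000, 1400), seed = 74)
  g <- generate_spectra(cfg)
  tr <- g$set$traits
  expect_true(all(tr[["C18:3 n-3"]] >= 0.29 & tr[["C18:3 n-3"]] <= 1.53))
  for (nm in c("DM", "NaCl", "MDA", "C18:3 n-3")) {
    target <- unique(tt$global_sd[tt$trait == nm])
    expect_lt(abs(sd(tr[[nm]]) - target) / target, 0.10)
    tgt_mean <- unique(tt$global_mean[tt$trait == nm])
    expect_lt(abs(mean(tr[[nm]]) - tgt_mean),
              0.1 * target + 0.02 * abs(tgt_mean))
  }
})

test_that("Black and Red spectra overlap while White stands apart", {
  g <- generate_spectra(generator_config(seed = 75))
  s <- select_wavelength_range(g$set, 1000, 1800)
  cls <- split(seq_len(n_samples(s)), s$meta$category)
  centroid <- function(idx) colMeans(s$spectra[idx, , drop = FALSE])
  d_br <- sqrt(sum((centroid(cls$Black) - centroid(cls$Red))^2))
  d_bw <- sqrt(sum((centroid(cls$Black) - centroid(cls$White))^2))
  d_rw <- sqrt(sum((centroid(cls$Red) - centroid(cls$White))^2))
  expect_lt(d_br, d_bw)
  expect_lt(d_br, d_rw)
})

test_that("scatter correction recovers the scatter-free spectra", {
  base_args <- list(noise_sd = 0, scatter_tilt_sd = 0, seed = 76)
  cfg_scatter <- do.call(generator_config, base_args)
  cfg_clean <- do.call(generator_config,
                       c(base_args, list(scatter_mult_sd = 0,
                                         scatter_add_sd = 0)))
  # same seed: identical structure before the scatter stage
  sc <- generate_spectra(cfg_scatter)$set
  cl <- generate_spectra(cfg_clean)$set
  pipe <- "SNV-DE"
  out_s <- apply_pipeline(select_wavelength_range(sc, 1000, 1800), pipe)
  out_c <- apply_pipeline(select_wavelength_range(cl, 1000, 1800), pipe)
  expect_equal(out_s$spectra, out_c$spectra, tolerance = 1e-6)
})

test_that("stronger class effects never hurt LDA recovery", {
  accs <- sapply(c(0.002, 0.03), function(amp) {
    mean(sapply(1:6, function(seed) {
      cfg <- generator_config(class_amp = amp, seed = 80 + seed,
                              grid = seq(1000, 1800),
                              trait_table = default_trait_table(0))
      s <- generate_spectra(cfg)$set
      fit <- fit_lda(s$spectra, s$meta$category)
      mean(classify_lda(fit, s$spectra)$predicted == s$meta$category)
    }))
  })
  expect_gte(accs[2], accs[1])
})
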