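#' Default per-class trait parameters
#'
#' Builds the generating distribution of the eleven quality traits. Pooled
#' mean, SD and range per trait come from the shipped reference statistics
#' (calibration set); class separations are expressed as offsets in pooled-SD
#' units and chosen so that pooled draws stay inside the reference range:
#' traits shaped by the finishing feeding regime (tocopherols, C18:1 n-9 and
#' C18:3 n-3 from acorn/grass feeding) run higher in the Black and Red
#' categories, fodder-associated fatty acids (C16:0, C18:0, C18:2 n-6) in
#' White; dry matter, salt and protein oxidation carry no class signal.
#' Within-class SD is reduced so the pooled SD matches the reference value.
#'
#' @param offset_scale Multiplier on all class offsets (1 keeps the default
#'   separations; 0 removes every compositional class difference).
#' @return Data frame with one row per trait x class: `trait`, `class`,
#'   `mean`, `sd`, plus pooled `global_mean`, `global_sd`, `min`, `max`,
#'   `coupling` (absorbance units per pooled SD), `meas_sd` (reference
#'   measurement noise) and `band` (coupling band centre, nm).
#' @export
default_trait_table <- function(offset_scale = 0.65) {
  stats <- reference_trait_stats()
  stats <- stats[stats$set == "cal", ]
  ## class offsets in pooled-SD units (Black, Red, White) and spectral
  ## coupling strength; C18:3 n-3 is deliberately the strongest-coupled
  ## trait and carbonyls the uncoupled ("null") one
  spec <- list(
    #                  offB   offR   offW  coupling meas_frac band
    "DM"               = c( 0.00,  0.00,  0.00, 0.0060, 0.30, 1440),
    "NaCl"             = c( 0.00,  0.00,  0.00, 0.0050, 0.30, 1180),
    "alpha_tocopherol" = c( 0.60,  0.35, -0.91, 0.0055, 0.30, 1690),
    "gamma_tocopherol" = c( 0.30,  0.20, -0.48, 0.0040, 0.30, 1705),
    "C16:0"            = c(-0.50, -0.35,  0.82, 0.0040, 0.35, 1215),
    "C18:0"            = c(-0.30, -0.20,  0.48, 0.0045, 0.30, 1390),
    "C18:1 n-9"        = c( 0.50,  0.35, -0.82, 0.0035, 0.35, 1725),
    "C18:2 n-6"        = c(-0.40, -0.30,  0.68, 0.0035, 0.35, 1760),
    "C18:3 n-3"        = c( 0.55,  0.40, -0.92, 0.0140, 0.25, 1160),
    "MDA"              = c(-0.20, -0.10,  0.29, 0.0040, 0.35, 1360),
    "carbonyls"        = c( 0.00,  0.00,  0.00, 0.0000, 0.30, 1520))
  n_by_class <- c(Black = 59, Red = 63, White = 63)
  w <- n_by_class / sum(n_by_class)
  ## moments of N(mu, sd) truncated to [a, b]
  tnorm_moments <- function(mu, sd, a, b) {
    an <- (a - mu) / sd; bn <- (b - mu) / sd
    Z <- stats::pnorm(bn) - stats::pnorm(an)
    if (!is.finite(Z) || Z < 1e-12)      # mass collapsed onto one bound
      return(c(mean = min(max(mu, a), b), var = 0))
    da <- stats::dnorm(an); db <- stats::dnorm(bn)
    m <- mu + sd * (da - db) / Z
    v <- sd^2 * (1 + (an * da - bn * db) / Z - ((da - db) / Z)^2)
    c(mean = m, var = max(v, 0))
  }
  rows <- list()
  for (tr in names(spec)) {
    s <- stats[stats$trait == tr, ]
    off <- offset_scale * spec[[tr]][1:3]
    off <- off - sum(w * off)          # centre offsets on the pooled mean
    between <- sum(w * off^2)
    within_sd <- s$sd * sqrt(max(1 - between, 0.09))
    ## emitted values are truncated to the reference range, which both
    ## shrinks the pooled SD and shifts class means when the range sits
    ## asymmetrically around them (left-skewed fatty acids). Calibrate the
    ## generating means and SD jointly so the *truncated* distribution
    ## reproduces the reference class means and pooled SD.
    meas_sd <- spec[[tr]][5] * s$sd
    want <- s$mean + off * s$sd
    gen_mean <- want
    target <- s$sd
    f <- 1
    for (pass in 1:4) {
      pooled_sd_after <- function(fc) {
        mom <- vapply(1:3, function(j)
          tnorm_moments(gen_mean[j], fc * within_sd, s$min, s$max),
          numeric(2))
        mbar <- sum(w * mom["mean", ])
        sqrt(sum(w * (mom["var", ] + (mom["mean", ] - mbar)^2)) + meas_sd^2)
      }
      f <- stats::optimize(function(fc) (pooled_sd_after(fc) - target)^2,
                           c(0.05, 4), tol = 1e-7)$minimum
      gen_mean <- vapply(1:3, function(j)
        stats::optimize(function(m)
          (tnorm_moments(m, f * within_sd, s$min, s$max)["mean"] -
             want[j])^2,
          want[j] + c(-6, 6) * f * within_sd, tol = 1e-8)$minimum,
        numeric(1))
    }
    within_sd <- f * within_sd
    for (j in 1:3) {
      k <- names(n_by_class)[j]
      rows[[paste(tr, k)]] <- data.frame(
        trait = tr, class = k,
        mean = gen_mean[j], sd = within_sd,
        global_mean = s$mean, global_sd = s$sd,
        min = s$min, max = s$max,
        coupling = spec[[tr]][4],
        meas_sd = spec[[tr]][5] * s$sd,
        band = spec[[tr]][6],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generator configuration
#'
#' Assembles the full description of the synthetic NIR experiment: a
#' 1000-2500 nm grid at 1 nm, the reference sample allocation (185 packages
#' over category x storage strata), a smooth Gaussian-band absorbance
#' baseline, class-dependent absorbance offsets concentrated around 1090,
#' 1280 and 1640 nm with the ordering White > Black ~ Red, per-sample
#' multiplicative/additive scatter with a small linear tilt, heteroscedastic
#' reflectance noise inflated above 1800 nm, and trait values linearly
#' coupled into band intensities.
#'
#' @param class_amp Absorbance amplitude of the White-vs-rest class effect.
#' @param black_red_sep Scale of the Black and Red band patterns relative
#'   to `class_amp`; their pattern coefficients are fractions of White's,
#'   so the Black-Red offset distance stays below the White offset.
#' @param nuisance_sd Amplitude SD of the sixteen within-class nuisance
#'   bands (biological variability unrelated to class or traits).
#' @param noise_sd Reflectance noise SD below 1800 nm.
#' @param noise_inflation Noise multiplier at and above 1800 nm.
#' @param scatter_mult_sd,scatter_add_sd,scatter_tilt_sd Scatter model:
#'   log-multiplicative SD, additive offset SD (absorbance units) and linear
#'   tilt SD (absorbance per nm).
#' @param trait_table Trait parameter table, see [default_trait_table()].
#' @param allocation Data frame `set`, `storage_time`, `category`, `n`;
#'   default the shipped reference allocation.
#' @param grid Wavelength grid (nm).
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(class_amp = 0.010,
                             black_red_sep = 1.9,
                             nuisance_sd = 0.0055,
                             noise_sd = 4e-4,
                             noise_inflation = 10,
                             scatter_mult_sd = 0.08,
                             scatter_add_sd = 0.02,
                             scatter_tilt_sd = 0,
                             trait_table = default_trait_table(),
                             allocation = reference_allocation(),
                             grid = seq(1000, 2500, by = 1),
                             seed = 1L) {
  stopifnot(all(allocation$n >= 0), noise_sd >= 0, nuisance_sd >= 0)
  structure(list(class_amp = class_amp, black_red_sep = black_red_sep,
                 nuisance_sd = nuisance_sd, noise_sd = noise_sd,
                 noise_inflation = noise_inflation,
                 scatter_mult_sd = scatter_mult_sd,
                 scatter_add_sd = scatter_add_sd,
                 scatter_tilt_sd = scatter_tilt_sd,
                 trait_table = trait_table, allocation = allocation,
                 grid = grid, seed = as.integer(seed)),
            class = "generator_config")
}

#' Calibration presets of the generator
#'
#' `"separable"` enlarges the class effect and quietens nuisance variability
#' so all three classifiers should approach perfect recovery; `"paper_like"`
#' is the default condition, with class overlap and noise set so the
#' classifiers land in the performance bands typical of packaged dry-cured
#' sausage spectra (LDA sensitivity/specificity in the 75-95% range,
#' SIMCA sensitivity near 100% with much weaker specificity); `"null"`
#' removes the class effect entirely so classification is at chance.
#'
#' @param level One of `"separable"`, `"paper_like"`, `"null"`.
#' @param seed Integer seed stored in the config.
#' @param ... Overrides forwarded to [generator_config()].
#' @return A `generator_config`.
#' @export
calibration_preset <- function(level = c("paper_like", "separable", "null"),
                               seed = 1L, ...) {
  level <- match.arg(level)
  quiet_traits <- function() {
    tt <- default_trait_table()
    tt$coupling <- 0.25 * tt$coupling
    tt
  }
  args <- switch(level,
    paper_like = list(),
    separable = list(class_amp = 0.06, black_red_sep = 1.5,
                     nuisance_sd = 0.002, noise_sd = 2e-4,
                     scatter_mult_sd = 0.02, scatter_add_sd = 0.005,
                     trait_table = quiet_traits()),
    null = list(class_amp = 0,
                trait_table = default_trait_table(offset_scale = 0)))
  over <- list(...)
  args[names(over)] <- over            # explicit overrides win
  do.call(generator_config, c(args, list(seed = seed)))
}

## Fixed smooth absorbance baseline: overtone/combination-band landscape of
## a fatty cured-meat matrix (C-H bands near 1200/1400/1700 nm, O-H water
## bands at 1450/1940 nm, strong combination bands above 2000 nm).
baseline_absorbance <- function(wl) {
  bands <- rbind(
    c(1090, 45, 0.10), c(1210, 55, 0.12), c(1280, 50, 0.10),
    c(1450, 55, 0.30), c(1640, 45, 0.08), c(1730, 40, 0.16),
    c(1940, 60, 0.45), c(2100, 80, 0.30), c(2310, 55, 0.28))
  a <- 0.45 + 2e-4 * (wl - 1000)
  for (i in seq_len(nrow(bands)))
    a <- a + bands[i, 3] * gauss_band(wl, bands[i, 1], bands[i, 2])
  a
}

## Class-effect spectral patterns: shared bands at 1090/1280/1640 nm; the
## per-class coefficient rows keep White well offset and Black/Red close
## but not identical.
class_effect_matrix <- function(wl, class_amp, black_red_sep) {
  g <- cbind(gauss_band(wl, 1090, 35), gauss_band(wl, 1280, 35),
             gauss_band(wl, 1640, 35))
  coefs <- rbind(
    Black = black_red_sep * c(0.6, 0.0, 0.4),
    Red   = black_red_sep * c(0.0, 0.5, 0.0),
    White = c(1.0, 0.9, 0.8))
  t(class_amp * coefs %*% t(g))      # p x 3, one column per class
}

## Nuisance (within-class biological variability) band shapes: a fixed set
## spanning the working range, including neighbours of the class-marker
## bands, so within-class variation occupies many spectral directions.
nuisance_shapes <- function(wl) {
  centres <- c(1040, 1080, 1150, 1220, 1270, 1330, 1400, 1470, 1540,
               1610, 1660, 1720, 1780, 1860, 1980, 2150)
  widths  <- c(35, 40, 55, 45, 40, 45, 50, 60, 45,
               40, 45, 40, 50, 55, 60, 70)
  sapply(seq_along(centres), function(i)
    gauss_band(wl, centres[i], widths[i]))
}

## Per-trait coupling shape: main Gaussian at the trait band plus a weaker
## satellite 560 nm up-field, mimicking overtone pairs.
trait_shape <- function(wl, band) {
  s <- gauss_band(wl, band, 40) + 0.5 * gauss_band(wl, band + 560, 50)
  s / sqrt(sum(s^2)) * sqrt(length(wl))   # unit RMS over the grid
}

#' Generate a synthetic spectra collection
#'
#' Draws labelled reflectance spectra and coupled trait values under the
#' configured study design. Absorbance is built as baseline + class effect +
#' nuisance variability + trait couplings, scattered per sample as
#' `a * A(lambda) + b + c * (lambda - mean)`, converted to reflectance
#' `R = 10^-A`, and degraded with heteroscedastic noise (inflated above
#' 1800 nm). Trait values are emitted as latent value + measurement noise,
#' truncated to the reference range. Deterministic under the config seed.
#'
#' @param config A [generator_config()].
#' @return List with `set` (a [spectra_set()] carrying meta and traits, all
#'   samples unassigned) and `truth` (generating class, latent trait values
#'   and scatter parameters per sample).
#' @export
generate_spectra <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  wl <- config$grid
  alloc <- config$allocation
  meta <- do.call(rbind, lapply(seq_len(nrow(alloc)), function(i)
    if (alloc$n[i] > 0)
      data.frame(category = alloc$category[i],
                 storage_time = alloc$storage_time[i],
                 set = "unassigned", stringsAsFactors = FALSE)[rep(1, alloc$n[i]), ]))
  rownames(meta) <- NULL
  n <- nrow(meta)
  meta <- data.frame(sample_id = sprintf("S%03d", seq_len(n)), meta,
                     stringsAsFactors = FALSE)
  p <- length(wl)
  tt <- config$trait_table
  traits_list <- split(tt, tt$trait)[unique(tt$trait)]
  with_seed(config$seed, {
    A_mat <- matrix(rep(baseline_absorbance(wl), each = n), n, p)
    ce <- class_effect_matrix(wl, config$class_amp, config$black_red_sep)
    A_mat <- A_mat + t(ce[, match(meta$category, colnames(ce)), drop = FALSE])
    ## nuisance variability
    ns <- nuisance_shapes(wl)
    zn <- matrix(stats::rnorm(n * ncol(ns)), n, ncol(ns))
    A_mat <- A_mat + config$nuisance_sd * zn %*% t(ns)
    ## traits: latent values and spectral couplings
    latent <- emitted <- list()
    for (tr in names(traits_list)) {
      pr <- traits_list[[tr]]
      row <- pr[match(meta$category, pr$class), ]
      lat <- rtnorm(n, row$mean, row$sd, pr$min[1], pr$max[1])
      zg <- (lat - pr$global_mean[1]) / pr$global_sd[1]
      if (pr$coupling[1] != 0)
        A_mat <- A_mat + pr$coupling[1] * outer(zg, trait_shape(wl, pr$band[1]))
      obs <- lat + pr$meas_sd[1] * stats::rnorm(n)
      obs <- pmin(pmax(obs, pr$min[1]), pr$max[1])
      latent[[tr]] <- lat
      emitted[[tr]] <- obs
    }
    ## per-sample scatter
    a <- exp(config$scatter_mult_sd * stats::rnorm(n))
    b <- config$scatter_add_sd * stats::rnorm(n)
    cc <- config$scatter_tilt_sd * stats::rnorm(n)
    A_mat <- A_mat * a + b + outer(cc, wl - mean(wl))
    R <- 10^(-A_mat)
    sd_vec <- config$noise_sd *
      ifelse(wl >= 1800, config$noise_inflation, 1)
    R <- R + matrix(stats::rnorm(n * p), n, p) * rep(sd_vec, each = n)
    clipped <- mean(R <= 0 | R > 1)
    if (clipped > 0.02)
      stop("configuration drives ", round(100 * clipped, 1),
           "% of reflectance out of (0, 1]; reduce amplitudes or noise")
    R <- pmin(pmax(R, 1e-4), 1)
    dimnames(R) <- NULL
    traits <- data.frame(sample_id = meta$sample_id, emitted,
                         check.names = FALSE, stringsAsFactors = FALSE)
    set <- spectra_set(R, wl, mode = "reflectance", meta = meta,
                       traits = traits,
                       provenance = "synthetic")
    truth <- list(class = meta$category,
                  latent_traits = data.frame(sample_id = meta$sample_id,
                                             latent, check.names = FALSE),
                  scatter = data.frame(sample_id = meta$sample_id,
                                       mult = a, add = b, tilt = cc))
    list(set = set, truth = truth)
  })
}
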