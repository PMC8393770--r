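Package: nircured
Title: NIR Spectral Chemometrics for Commercial-Category Authentication of
    Dry-Cured Sausage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for near-infrared reflectance spectra of
    packaged dry-cured sausage: spectral pre-treatments (absorbance
    transform, standard normal variate, polynomial detrending,
    Savitzky-Golay derivatives), PCA-based outlier screening with leverage
    and residual rules, PLS-DA, SIMCA and Mahalanobis LDA classification
    into the Black/Red/White commercial categories, and PLSR prediction of
    eleven quality traits with leave-one-out cross-validation, latent
    variable selection and external-validation statistics (1-VR, RMSECV,
    SECV, R2v, RMSEV, RPD, RER). Includes a synthetic spectra generator
    emulating the study design so every stage runs without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
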