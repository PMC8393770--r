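#!/usr/bin/env Rscript
# Classification of the packages into commercial categories with the three
# qualitative approaches, each on its best-performing pre-treatment:
# PLS-DA on SNV-detrend + first Savitzky-Golay derivative, SIMCA on plain
# absorbance, LDA (Mahalanobis, on PCA scores) on SNV-detrend.
# Expected picture: PLS-DA and LDA balanced SE/SP; SIMCA near-perfect
# sensitivity but weak specificity (overlapping class envelopes).

library(nircured)

seed <- 1
dir.create("results", showWarnings = FALSE)

set <- read_spectra_csv("results/data/salchichon_spectra.csv",
                        "results/data/salchichon_meta.csv",
                        "results/data/salchichon_traits.csv")

res <- classify_all(set, cv = TRUE)

for (method in c("plsda", "simca", "lda")) {
  path <- file.path("results", paste0("classification_", method, ".tsv"))
  render_classification_table(res[[method]], path)
  message("== ", toupper(method), " ==")
  print(res[[method]][, c("category", "n_cal", "SE_cal", "SP_cal",
                          "n_val", "SE_val", "SP_val")], digits = 4)
}

message("PLS-DA cross-validated 1-VR per class:")
print(round(res$plsda_cv$one_minus_vr, 3))
message("PLS-DA cross-validated RMSECV per class:")
print(round(res$plsda_cv$rmsecv, 3))
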