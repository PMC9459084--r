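#!/usr/bin/env Rscript
# Step 1 — simulate a raw/processed herbal cohort with planted toxicity
# markers, plus its cytotoxicity plates and an untargeted feature matrix.
# Writes: results/quant.csv, results/ic50_true.csv, results/plates.csv,
#         results/feature_matrix.csv, results/truth.json

library(pmtox)

seed <- 20260920L
dir.create("results", showWarnings = FALSE)

spec <- cohort_spec(seed = seed)
co <- generate_quant_cohort(spec)
cat("cohort:", nrow(co$quant), "batches x", ncol(co$quant), "compounds;",
    "planted markers:", paste(co$truth$planted_compounds, collapse = ", "),
    "\n")
write_quant_table(co$quant, "results/quant.csv")
write_toxicity_table(co$toxicity, "results/ic50_true.csv")

plates <- generate_dose_response_plates(co, od_noise_sd = 0.02,
                                        seed = seed + 1L)
write.csv(plates, "results/plates.csv", row.names = FALSE)
cat("plates:", nrow(plates), "wells over",
    length(unique(plates$batch)), "batches x",
    length(unique(plates$cell_line)), "cell lines\n")

feat <- generate_metabolomics_matrix(seed = seed + 2L)
write.csv(data.frame(sample = rownames(feat$matrix), group = feat$groups,
                     feat$matrix, check.names = FALSE),
          "results/feature_matrix.csv", row.names = FALSE)
cat("feature matrix:", nrow(feat$matrix), "samples x", ncol(feat$matrix),
    "features;", sum(feat$truth), "planted differential\n")

jsonlite::write_json(
  list(seed = seed, planted_markers = co$truth$planted_compounds,
       reduction_factors = co$truth$reduction_factors,
       differential_features = colnames(feat$matrix)[feat$truth]),
  "results/truth.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("ground truth written to results/truth.json\n")
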