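#!/usr/bin/env Rscript
# Step 2 — untargeted differential screening: total-intensity normalization,
# PCA overview, OPLS-DA VIP, Welch p and fold change, and the
# VIP > 1.5 / p < 0.05 / FC < 0.5 cascade.
# Reads:  results/feature_matrix.csv, results/truth.json
# Writes: results/screen_stats.csv, results/pca_scores.csv

library(pmtox)

df <- read.csv("results/feature_matrix.csv", check.names = FALSE)
mat <- as.matrix(df[, -(1:2)])
rownames(mat) <- df$sample
groups <- df$group

pca <- fit_pca(normalize_and_scale(mat), n_components = 2, center = FALSE)
write.csv(data.frame(sample = df$sample, group = groups, pca$scores),
          "results/pca_scores.csv", row.names = FALSE)
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$explained_variance[1], 100 * pca$explained_variance[2]))

res <- screen_feature_matrix(mat, groups)
write.csv(res$stats, "results/screen_stats.csv", row.names = FALSE)
cat(sprintf("OPLS-DA: R2Y %.3f, Q2 %.3f, %d orthogonal component(s)\n",
            res$model$R2Y, res$model$Q2, res$model$n_orthogonal))
cat(length(res$selected), "features pass the VIP/p/FC cascade\n")

truth <- jsonlite::read_json("results/truth.json", simplifyVector = TRUE)
tp <- intersect(res$selected, truth$differential_features)
cat(sprintf("recovered %d/%d planted differential features, %d false positives\n",
            length(tp), length(truth$differential_features),
            length(res$selected) - length(tp)))
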