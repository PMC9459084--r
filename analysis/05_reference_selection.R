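#!/usr/bin/env Rscript
# Step 5 — apply the selection rules to the published per-compound score
# tables of the 50-batch P. multiflorum cohort and rebuild the reported
# three-marker consensus.
# Writes: results/reference_consensus.csv

library(pmtox)

scores <- pm_model_scores()
panel <- pm_compound_panel()
vip_all <- setNames(rep(1, nrow(scores)), scores$compound)

opls_sel <- lapply(c(L02 = "opls_r_L02", HepG2 = "opls_r_HepG2"),
                   function(col) select_by_vip_coefficient(
                     list(vip = vip_all,
                          coefficients = setNames(scores[[col]],
                                                  scores$compound))))
ann_sel <- lapply(c(L02 = "miv_L02", HepG2 = "miv_HepG2"),
                  function(col) select_by_miv(setNames(scores[[col]],
                                                       scores$compound)))
gra_sel <- lapply(c(L02 = "gra_L02", HepG2 = "gra_HepG2"),
                  function(col) select_by_degree(
                    list(degree = setNames(scores[[col]], scores$compound)),
                    0.6))

for (cl in c("L02", "HepG2")) {
  cat(sprintf("%s: GRA %d | OPLS {%s} | BP-ANN {%s}\n", cl,
              length(gra_sel[[cl]]),
              paste(sort(opls_sel[[cl]]), collapse = ","),
              paste(sort(ann_sel[[cl]]), collapse = ",")))
}

cons <- across_model_intersection(
  model_selections(gra = gra_sel, opls = opls_sel, bpann = ann_sel))
print(cons)

out <- merge(data.frame(compound = cons$markers), panel, by = "compound")
write.csv(out, "results/reference_consensus.csv", row.names = FALSE)
cat("toxicity markers with identities written to results/reference_consensus.csv\n")
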