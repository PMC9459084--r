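test_that("cohort generation is deterministic under a fixed seed", {
  s <- cohort_spec(seed = 7)
  c1 <- generate_quant_cohort(s)
  c2 <- generate_quant_cohort(s)
  expect_identical(as.matrix(c1$quant), as.matrix(c2$quant))
  expect_identical(c1$toxicity$ic50, c2$toxicity$ic50)
  expect_identical(c1$truth, c2$truth)
})

test_that("processed/raw mean-area ratio matches the reduction factor", {
  s <- cohort_spec(n_raw = 5000, n_processed = 5000, n_compounds = 2,
                   planted_toxic = 1L, reduction_factors = c(0.2, 1),
                   noise_cv = 0, seed = 21)
  co <- generate_quant_cohort(s)
  g <- attr(co$quant, "group")
  ratio <- colMeans(co$quant[g == "processed", ]) /
    colMeans(co$quant[g == "raw", ])
  expect_equal(unname(ratio[1]), 0.2, tolerance = 0.02)
  expect_equal(unname(ratio[2]), 1, tolerance = 0.02)
})

test_that("with zero betas and zero noise every IC50 equals the baseline", {
  s <- cohort_spec(n_raw = 6, n_processed = 4, n_compounds = 3,
                   planted_toxic = 1L, toxicity_coefficients = c(0, 0, 0),
                   baseline_inverse_ic50 = 1 / 500, noise_cv = 0,
                   cell_lines = c(L02 = 1), seed = 3)
  co <- generate_quant_cohort(s)
  expect_equal(co$toxicity$ic50, rep(500, 10))
})

test_that("generated quantities respect their supports", {
  co <- generate_quant_cohort(cohort_spec(seed = 99))
  expect_true(all(as.matrix(co$quant) >= 0))
  expect_true(all(co$toxicity$ic50 > 0))
  plates <- generate_dose_response_plates(co, od_noise_sd = 0.01, seed = 1)
  expect_true(all(plates$od > 0))
})

test_that("planted markers explain at least half the potency variance", {
  # the calibration contract behind the end-to-end recovery conditions
  for (s in 1:5) {
    co <- generate_quant_cohort(cohort_spec(seed = 200 + s))
    A <- as.matrix(co$quant)
    det <- as.numeric(A %*% co$truth$beta)
    inv <- co$toxicity$inv_ic50[co$toxicity$cell_line == "L02"]
    expect_gte(var(det) / var(inv), 0.5)
  }
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(planted_toxic = 20L), "spec error")
  expect_error(cohort_spec(reduction_factors = c(rep(1, 15), 0)),
               "spec error")
  expect_error(cohort_spec(noise_cv = -0.1), "spec error")
  expect_error(cohort_spec(n_compounds = 3, planted_toxic = 1L,
                           toxicity_coefficients = c(0, 1, 0)),
               "planted set")
  expect_error(generate_dose_response_plates(
    generate_quant_cohort(cohort_spec(seed = 1)), od_noise_sd = -1),
    "spec error")
})

test_that("noise-free plates round-trip the true IC50 through the 4PL fit", {
  s <- cohort_spec(n_raw = 2, n_processed = 2, n_compounds = 2,
                   planted_toxic = 1L, mean_raw_ic50 = 40, noise_cv = 0,
                   cell_lines = c(L02 = 1), seed = 5)
  co <- generate_quant_cohort(s)
  plates <- generate_dose_response_plates(co, od_noise_sd = 0,
                                          replicates = 1, seed = 2)
  tox <- plates_to_toxicity(plates)
  merged <- merge(as.data.frame(tox), as.data.frame(co$toxicity),
                  by = c("batch", "cell_line"))
  ok <- merged$ic50.y < 900  # within the tested grid
  expect_true(all(abs(merged$ic50.x - merged$ic50.y)[ok] /
                    merged$ic50.y[ok] < 1e-4))
})

test_that("metabolomics matrices are deterministic with planted fold changes", {
  m1 <- generate_metabolomics_matrix(n_features = 50, n_differential = 5,
                                     seed = 13)
  m2 <- generate_metabolomics_matrix(n_features = 50, n_differential = 5,
                                     seed = 13)
  expect_identical(m1$matrix, m2$matrix)
  expect_equal(sum(m1$truth), 5L)
  expect_true(all(m1$fc[m1$truth] >= 0.137 & m1$fc[m1$truth] <= 0.441))
  expect_error(generate_metabolomics_matrix(fc_range = c(0.2, 1.2)),
               "spec error")
  expect_error(generate_metabolomics_matrix(n_features = 5,
                                            n_differential = 6),
               "n_differential")
})

test_that("QC replicates cluster tighter than the raw/processed separation", {
  d <- generate_metabolomics_matrix(n_features = 100, n_differential = 10,
                                    n_qc = 6, qc_cv = 0.01, seed = 17)
  scaled <- normalize_and_scale(d$matrix)
  pca <- fit_pca(scaled, n_components = 2, center = FALSE)
  sc <- pca$scores
  qc <- sc[d$groups == "QC", ]
  qc_dist <- mean(dist(qc))
  between <- mean(as.matrix(dist(sc))[d$groups == "raw",
                                      d$groups == "processed"])
  expect_lt(qc_dist, between)
})
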