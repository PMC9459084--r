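grid7 <- c(0.064, 0.32, 1.6, 8, 40, 200, 1000)

test_that("inhibition ratio follows the plate-control definition", {
  expect_equal(inhibition_ratio(1.4, 1.4, 0.2), 0)
  expect_equal(inhibition_ratio(0.2, 1.4, 0.2), 100)
  expect_equal(inhibition_ratio(1.0, 1.4, 0.2), 100 * (1 - 1.4) / (0.2 - 1.4))
  expect_equal(round(inhibition_ratio(1.0, 1.4, 0.2), 2), 33.33)
  # affine invariance: shifting all ODs leaves the ratio unchanged
  expect_equal(inhibition_ratio(1.0 + 0.3, 1.4 + 0.3, 0.2 + 0.3),
               inhibition_ratio(1.0, 1.4, 0.2))
  expect_error(inhibition_ratio(1, 0.5, 0.5), "degenerate-control")
})

test_that("noise-free 4PL curves are recovered exactly", {
  for (pars in list(c(40, 1), c(40, 2), c(3.7, 0.8), c(500, 1.5))) {
    inh <- fourpl_curve(grid7, ic50 = pars[1], hill = pars[2])
    fit <- fit_four_pl(grid7, inh)
    expect_equal(fit$ic50, pars[1], tolerance = 1e-6)
    expect_equal(fit$hill, pars[2], tolerance = 1e-4)
    expect_false(fit$censored)
  }
  # at the midpoint concentration the generating inhibition is exactly 50%
  expect_equal(fourpl_curve(40, ic50 = 40), 50)
})

test_that("4PL fit is scale-equivariant in concentration", {
  inh <- fourpl_curve(grid7, ic50 = 25, hill = 1.3)
  f1 <- fit_four_pl(grid7, inh)
  f2 <- fit_four_pl(grid7 * 3, inh)
  expect_equal(f2$ic50 / f1$ic50, 3, tolerance = 1e-5)
})

test_that("no-effect plates are censored above the tested range", {
  set.seed(31)
  inh <- rnorm(7, 0, 1.5)
  fit <- fit_four_pl(grid7, inh)
  expect_true(fit$censored)
  expect_gt(fit$ic50, 1000)
})

test_that("noisy plates are refit with small median IC50 error", {
  set.seed(77)
  res <- vapply(1:30, function(i) {
    ic50 <- exp(runif(1, log(5), log(400)))
    inh_true <- fourpl_curve(grid7, ic50)
    od_nc <- 1.3; od_stsp <- 0.2
    od <- od_nc + (od_stsp - od_nc) * inh_true / 100 + rnorm(7, 0, 0.02)
    inh <- inhibition_ratio(od, od_nc + rnorm(1, 0, 0.02),
                            od_stsp + rnorm(1, 0, 0.02))
    fit <- fit_four_pl(grid7, inh)
    c(err = abs(fit$ic50 - ic50) / ic50,
      oracle_err = abs(fourpl_grid_ic50(grid7, inh) - ic50) / ic50)
  }, c(err = 0, oracle_err = 0))
  expect_lt(median(res["err", ]), 0.1)
  # the free-asymptote fit is at least as accurate as the fixed-asymptote
  # grid-search oracle on the same plates (up to the oracle's resolution)
  expect_lte(median(res["err", ]), median(res["oracle_err", ]) + 0.02)
})

test_that("replicate IC50s are summarized by their arithmetic mean", {
  s <- summarize_ic50(c(30, 40, 50))
  expect_equal(s$ic50, 40)
  expect_equal(s$inv_ic50, 1 / 40)
  expect_false(s$censored)
  expect_equal(summarize_ic50(35)$ic50, 35)
  s2 <- summarize_ic50(c(100, 2000), censored = c(FALSE, TRUE))
  expect_true(s2$censored)
})

test_that("group means are reported faithfully and identical groups give p near 1", {
  tox <- as_toxicity_table(batch = c("S1", "S2", "S3", "Z1", "Z2", "Z3"),
                           cell_line = "L02",
                           ic50 = c(100, 200, 300, 100, 200, 300))
  cmp <- compare_groups(tox)
  expect_equal(cmp$mean_raw, 200)
  expect_equal(cmp$mean_processed, 200)
  expect_gt(cmp$p_welch, 0.95)
  expect_error(compare_groups(tox[-(1:2), ]), "test error")
})

test_that("a three-fold processed IC50 shift is detected at p < 1e-4", {
  hits <- 0L
  for (s in 1:40) {
    set.seed(6000 + s)
    raw <- rlnorm(30, log(250), sqrt(log(1 + 0.3^2)))
    proc <- rlnorm(20, log(750), sqrt(log(1 + 0.3^2)))
    tox <- as_toxicity_table(c(sprintf("S%d", 1:30), sprintf("Z%d", 1:20)),
                             "L02", c(raw, proc))
    if (compare_groups(tox)$p_welch < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("plate tables flow through fitting into a toxicity table", {
  co <- generate_quant_cohort(cohort_spec(n_raw = 3, n_processed = 2,
                                          n_compounds = 4,
                                          planted_toxic = 1L, seed = 9))
  plates <- generate_dose_response_plates(co, od_noise_sd = 0, replicates = 2,
                                          seed = 4)
  tox <- plates_to_toxicity(plates)
  expect_s3_class(tox, "toxicity_table")
  expect_equal(nrow(tox), nrow(co$toxicity))
  merged <- merge(as.data.frame(tox), as.data.frame(co$toxicity),
                  by = c("batch", "cell_line"))
  in_range <- merged$ic50.y > min(grid7) & merged$ic50.y < max(grid7)
  expect_true(all(abs(merged$ic50.x - merged$ic50.y)[in_range] /
                    merged$ic50.y[in_range] < 1e-4))
})
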