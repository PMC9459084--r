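#' Specification of a synthetic raw/processed cohort
#'
#' Describes the statistical structure the spectrum-effect pipeline assumes:
#' log-normal compound peak areas, a compound-specific processing reduction
#' acting on the processed batches, and a latent linear model on the potency
#' scale, `1/IC50 = baseline + sum_j beta_j * area_j + noise`, with the
#' toxicity coefficients `beta` nonzero only on a planted marker subset.
#'
#' By default the cohort mirrors the reference study's conditions: 30 raw +
#' 20 processed batches, 16 compounds, markers X6/X7/X14, processing
#' reduction factors drawn from the published fold-change range
#' [0.137, 0.441] for the planted compounds, a 40% geometric CV for
#' abundances, a raw-group mean IC50 near 250 ug/ml, and two hepatocyte
#' lines (L02, HepG2) sharing the same toxic compounds.
#'
#' @param n_raw,n_processed Batch counts per group.
#' @param n_compounds Number of quantified compounds.
#' @param planted_toxic Integer indices of the toxicity markers.
#' @param reduction_factors Per-compound processed/raw ratio in (0, 1];
#'   `NULL` draws the planted compounds' factors uniformly from
#'   `fc_range` and leaves the rest at 1.
#' @param fc_range Range the planted reduction factors are drawn from.
#' @param toxicity_coefficients Per-compound `beta` (>= 0, nonzero only on
#'   the planted set); `NULL` calibrates them so the raw-group mean IC50 is
#'   `mean_raw_ic50`, split equally across markers.
#' @param baseline_inverse_ic50 Potency with no marker contribution
#'   (1/(ug/ml)).
#' @param mean_raw_ic50 Target raw-group mean IC50 used by the automatic
#'   beta calibration (ug/ml).
#' @param noise_cv Gaussian potency noise, as a fraction of the mean
#'   deterministic raw potency.
#' @param abundance_gcv Geometric coefficient of variation of the
#'   log-normal areas.
#' @param cell_lines Named numeric vector of cell-line potency multipliers.
#' @param seed Integer seed.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_raw = 30L, n_processed = 20L, n_compounds = 16L,
                        planted_toxic = c(6L, 7L, 14L),
                        reduction_factors = NULL,
                        fc_range = c(0.137, 0.441),
                        toxicity_coefficients = NULL,
                        baseline_inverse_ic50 = 1 / 3500,
                        mean_raw_ic50 = 250,
                        noise_cv = 0.1,
                        abundance_gcv = 0.4,
                        cell_lines = c(L02 = 1, HepG2 = 0.89),
                        seed = 1L) {
  if (!all(planted_toxic %in% seq_len(n_compounds))) {
    stop("spec error: planted_toxic must index 1..n_compounds")
  }
  if (!is.null(reduction_factors)) {
    if (length(reduction_factors) != n_compounds ||
        any(reduction_factors <= 0) || any(reduction_factors > 1)) {
      stop("spec error: reduction_factors must be length n_compounds in (0, 1]")
    }
  }
  if (any(fc_range <= 0) || any(fc_range > 1)) {
    stop("spec error: fc_range must lie in (0, 1]")
  }
  if (noise_cv < 0) stop("spec error: noise_cv must be >= 0")
  if (!is.null(toxicity_coefficients)) {
    if (length(toxicity_coefficients) != n_compounds ||
        any(toxicity_coefficients < 0)) {
      stop("spec error: toxicity_coefficients must be length n_compounds, >= 0")
    }
    if (any(toxicity_coefficients[-planted_toxic] != 0)) {
      stop("spec error: beta must be zero off the planted set")
    }
  }
  structure(list(n_raw = as.integer(n_raw),
                 n_processed = as.integer(n_processed),
                 n_compounds = as.integer(n_compounds),
                 planted_toxic = as.integer(planted_toxic),
                 reduction_factors = reduction_factors, fc_range = fc_range,
                 toxicity_coefficients = toxicity_coefficients,
                 baseline_inverse_ic50 = baseline_inverse_ic50,
                 mean_raw_ic50 = mean_raw_ic50, noise_cv = noise_cv,
                 abundance_gcv = abundance_gcv, cell_lines = cell_lines,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic quantification cohort with planted toxicity markers
#'
#' Draws log-normal raw-batch abundances per compound, multiplies processed
#' batches by the compound's reduction factor, and maps abundances to batch
#' potency `1/IC50` through the latent linear model of the spec (truncated
#' to keep IC50 finite and positive). Ground truth (planted indices, betas)
#' is carried along for recovery testing.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `quant` (a `quant_table`),
#'   `toxicity` (a `toxicity_table` over the spec's cell lines), `truth`
#'   (planted indices, compound names, betas, reduction factors), `spec`.
#' @export
generate_quant_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  p <- spec$n_compounds
  compounds <- paste0("X", seq_len(p))
  meanlog <- stats::runif(p, log(5e4), log(5e5))
  sdlog <- sqrt(log(1 + spec$abundance_gcv^2))
  red <- spec$reduction_factors
  if (is.null(red)) {
    red <- rep(1, p)
    red[spec$planted_toxic] <- stats::runif(length(spec$planted_toxic),
                                            spec$fc_range[1], spec$fc_range[2])
  }
  n <- spec$n_raw + spec$n_processed
  A <- matrix(stats::rlnorm(n * p, rep(meanlog, each = n), sdlog),
              nrow = n, dimnames = list(NULL, compounds))
  proc_rows <- spec$n_raw + seq_len(spec$n_processed)
  A[proc_rows, ] <- sweep(A[proc_rows, , drop = FALSE], 2, red, `*`)
  batches <- c(sprintf("S%d", seq_len(spec$n_raw)),
               sprintf("Z%d", seq_len(spec$n_processed)))
  quant <- as_quant_table(A, batches = batches)

  beta <- spec$toxicity_coefficients
  if (is.null(beta)) {
    # split the raw-group potency excess over baseline equally across markers
    total <- 1 / spec$mean_raw_ic50 - spec$baseline_inverse_ic50
    if (total <= 0) stop("spec error: mean_raw_ic50 above the baseline IC50")
    mean_area <- exp(meanlog + sdlog^2 / 2)
    beta <- numeric(p)
    beta[spec$planted_toxic] <-
      (total / length(spec$planted_toxic)) / mean_area[spec$planted_toxic]
  }
  det <- spec$baseline_inverse_ic50 + as.numeric(A %*% beta)
  tox <- do.call(rbind, lapply(names(spec$cell_lines), function(cl) {
    # multiplicative potency noise: noise_cv is a coefficient of variation,
    # so assay error scales with the batch potency instead of blowing up
    # the IC50 of weak batches
    inv <- spec$cell_lines[[cl]] * det * (1 + stats::rnorm(n, 0, spec$noise_cv))
    inv <- pmax(inv, 1e-6)  # keep IC50 finite and positive
    data.frame(batch = batches, cell_line = cl, ic50 = 1 / inv,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    quant = quant,
    toxicity = as_toxicity_table(tox$batch, tox$cell_line, tox$ic50),
    truth = list(planted_toxic = spec$planted_toxic,
                 planted_compounds = compounds[spec$planted_toxic],
                 beta = beta, reduction_factors = red, meanlog = meanlog),
    spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d batches x %d compounds; markers %s\n",
              nrow(x$quant), ncol(x$quant),
              paste(x$truth$planted_compounds, collapse = ", ")))
  invisible(x)
}

#' Simulate dose-response plates for a synthetic cohort
#'
#' For every batch, cell line and replicate, emits negative-control,
#' positive-control and per-concentration sample optical densities such that
#' the noise-free inhibition ratio follows a four-parameter logistic
#' (bottom 0, top 100) with midpoint at the batch's true IC50.
#'
#' @param cohort A `synthetic_cohort` (or any `toxicity_table` in
#'   `cohort$toxicity`).
#' @param grid Strictly increasing concentration grid (ug/ml); default the
#'   7-point assay grid 0.064-1000.
#' @param hill_slope Hill slope of the generating curve (> 0).
#' @param od_noise_sd Gaussian OD noise standard deviation (OD units).
#' @param od_nc,od_stsp Mean control optical densities.
#' @param replicates Parallel replicates per batch (default 3).
#' @param seed Integer seed.
#' @return Long data frame: `batch`, `cell_line`, `replicate`, `role`,
#'   `concentration`, `od`.
#' @export
generate_dose_response_plates <- function(cohort,
                                          grid = c(0.064, 0.32, 1.6, 8, 40,
                                                   200, 1000),
                                          hill_slope = 1, od_noise_sd = 0.02,
                                          od_nc = 1.3, od_stsp = 0.2,
                                          replicates = 3L, seed = 1L) {
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0)) {
    stop("spec error: grid must be strictly increasing and positive")
  }
  if (hill_slope <= 0) stop("spec error: hill_slope must be > 0")
  if (od_noise_sd < 0) stop("spec error: od_noise_sd must be >= 0")
  tox <- if (inherits(cohort, "synthetic_cohort")) cohort$toxicity else cohort
  set.seed(seed)
  rows <- lapply(seq_len(nrow(tox)), function(i) {
    ic50 <- tox$ic50[i]
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      inh <- 100 / (1 + (ic50 / grid)^hill_slope)
      od_s <- od_nc + (od_stsp - od_nc) * inh / 100
      data.frame(batch = tox$batch[i], cell_line = tox$cell_line[i],
                 replicate = r,
                 role = c("NC", "STSP", rep("sample", length(grid))),
                 concentration = c(NA, NA, grid),
                 od = c(od_nc, od_stsp, od_s) +
                   stats::rnorm(length(grid) + 2, 0, od_noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Generate an untargeted feature matrix with planted differential features
#'
#' Log-normal intensities for `n_features` ions over raw, processed and
#' pooled-QC samples. The planted differential features have a processed
#' group mean equal to the raw mean times a fold change drawn from
#' `fc_range`; QC samples are tight replicates of the grand mean.
#'
#' @param n_features Total feature count.
#' @param n_differential Number of planted reduced features
#'   (<= `n_features`).
#' @param n_raw,n_processed,n_qc Group sizes.
#' @param fc_range Fold-change range in (0, 1) for the planted features.
#' @param cv Within-group geometric CV of intensities (default 0.2).
#' @param qc_cv Geometric CV of the QC replicates (default 0.05).
#' @param seed Integer seed.
#' @return List with `matrix` (samples x features), `groups` (factor
#'   raw/processed/QC), `truth` (logical differential flag per feature),
#'   `fc` (true per-feature fold change).
#' @export
generate_metabolomics_matrix <- function(n_features = 200L,
                                         n_differential = 20L,
                                         n_raw = 23L, n_processed = 23L,
                                         n_qc = 6L,
                                         fc_range = c(0.137, 0.441),
                                         cv = 0.2, qc_cv = 0.05, seed = 1L) {
  if (n_differential > n_features) stop("n_differential must be <= n_features")
  if (any(fc_range <= 0) || any(fc_range >= 1)) {
    stop("spec error: fc_range must lie inside (0, 1)")
  }
  set.seed(seed)
  meanlog <- stats::runif(n_features, log(1e4), log(1e6))
  sdlog <- sqrt(log(1 + cv^2))
  sdlog_qc <- sqrt(log(1 + qc_cv^2))
  fc <- rep(1, n_features)
  diff_idx <- seq_len(n_differential)
  fc[diff_idx] <- stats::runif(n_differential, fc_range[1], fc_range[2])
  draw <- function(n, ml, sl) {
    matrix(stats::rlnorm(n * n_features, rep(ml, each = n), sl), nrow = n)
  }
  raw <- draw(n_raw, meanlog, sdlog)
  proc <- sweep(draw(n_processed, meanlog, sdlog), 2, fc, `*`)
  grand <- (colMeans(raw) * n_raw + colMeans(proc) * n_processed) /
    (n_raw + n_processed)
  qc <- sweep(draw(n_qc, rep(0, n_features), sdlog_qc), 2, grand, `*`)
  mat <- rbind(raw, proc, qc)
  rownames(mat) <- c(sprintf("S%d", seq_len(n_raw)),
                     sprintf("Z%d", seq_len(n_processed)),
                     sprintf("QC%d", seq_len(n_qc)))
  colnames(mat) <- sprintf("F%04d", seq_len(n_features))
  groups <- factor(c(rep("raw", n_raw), rep("processed", n_processed),
                     rep("QC", n_qc)), levels = c("raw", "processed", "QC"))
  list(matrix = mat, groups = groups,
       truth = seq_len(n_features) %in% diff_idx, fc = fc)
}
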