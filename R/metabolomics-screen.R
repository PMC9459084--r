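#' Normalize and scale an untargeted feature matrix
#'
#' Total-intensity normalization rescales every sample so its intensity sum
#' equals the cohort-median sum; unit-variance scaling centres each feature
#' and divides by its standard deviation, pareto scaling by the square root
#' of the standard deviation.
#'
#' @param matrix Numeric samples x features matrix, intensities >= 0.
#' @param normalization `"total-intensity"` or `"none"`.
#' @param scaling `"unit-variance"`, `"pareto"` or `"none"`.
#' @return Transformed matrix of the same shape.
#' @export
normalize_and_scale <- function(matrix,
                                normalization = c("total-intensity", "none"),
                                scaling = c("unit-variance", "pareto",
                                            "none")) {
  normalization <- match.arg(normalization)
  scaling <- match.arg(scaling)
  m <- as.matrix(matrix)
  if (any(m < 0)) stop("intensities must be >= 0")
  if (normalization == "total-intensity") {
    sums <- rowSums(m)
    if (any(sums == 0)) {
      stop("normalization error: all-zero sample(s): ",
           paste(rownames(m)[sums == 0], collapse = ", "))
    }
    m <- m * (stats::median(sums) / sums)
  }
  if (scaling != "none") {
    sds <- apply(m, 2, stats::sd)
    div <- if (scaling == "unit-variance") sds else sqrt(sds)
    div[div == 0] <- 1
    m <- scale(m, center = TRUE, scale = div)
  }
  m
}

#' Principal component analysis of a (scaled) feature matrix
#'
#' @param matrix Samples x features matrix, already normalized/scaled as
#'   desired.
#' @param n_components Number of components to keep.
#' @param center Centre columns before decomposition (default TRUE; set
#'   FALSE for pre-centred input).
#' @return List with `scores` (samples x k), `loadings` (features x k,
#'   orthonormal), `explained_variance` (fractions, non-increasing).
#' @export
fit_pca <- function(matrix, n_components = 2L, center = TRUE) {
  m <- as.matrix(matrix)
  if (n_components > min(nrow(m) - 1L, ncol(m))) {
    stop("dimension error: n_components exceeds min(samples - 1, features)")
  }
  pc <- stats::prcomp(m, center = center, scale. = FALSE, rank. = n_components)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance =
         (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)])
}

#' Per-feature univariate statistics between raw and processed groups
#'
#' Two-sided Welch t-test p-value and fold change (processed mean / raw
#' mean) per feature, QC samples excluded. Features identical in both
#' groups (zero variance, equal means) get `p = 1` and are flagged.
#'
#' @param matrix Samples x features intensity matrix (normalized, unscaled).
#' @param groups Factor/character per sample: `raw`, `processed`, `QC`.
#' @param log_transform Run the t-test on log2 intensities (default FALSE).
#' @return Data frame: `feature`, `p`, `fc`, `degenerate`.
#' @export
compute_univariate_stats <- function(matrix, groups, log_transform = FALSE) {
  m <- as.matrix(matrix)
  if (is.null(colnames(m))) colnames(m) <- sprintf("F%d", seq_len(ncol(m)))
  groups <- as.character(groups)
  raw <- m[groups == "raw", , drop = FALSE]
  proc <- m[groups == "processed", , drop = FALSE]
  if (nrow(raw) < 3 || nrow(proc) < 3) stop("each group needs >= 3 samples")
  tm <- if (log_transform) function(x) log2(x + 1) else identity
  res <- vapply(seq_len(ncol(m)), function(j) {
    a <- tm(raw[, j]); b <- tm(proc[, j])
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(c(p = 1, degenerate = 1))
    }
    c(p = stats::t.test(b, a)$p.value, degenerate = 0)
  }, c(p = 0, degenerate = 0))
  data.frame(feature = colnames(m), p = res["p", ],
             fc = colMeans(proc) / colMeans(raw),
             degenerate = as.logical(res["degenerate", ]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' VIP/p/fold-change screening cascade
#'
#' A feature is selected iff `VIP > vip_min` AND `p < p_max` AND
#' `FC < fc_max` (all strict), i.e. it is multivariately important,
#' univariately significant and reduced after processing.
#'
#' @param stats Data frame from [compute_univariate_stats()] with a `vip`
#'   column attached (or columns `feature`, `vip`, `p`, `fc`).
#' @param vip_min,p_max,fc_max Thresholds (defaults 1.5, 0.05, 0.5).
#' @return The `stats` data frame with a logical `selected` column.
#' @export
screen_differential <- function(stats, vip_min = 1.5, p_max = 0.05,
                                fc_max = 0.5) {
  if (vip_min <= 0 || p_max <= 0 || fc_max <= 0) {
    stop("config error: thresholds must be positive")
  }
  need <- c("feature", "vip", "p", "fc")
  if (!all(need %in% names(stats))) {
    stop("stats needs columns ", paste(need, collapse = ", "))
  }
  stats$selected <- stats$vip > vip_min & stats$p < p_max & stats$fc < fc_max
  stats
}

#' Full untargeted differential screening stage
#'
#' Normalizes the matrix, fits OPLS-DA (binary raw/processed response, QC
#' excluded) on the unit-variance scaled data for VIP, computes univariate
#' p and fold change on the normalized intensities, and applies the
#' screening cascade.
#'
#' @param matrix Raw samples x features intensity matrix.
#' @param groups Sample group labels (`raw` / `processed` / `QC`).
#' @param vip_min,p_max,fc_max Cascade thresholds.
#' @param normalization,scaling Preprocessing (see [normalize_and_scale()]).
#' @param n_orthogonal Orthogonal components of the OPLS-DA engine
#'   (default `"auto"`).
#' @return List with `stats` (screen table incl. `selected`), `model`
#'   (the OPLS-DA fit), `selected` (feature names).
#' @export
screen_feature_matrix <- function(matrix, groups, vip_min = 1.5,
                                  p_max = 0.05, fc_max = 0.5,
                                  normalization = "total-intensity",
                                  scaling = "unit-variance",
                                  n_orthogonal = "auto") {
  groups <- as.character(groups)
  norm <- normalize_and_scale(matrix, normalization, scaling = "none")
  keep <- groups %in% c("raw", "processed")
  scaled <- normalize_and_scale(norm[keep, , drop = FALSE],
                                normalization = "none", scaling = scaling)
  y <- ifelse(groups[keep] == "processed", 1, 0)
  model <- fit_opls(scaled, y, n_orthogonal = n_orthogonal)
  stats <- compute_univariate_stats(norm, groups)
  stats$vip <- unname(vip_scores(model))
  stats <- screen_differential(stats, vip_min, p_max, fc_max)
  list(stats = stats, model = model,
       selected = stats$feature[stats$selected])
}
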