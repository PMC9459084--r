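#' Analysis configuration for the spectrum-effect pipeline
#'
#' Bundles every tunable threshold of the stepwise analysis. Defaults follow
#' the reference study's settings where stated (screening VIP > 1.5,
#' p < 0.05, FC < 0.5; OPLS selection VIP > 0.7, coefficient < -0.1; 10
#' hidden units, 80/20 split; 7-point 0.064-1000 ug/ml dose grid) and field
#' conventions elsewhere (GRA rho 0.5, degree > 0.6; MIV delta 0.1).
#'
#' @param screening List: `vip_min`, `p_max`, `fc_max`.
#' @param gra List: `rho` in (0, 1], `normalization`, `degree_min`.
#' @param opls List: `n_orthogonal` (count or `"auto"`), `cv_folds`,
#'   `n_permutations` (0 disables the permutation test inside the
#'   pipeline), `vip_min`, `coef_max`.
#' @param ann List: `hidden_units`, `train_fraction`, `restarts`,
#'   `miv_delta`.
#' @param dose_response List: `grid` (ug/ml, strictly increasing),
#'   `censor_limit`.
#' @param seed Integer master seed for the stochastic stages.
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(screening = list(),
                            gra = list(),
                            opls = list(),
                            ann = list(),
                            dose_response = list(),
                            seed = 1L) {
  merge_opts <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown option(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    screening = merge_opts(list(vip_min = 1.5, p_max = 0.05, fc_max = 0.5),
                           screening),
    gra = merge_opts(list(rho = 0.5, normalization = "mean",
                          degree_min = 0.6), gra),
    opls = merge_opts(list(n_orthogonal = "auto", cv_folds = 7L,
                           n_permutations = 0L, vip_min = 0.7,
                           coef_max = -0.1), opls),
    ann = merge_opts(list(hidden_units = 10L, train_fraction = 0.8,
                          restarts = 5L, miv_delta = 0.1), ann),
    dose_response = merge_opts(list(grid = c(0.064, 0.32, 1.6, 8, 40, 200,
                                             1000),
                                    censor_limit = 1000), dose_response),
    seed = as.integer(seed))
  with(cfg, {
    stopifnot(gra$rho > 0, gra$rho <= 1,
              ann$train_fraction > 0, ann$train_fraction < 1,
              all(is.finite(unlist(screening))),
              all(diff(dose_response$grid) > 0),
              all(dose_response$grid > 0))
  })
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Top-level keys mirror the arguments of [analysis_config()]; missing keys
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y[intersect(names(y),
                                       c("screening", "gra", "opls", "ann",
                                         "dose_response", "seed"))])
}

#' Run the full spectrum-effect pipeline on a cohort
#'
#' For each cell line, aligns the quantification and toxicity tables over
#' batches, then runs the three engines — gray relational analysis against
#' the 1/IC50 reference series, single-response OPLS regression on IC50
#' with the VIP/coefficient rule, and the BP-ANN with MIV screening — and
#' combines their selections into the consensus marker set. Also returns
#' per-compound z-scored areas (the heat-map matrix) and group comparison
#' tests. Deterministic given `(inputs, config, seed)`.
#'
#' @param quant A `quant_table`.
#' @param toxicity A `toxicity_table` covering the same batches (one or more
#'   cell lines).
#' @param config An [analysis_config()].
#' @param out_dir Optional directory: when given, per-engine CSVs, the
#'   consensus table and a JSON summary are written there.
#' @return A `pm_report`: list with `per_cell_line` (engine outputs per cell
#'   line), `selections`, `consensus`, `ranked_markers`, `group_tests`,
#'   `zscore_matrix`, `config`.
#' @export
run_pipeline <- function(quant, toxicity, config = analysis_config(),
                         out_dir = NULL) {
  stopifnot(inherits(quant, "quant_table"))
  cell_lines <- unique(toxicity$cell_line)
  compounds <- colnames(quant)
  sel_gra <- sel_opls <- sel_ann <- list()
  per_cell <- list()
  for (cl in cell_lines) {
    tox_cl <- toxicity[toxicity$cell_line == cl, ]
    missing_tox <- setdiff(rownames(quant), tox_cl$batch)
    missing_quant <- setdiff(tox_cl$batch, rownames(quant))
    if (length(missing_tox) || length(missing_quant)) {
      stop("join error for cell line ", cl, ": batches missing from ",
           "toxicity table: [", paste(missing_tox, collapse = ", "),
           "]; missing from quant table: [",
           paste(missing_quant, collapse = ", "), "]")
    }
    X <- as.matrix(quant)[tox_cl$batch, , drop = FALSE]
    ic50 <- tox_cl$ic50

    gra <- relational_degree(1 / ic50, X, rho = config$gra$rho,
                             normalization = config$gra$normalization)
    sel_gra[[cl]] <- select_by_degree(gra, config$gra$degree_min)

    opls <- fit_opls(X, ic50, n_orthogonal = config$opls$n_orthogonal,
                     cv_folds = config$opls$cv_folds)
    sel_opls[[cl]] <- select_by_vip_coefficient(opls, config$opls$vip_min,
                                                config$opls$coef_max)
    perm <- if (config$opls$n_permutations > 0) {
      permutation_test(X, ic50,
                       n_permutations = config$opls$n_permutations,
                       n_orthogonal = opls$n_orthogonal,
                       folds = config$opls$cv_folds, seed = config$seed)
    }

    ann <- train_bpann(X, ic50, hidden_units = config$ann$hidden_units,
                       train_fraction = config$ann$train_fraction,
                       seed = config$seed, restarts = config$ann$restarts)
    miv <- mean_impact_value(ann, X, delta = config$ann$miv_delta)
    sel_ann[[cl]] <- select_by_miv(miv)

    per_cell[[cl]] <- list(gra = gra, opls = opls, permutation = perm,
                           ann = ann, miv = miv,
                           garson = garson_sensitivity(ann))
  }
  selections <- model_selections(gra = sel_gra, opls = sel_opls,
                                 bpann = sel_ann)
  consensus <- across_model_intersection(selections)
  ranked <- if (length(consensus$markers)) {
    ev <- do.call(cbind, lapply(cell_lines, function(cl) {
      pc <- per_cell[[cl]]
      cbind(gra = pc$gra$degree[compounds],
            opls = abs(pc$opls$coefficients[compounds]) *
              pc$opls$vip[compounds],
            miv = abs(pc$miv[compounds]))
    }))
    rownames(ev) <- compounds
    colnames(ev) <- paste(rep(cell_lines, each = 3),
                          c("gra", "opls_coef_vip", "abs_miv"), sep = "_")
    rank_markers(consensus, ev)
  }
  report <- structure(list(
    per_cell_line = per_cell, selections = selections,
    consensus = consensus, ranked_markers = ranked,
    group_tests = compare_groups(toxicity),
    zscore_matrix = scale(as.matrix(quant)),
    config = config), class = "pm_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pm_report <- function(x, ...) {
  cat("spectrum-effect pipeline report\n")
  print(x$consensus)
  cat("group comparison (IC50, processed vs raw):\n")
  print(x$group_tests, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits `selections.csv` (engine x cell line x compound), `consensus.csv`,
#' `group_tests.csv`, `zscore_matrix.csv` and `summary.json`.
#'
#' @param report A `pm_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$consensus$provenance,
                   file.path(out_dir, "selections.csv"), row.names = FALSE)
  cons <- data.frame(compound = report$consensus$markers)
  utils::write.csv(cons, file.path(out_dir, "consensus.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_tests, file.path(out_dir, "group_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(batch = rownames(report$zscore_matrix),
                              report$zscore_matrix, check.names = FALSE),
                   file.path(out_dir, "zscore_matrix.csv"), row.names = FALSE)
  summary <- list(
    markers = report$consensus$markers,
    per_engine_common = report$consensus$per_engine,
    model_stats = lapply(report$per_cell_line, function(pc) {
      list(opls = list(R2X = pc$opls$R2X, R2Y = pc$opls$R2Y,
                       Q2 = pc$opls$Q2,
                       n_orthogonal = pc$opls$n_orthogonal),
           permutation_pass = if (!is.null(pc$permutation)) pc$permutation$pass,
           ann = pc$ann$metrics)
    }))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
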