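#' Read a batch-by-compound peak-area table
#'
#' Reads a comma-separated quantification table with one batch per row (first
#' column `batch`) and one column per MRM-quantified compound. Group labels
#' (`raw` / `processed`) are attached per batch, by default inferred from the
#' batch-ID prefix used for raw/processed herbal cohorts (`S` = raw,
#' `Z` = processed).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param compounds Optional character vector of expected compound columns.
#'   Columns not listed are dropped with a warning; a listed column that is
#'   missing is an error. `NULL` keeps every non-batch column.
#' @param group_map Optional named character vector mapping batch IDs to
#'   `"raw"` or `"processed"`. When `NULL`, groups are inferred from the
#'   `S`/`Z` ID prefix.
#' @return A `quant_table`: data frame of peak areas with row names the batch
#'   IDs, compound columns in file order, and a `group` factor stored in
#'   `attr(, "group")`.
#' @export
read_quant_table <- function(path, compounds = NULL, group_map = NULL) {
  if (!file.exists(path)) stop("quant table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("format error: quant table at ", path,
         " must have a 'batch' column plus at least one compound column")
  }
  id_col <- if ("batch" %in% names(df)) "batch" else names(df)[1L]
  batches <- as.character(df[[id_col]])
  areas <- df[setdiff(names(df), id_col)]
  if (!is.null(compounds)) {
    missing <- setdiff(compounds, names(areas))
    if (length(missing)) {
      stop("format error: missing compound column(s): ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(names(areas), compounds)
    if (length(extra)) {
      warning("ignoring unexpected column(s): ", paste(extra, collapse = ", "))
      areas <- areas[compounds]
    }
  }
  areas[] <- lapply(areas, as.numeric)
  as_quant_table(areas, batches = batches, group = resolve_groups(batches, group_map))
}

#' Construct a quant_table from in-memory values
#'
#' @param areas Data frame or matrix of non-negative peak areas
#'   (batches x compounds).
#' @param batches Character batch IDs (row names used when missing).
#' @param group Factor/character of `"raw"`/`"processed"` per batch.
#' @return A `quant_table` data frame.
#' @export
as_quant_table <- function(areas, batches = rownames(areas), group = NULL) {
  areas <- as.data.frame(areas, check.names = FALSE)
  if (is.null(batches)) stop("batch IDs are required")
  if (anyDuplicated(batches)) stop("duplicate batch IDs")
  bad <- vapply(areas, function(x) any(!is.finite(x)) || any(x < 0), logical(1))
  if (any(bad)) {
    stop("validation error: negative or non-finite areas in compound(s): ",
         paste(names(areas)[bad], collapse = ", "))
  }
  rownames(areas) <- batches
  if (is.null(group)) group <- resolve_groups(batches, NULL)
  group <- factor(as.character(group), levels = c("raw", "processed"))
  if (anyNA(group)) stop("every batch needs a 'raw' or 'processed' group label")
  attr(areas, "group") <- group
  class(areas) <- c("quant_table", "data.frame")
  areas
}

resolve_groups <- function(batches, group_map) {
  if (!is.null(group_map)) {
    g <- unname(group_map[batches])
    if (anyNA(g)) {
      stop("group label missing for batch(es): ",
           paste(batches[is.na(g)], collapse = ", "))
    }
    return(g)
  }
  g <- ifelse(startsWith(toupper(batches), "S"), "raw",
              ifelse(startsWith(toupper(batches), "Z"), "processed", NA))
  if (anyNA(g)) {
    stop("cannot infer raw/processed group from batch ID(s): ",
         paste(batches[is.na(g)], collapse = ", "), "; supply group_map")
  }
  g
}

#' @export
print.quant_table <- function(x, ...) {
  g <- table(attr(x, "group"))
  cat(sprintf("quant_table: %d batches (%d raw, %d processed) x %d compounds\n",
              nrow(x), g[["raw"]], g[["processed"]], ncol(x)))
  invisible(x)
}

#' Write a quant_table to CSV
#'
#' Inverse of [read_quant_table()]: full double precision, so a write/read
#' round trip reproduces values bit-identically.
#'
#' @param quant A `quant_table`.
#' @param path Output CSV path.
#' @export
write_quant_table <- function(quant, path) {
  df <- data.frame(batch = rownames(quant), quant, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a batch x cell-line IC50 table
#'
#' Accepts either one row per batch/cell line with a mean `ic50`, or several
#' replicate rows per batch/cell line (column `replicate`), which are averaged.
#'
#' @param path CSV with columns `batch`, `cell_line`, `ic50` and optionally
#'   `replicate` and `censored`.
#' @param group_map Optional batch ID to group mapping, as in
#'   [read_quant_table()].
#' @return A `toxicity_table`: data frame with columns `batch`, `cell_line`,
#'   `group`, `ic50`, `inv_ic50`, `censored`.
#' @export
read_toxicity_table <- function(path, group_map = NULL) {
  if (!file.exists(path)) stop("toxicity table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("batch", "cell_line", "ic50")
  if (!all(need %in% names(df))) {
    stop("format error: toxicity table needs columns ",
         paste(need, collapse = ", "))
  }
  if (!"censored" %in% names(df)) df$censored <- FALSE
  if ("replicate" %in% names(df)) {
    agg <- stats::aggregate(cbind(ic50 = df$ic50) ~ batch + cell_line, df, mean)
    cen <- stats::aggregate(cbind(censored = df$censored) ~ batch + cell_line,
                            df, function(x) any(as.logical(x)))
    df <- merge(agg, cen, by = c("batch", "cell_line"))
  }
  as_toxicity_table(df$batch, df$cell_line, df$ic50,
                    censored = as.logical(df$censored), group_map = group_map)
}

#' Construct a toxicity_table
#'
#' @param batch,cell_line,ic50 Vectors of equal length; `ic50` in ug/ml, > 0.
#' @param censored Logical flag per row: IC50 extrapolated beyond the tested
#'   concentration range.
#' @param group_map Optional batch ID to group mapping.
#' @return A `toxicity_table` data frame (adds `group` and `inv_ic50`).
#' @export
as_toxicity_table <- function(batch, cell_line, ic50, censored = FALSE,
                              group_map = NULL) {
  ic50 <- as.numeric(ic50)
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("validation error: IC50 values must be finite and positive")
  }
  out <- data.frame(batch = as.character(batch),
                    cell_line = as.character(cell_line),
                    group = resolve_groups(as.character(batch), group_map),
                    ic50 = ic50, inv_ic50 = 1 / ic50,
                    censored = rep_len(as.logical(censored), length(ic50)),
                    stringsAsFactors = FALSE)
  class(out) <- c("toxicity_table", "data.frame")
  out
}

#' Write a toxicity_table to CSV
#' @param toxicity A `toxicity_table`.
#' @param path Output CSV path.
#' @export
write_toxicity_table <- function(toxicity, path) {
  utils::write.csv(format(as.data.frame(toxicity), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Method-validation QC metrics for a quantification method
#'
#' Computes the relative standard deviation (RSD) of replicate peak areas per
#' compound (repeatability / precision / stability checks) and the Pearson
#' linearity of peak area against injected volume.
#'
#' @param replicate_areas Named list: per compound, a numeric vector of
#'   replicate peak areas (>= 3 replicates).
#' @param linearity_pairs Optional named list: per compound, a two-column
#'   matrix or data frame of (injected volume, peak area) with >= 3 points.
#' @return A data frame with columns `compound`, `rsd_percent` and (when
#'   linearity data are given) `linearity_r`.
#' @export
compute_validation_metrics <- function(replicate_areas, linearity_pairs = NULL) {
  if (!length(replicate_areas)) stop("no replicate series supplied")
  rsd <- vapply(names(replicate_areas), function(cmp) {
    x <- as.numeric(replicate_areas[[cmp]])
    if (length(x) < 3) stop("need >= 3 replicates for ", cmp)
    m <- mean(x)
    if (m == 0) stop("undefined RSD: mean area of ", cmp, " is zero")
    100 * stats::sd(x) / m
  }, numeric(1))
  out <- data.frame(compound = names(replicate_areas), rsd_percent = unname(rsd),
                    stringsAsFactors = FALSE)
  if (!is.null(linearity_pairs)) {
    r <- vapply(names(linearity_pairs), function(cmp) {
      xy <- as.data.frame(linearity_pairs[[cmp]])
      if (nrow(xy) < 3) stop("need >= 3 linearity points for ", cmp)
      stats::cor(xy[[1]], xy[[2]])
    }, numeric(1))
    out$linearity_r <- unname(r[match(out$compound, names(r))])
  }
  out
}

#' Reference model-score table for the published 50-batch cohort
#'
#' Per-compound summary scores reported for the 50-batch raw/processed
#' *Polygonum multiflorum* cohort on L02 and HepG2 hepatocytes: gray
#' relational degrees, OPLS standardized coefficients ("R values"), Garson
#' sensitivity percentages and mean impact values. Used to exercise the
#' selection rules on real reported numbers.
#'
#' @return Data frame with one row per compound (X1..X16).
#' @export
pm_model_scores <- function() {
  utils::read.csv(system.file("extdata", "pm_model_scores.csv",
                              package = "pmtox"),
                  stringsAsFactors = FALSE)
}

#' Compound panel of the pseudotargeted MRM method
#'
#' The 16 MRM-quantified compounds (dianthrones, anthraquinone glycosides,
#' stilbene glycosides, flavanols) with their structural class.
#'
#' @return Data frame with columns `compound`, `name`, `class`.
#' @export
pm_compound_panel <- function() {
  utils::read.csv(system.file("extdata", "pm_compound_panel.csv",
                              package = "pmtox"),
                  stringsAsFactors = FALSE)
}

#' Differential-feature screening results for the reference cohort
#'
#' VIP, p and fold-change values of the 13 identified differential compounds
#' retained by the untargeted screening cascade in the reference cohort.
#'
#' @return Data frame with columns `compound`, `rt_mz`, `vip`, `p_value`, `fc`.
#' @export
pm_differential_features <- function() {
  utils::read.csv(system.file("extdata", "pm_differential_features.csv",
                              package = "pmtox"),
                  stringsAsFactors = FALSE)
}
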