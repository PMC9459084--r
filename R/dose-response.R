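#' Inhibition ratio from plate optical densities
#'
#' `100 * (OD_S - OD_NC) / (OD_STSP - OD_NC)`, where the negative control
#' (cells + vehicle) defines 0% and the positive kill control (staurosporine)
#' defines 100% inhibition. With noisy plates the ratio may fall outside
#' `[0, 100]`.
#'
#' @param od_s Sample well optical density (vectorized).
#' @param od_nc Negative-control optical density.
#' @param od_stsp Positive-control optical density.
#' @return Inhibition percentage(s).
#' @export
inhibition_ratio <- function(od_s, od_nc, od_stsp) {
  if (any(od_stsp == od_nc)) {
    stop("degenerate-control error: OD_STSP equals OD_NC")
  }
  100 * (od_s - od_nc) / (od_stsp - od_nc)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `inhibition = bottom + (top - bottom) / (1 + (ic50/conc)^hill)` on the
#' log-concentration axis, with multi-start initialization (IC50 seeded at
#' the concentration bracketing the half-maximal response; hill started at
#' 0.5, 1 and 2). The reported IC50 is the *relative* one: the concentration
#' at the midpoint between fitted bottom and top. Fits whose IC50 exceeds
#' the highest tested concentration are flagged censored, not dropped.
#'
#' @param concentrations Strictly increasing dose grid (ug/ml), length >= 5.
#' @param inhibitions Inhibition percentages, same length.
#' @param censor_limit Concentration above which the IC50 is flagged
#'   censored (default the top tested concentration).
#' @return A `dose_response_curve`: list with `ic50`, `bottom`, `top`,
#'   `hill`, `sse`, `censored`, plus the data.
#' @export
fit_four_pl <- function(concentrations, inhibitions,
                        censor_limit = max(concentrations)) {
  conc <- as.numeric(concentrations); inh <- as.numeric(inhibitions)
  if (length(conc) < 5) stop("need >= 5 concentration points")
  if (is.unsorted(conc, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  if (any(conc <= 0)) stop("concentrations must be positive")
  lc <- log(conc)
  if (diff(range(inh)) < 10 && max(inh) < 50) {
    # no measurable response anywhere on the grid: the half-maximal
    # concentration lies beyond it and a 4PL midpoint is unidentifiable
    return(structure(list(concentrations = conc, inhibitions = inh,
                          bottom = min(inh), top = max(inh),
                          ic50 = censor_limit * 10, hill = NA_real_,
                          sse = sum((inh - mean(inh))^2), censored = TRUE),
                     class = "dose_response_curve"))
  }
  df <- data.frame(lc = lc, inh = inh)
  # IC50 start: first concentration where inhibition crosses the half range
  half <- (min(inh) + max(inh)) / 2
  above <- which(inh >= half)
  l50 <- if (length(above) && min(above) > 1) {
    i <- min(above)
    mean(lc[c(i - 1, i)])
  } else stats::median(lc)
  best <- NULL
  starts <- expand.grid(hill = c(0.5, 1, 2),
                        bottom = c(max(min(inh), -10), 0),
                        top = c(min(max(inh), 110), 100),
                        l50 = c(l50, stats::median(lc)))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        inh ~ bottom + (top - bottom) / (1 + exp(hill * (l50_ - lc))),
        data = df,
        start = list(bottom = starts$bottom[i], top = starts$top[i],
                     l50_ = starts$l50[i], hill = starts$hill[i]),
        lower = c(bottom = -50, top = 0, l50_ = min(lc) - 6, hill = 0.05),
        upper = c(bottom = 50, top = 200, l50_ = max(lc) + 6, hill = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
      if (best$sse < 1e-10) break
    }
  }
  if (is.null(best)) {
    stop("fit error: four-parameter logistic did not converge from any start")
  }
  cf <- stats::coef(best$fit)
  ic50 <- exp(cf[["l50_"]])
  if (stats::cor(lc, inh) < -0.2 && diff(range(inh)) > 20) {
    warning("inhibition decreases with concentration beyond noise tolerance")
  }
  structure(list(concentrations = conc, inhibitions = inh,
                 bottom = cf[["bottom"]], top = cf[["top"]], ic50 = ic50,
                 hill = cf[["hill"]], sse = best$sse,
                 censored = ic50 > censor_limit),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("4PL fit: IC50 %.4g ug/ml%s (bottom %.1f, top %.1f, hill %.2f, SSE %.3g)\n",
              x$ic50, if (x$censored) " [censored]" else "", x$bottom, x$top,
              x$hill, x$sse))
  invisible(x)
}

#' Summarize replicate IC50 fits into one batch value
#'
#' @param curves List of `dose_response_curve` fits (parallel replicates of
#'   one batch/cell line), or a numeric vector of replicate IC50s.
#' @param censored Logical per replicate when `curves` is numeric.
#' @return List with `ic50` (arithmetic mean of replicates), `inv_ic50`,
#'   `censored` (TRUE when any replicate was censored), `n`.
#' @export
summarize_ic50 <- function(curves, censored = FALSE) {
  if (is.numeric(curves)) {
    vals <- curves
    cen <- rep_len(censored, length(vals))
  } else {
    vals <- vapply(curves, `[[`, numeric(1), "ic50")
    cen <- vapply(curves, `[[`, logical(1), "censored")
  }
  if (!length(vals)) stop("need at least one replicate")
  m <- mean(vals)
  list(ic50 = m, inv_ic50 = 1 / m, censored = any(cen), n = length(vals))
}

#' Fit every plate in a long plate table and build a toxicity table
#'
#' @param plates Data frame with columns `batch`, `cell_line`, `replicate`,
#'   `role` (`sample`/`NC`/`STSP`), `concentration`, `od` — one row per well.
#' @param group_map Optional batch-to-group mapping.
#' @return A `toxicity_table` with one row per batch x cell line.
#' @export
plates_to_toxicity <- function(plates, group_map = NULL) {
  need <- c("batch", "cell_line", "replicate", "role", "concentration", "od")
  if (!all(need %in% names(plates))) {
    stop("plate table needs columns ", paste(need, collapse = ", "))
  }
  keys <- unique(plates[c("batch", "cell_line")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- plates[plates$batch == keys$batch[i] &
                    plates$cell_line == keys$cell_line[i], ]
    curves <- lapply(split(sub, sub$replicate), function(rep_df) {
      od_nc <- mean(rep_df$od[rep_df$role == "NC"])
      od_stsp <- mean(rep_df$od[rep_df$role == "STSP"])
      s <- rep_df[rep_df$role == "sample", ]
      s <- s[order(s$concentration), ]
      fit_four_pl(s$concentration,
                  inhibition_ratio(s$od, od_nc, od_stsp))
    })
    sm <- summarize_ic50(curves)
    data.frame(batch = keys$batch[i], cell_line = keys$cell_line[i],
               ic50 = sm$ic50, censored = sm$censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  as_toxicity_table(out$batch, out$cell_line, out$ic50,
                    censored = out$censored, group_map = group_map)
}

#' Compare IC50 between raw and processed batches
#'
#' Per cell line, a two-sided Welch t-test and a Mann-Whitney U test of the
#' batch IC50s by group.
#'
#' @param toxicity A `toxicity_table`.
#' @return Data frame per cell line with group means, Welch statistic and p,
#'   and Mann-Whitney p.
#' @export
compare_groups <- function(toxicity) {
  do.call(rbind, lapply(split(as.data.frame(toxicity), toxicity$cell_line),
    function(sub) {
      raw <- sub$ic50[sub$group == "raw"]
      proc <- sub$ic50[sub$group == "processed"]
      if (length(raw) < 2 || length(proc) < 2) {
        stop("test error: each group needs >= 2 batches")
      }
      tt <- stats::t.test(proc, raw)
      wt <- suppressWarnings(stats::wilcox.test(proc, raw))
      data.frame(cell_line = sub$cell_line[1],
                 mean_raw = mean(raw), mean_processed = mean(proc),
                 t_statistic = unname(tt$statistic), p_welch = tt$p.value,
                 p_mann_whitney = wt$p.value, stringsAsFactors = FALSE)
    }))
}
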