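#' Per-engine selections container
#'
#' @param gra,opls,bpann Named lists mapping cell line to a character vector
#'   of selected compounds, e.g. `list(L02 = c("X6"), HepG2 = c("X6"))`.
#' @return A `model_selections` list.
#' @export
model_selections <- function(gra = NULL, opls = NULL, bpann = NULL) {
  sel <- list(GRA = gra, OPLS = opls, `BP-ANN` = bpann)
  structure(sel[!vapply(sel, is.null, logical(1))],
            class = "model_selections")
}

#' Compounds retained by one engine in every cell line
#'
#' @param selections A `model_selections` (or plain named list of engines).
#' @param engine Engine name, e.g. `"OPLS"`.
#' @return Character vector: intersection over the engine's cell lines.
#' @export
within_model_common <- function(selections, engine) {
  if (!engine %in% names(selections)) {
    stop("input error: no selections for engine ", engine)
  }
  cl <- selections[[engine]]
  if (length(cl) < 1 || is.null(names(cl)) || any(!nzchar(names(cl)))) {
    stop("input error: engine ", engine, " needs named per-cell-line sets")
  }
  Reduce(intersect, cl)
}

#' Final marker set: intersection of the per-engine common sets
#'
#' The paper's narrative order: intersect within each engine across cell
#' lines first, then across engines. Empty engine sets trigger a warning but
#' still participate (the consensus may legitimately be empty).
#'
#' @param selections A `model_selections` over >= 2 engines.
#' @return A `consensus_result`: list with `markers`, `per_engine` (common
#'   set per engine), `provenance` (long data frame of every retaining
#'   engine/cell line per compound).
#' @export
across_model_intersection <- function(selections) {
  if (length(selections) < 2) stop("need selections from >= 2 engines")
  per_engine <- lapply(names(selections), function(e)
    within_model_common(selections, e))
  names(per_engine) <- names(selections)
  empty <- !lengths(per_engine)
  if (any(empty)) {
    warning("engine(s) with empty common set: ",
            paste(names(per_engine)[empty], collapse = ", "))
  }
  markers <- Reduce(intersect, per_engine)
  prov <- do.call(rbind, unlist(lapply(names(selections), function(e) {
    lapply(names(selections[[e]]), function(cl) {
      cmp <- selections[[e]][[cl]]
      if (!length(cmp)) return(NULL)
      data.frame(compound = cmp, engine = e, cell_line = cl,
                 stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  structure(list(markers = markers, per_engine = per_engine,
                 provenance = prov),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus toxicity markers:",
      if (length(x$markers)) paste(x$markers, collapse = ", ") else "(none)",
      "\n")
  for (e in names(x$per_engine)) {
    cat(sprintf("  %-7s common set: %s\n", e,
                paste(x$per_engine[[e]], collapse = ", ")))
  }
  invisible(x)
}

#' Rank consensus markers by mean rank over evidence columns
#'
#' Each evidence column (e.g. GRA degree, OPLS |coefficient| x VIP, |MIV|)
#' is ranked with the largest value best; markers are ordered by the mean of
#' their ranks, ties broken by compound index order.
#'
#' @param consensus A `consensus_result` (or character marker vector).
#' @param evidence Data frame/matrix of evidence values, rows named by
#'   compound, larger = stronger toxicity evidence.
#' @return Data frame `compound`, `mean_rank`, one rank column per evidence
#'   column, ordered best first.
#' @export
rank_markers <- function(consensus, evidence) {
  markers <- if (inherits(consensus, "consensus_result")) consensus$markers
             else as.character(consensus)
  if (!length(markers)) stop("consensus is empty; nothing to rank")
  ev <- as.matrix(evidence)[markers, , drop = FALSE]
  ranks <- apply(-ev, 2, rank, ties.method = "average")
  if (length(markers) == 1L) ranks <- matrix(ranks, nrow = 1)
  mean_rank <- rowMeans(ranks)
  ord <- order(mean_rank, match(markers, rownames(as.matrix(evidence))))
  out <- data.frame(compound = markers, mean_rank = mean_rank,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ranks))
  out[ord, , drop = FALSE]
}
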