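#' Dimensionless transform of a series for gray relational analysis
#'
#' GRA compares the *shape* of series, so each series is made dimensionless
#' first: `mean` divides by the series mean, `initial` by the first element,
#' `minmax` maps onto `[0, 1]`.
#'
#' @param series Numeric vector.
#' @param method One of `"mean"`, `"initial"`, `"minmax"`.
#' @return Transformed numeric vector.
#' @export
dimensionless_transform <- function(series,
                                    method = c("mean", "initial", "minmax")) {
  method <- match.arg(method)
  x <- as.numeric(series)
  switch(method,
    mean = {
      m <- mean(x)
      if (m == 0) stop("transform error: series mean is zero")
      x / m
    },
    initial = {
      if (x[1] == 0) stop("transform error: first element is zero")
      x / x[1]
    },
    minmax = {
      r <- range(x)
      if (r[1] == r[2]) stop("transform error: constant series under minmax")
      (x - r[1]) / (r[2] - r[1])
    })
}

#' Gray relational degree of compound series against a reference series
#'
#' Deng's gray relational analysis: after a dimensionless transform, the
#' absolute deviation between the reference series (here typically the
#' 1/IC50 potency series over batches) and each comparison series (compound
#' peak areas) is turned into per-point relational coefficients
#' `(d_min + rho * d_max) / (d_ik + rho * d_max)`, with the two-level
#' extrema `d_min`/`d_max` taken over all comparison series and points. The
#' relational degree of a compound is the mean of its coefficients.
#'
#' @param reference Numeric reference series (length n >= 3).
#' @param comparisons Numeric matrix or data frame, one column per compound,
#'   n rows.
#' @param rho Resolution coefficient in (0, 1], default 0.5.
#' @param normalization Dimensionless method applied to all series
#'   (see [dimensionless_transform()]); `"none"` assumes pre-transformed data.
#' @return A `gra_result`: list with `degree` (named, sorted decreasing),
#'   `coefficients` (n x compounds matrix), `rho`, `normalization`.
#' @export
relational_degree <- function(reference, comparisons, rho = 0.5,
                              normalization = c("mean", "initial", "minmax",
                                                "none")) {
  normalization <- match.arg(normalization)
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  comparisons <- as.matrix(comparisons)
  if (length(reference) != nrow(comparisons)) {
    stop("dimension error: reference and comparison series lengths differ")
  }
  if (length(reference) < 3) stop("need series of length >= 3")
  tf <- function(x) if (normalization == "none") as.numeric(x) else
    dimensionless_transform(x, normalization)
  x0 <- tf(reference)
  xi <- apply(comparisons, 2, tf)
  delta <- abs(xi - x0)
  dmin <- min(delta)
  dmax <- max(delta)
  coefs <- if (dmax == 0) {
    # every comparison series identical to the reference: perfect relation
    array(1, dim(delta), dimnames = dimnames(delta))
  } else {
    (dmin + rho * dmax) / (delta + rho * dmax)
  }
  degree <- colMeans(coefs)
  structure(list(degree = sort(degree, decreasing = TRUE),
                 coefficients = coefs, rho = rho,
                 normalization = normalization),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat(sprintf("gray relational degrees (rho = %.2f, %s-normalized):\n",
              x$rho, x$normalization))
  print(round(x$degree, 3))
  invisible(x)
}

#' Threshold gray relational degrees
#'
#' @param result A `gra_result`, or any list with a named `degree` element.
#' @param degree_min Retain compounds with degree strictly above this
#'   (default 0.6).
#' @return Character vector of compounds ranked by decreasing degree.
#' @export
select_by_degree <- function(result, degree_min = 0.6) {
  d <- sort(result$degree, decreasing = TRUE)
  names(d[d > degree_min])
}
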