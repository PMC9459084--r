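#' Train a three-layer back-propagation network on compound areas vs IC50
#'
#' Fits a feedforward network with one hidden layer (default 10 units,
#' sigmoid activation) and a linear output, mapping min-max scaled peak
#' areas to the min-max scaled IC50. Training uses [nnet::nnet()] with a
#' small weight decay; several random restarts are made under one master
#' seed and the restart with the best validation mean squared error is kept.
#'
#' @param X Numeric matrix (batches x compounds), original units.
#' @param y Numeric response (IC50 per batch), original units.
#' @param hidden_units Hidden layer size (default 10).
#' @param train_fraction Fraction of samples used for training; the rest is
#'   the validation split (default 0.8).
#' @param seed Master integer seed (split and all restarts derive from it).
#' @param restarts Random weight restarts (default 5).
#' @param decay Weight decay passed to the optimizer (default 1e-3).
#' @param maxit Maximum optimizer iterations per restart (default 2000).
#' @return A `bpann` model: input-hidden weights `w` (inputs x hidden),
#'   hidden biases `hidden_bias`, hidden-output weights `e`, `output_bias`,
#'   min-max scaling parameters, split indices, and `metrics` (MSE on the
#'   scaled response and Pearson R, for train and validation splits).
#' @export
train_bpann <- function(X, y, hidden_units = 10L, train_fraction = 0.8,
                        seed = 1L, restarts = 5L, decay = 1e-3,
                        maxit = 2000L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("data error: non-finite inputs")
  n <- nrow(X)
  if (n != length(y)) stop("dimension error: nrow(X) != length(y)")
  if (n < 15) stop("need at least 15 samples")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  x_min <- apply(X, 2, min); x_max <- apply(X, 2, max)
  if (any(x_max == x_min)) stop("data error: constant input column")
  y_min <- min(y); y_max <- max(y)
  if (y_max == y_min) stop("data error: constant response")
  Xs <- scale(X, center = x_min, scale = x_max - x_min)
  ys <- (y - y_min) / (y_max - y_min)

  set.seed(seed)
  train_idx <- sort(sample.int(n, floor(train_fraction * n)))
  val_idx <- setdiff(seq_len(n), train_idx)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- nnet::nnet(Xs[train_idx, , drop = FALSE], ys[train_idx],
                      size = hidden_units, linout = TRUE, decay = decay,
                      maxit = maxit, trace = FALSE)
    val_pred <- as.numeric(stats::predict(fit, Xs[val_idx, , drop = FALSE]))
    val_mse <- mean((ys[val_idx] - val_pred)^2)
    if (is.null(best) || val_mse < best$val_mse) {
      best <- list(fit = fit, val_mse = val_mse)
    }
  }
  fit <- best$fit
  m <- ncol(X); h <- hidden_units
  wm <- matrix(fit$wts[seq_len((m + 1) * h)], nrow = m + 1)
  out_w <- fit$wts[((m + 1) * h + 1):length(fit$wts)]
  model <- structure(list(
    w = matrix(wm[-1, , drop = FALSE], nrow = m,
               dimnames = list(colnames(X), NULL)),
    hidden_bias = wm[1, ], e = out_w[-1], output_bias = out_w[1],
    x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
    hidden_units = h, train_idx = train_idx, val_idx = val_idx,
    seed = seed), class = "bpann")
  pr_tr <- predict(model, X[train_idx, , drop = FALSE])
  pr_va <- predict(model, X[val_idx, , drop = FALSE])
  sc <- function(v) (v - y_min) / (y_max - y_min)
  model$metrics <- list(
    train = list(mse = mean((sc(y[train_idx]) - sc(pr_tr))^2),
                 r = stats::cor(y[train_idx], pr_tr)),
    validation = list(mse = mean((sc(y[val_idx]) - sc(pr_va))^2),
                      r = stats::cor(y[val_idx], pr_va)))
  model
}

#' Predict IC50 from a trained bpann model
#' @param object A `bpann` model.
#' @param newdata Matrix of compound areas, original units.
#' @param ... Unused.
#' @return Predicted response on the original scale.
#' @export
predict.bpann <- function(object, newdata, ...) {
  Xs <- scale(as.matrix(newdata), center = object$x_min,
              scale = object$x_max - object$x_min)
  predict_scaled_bpann(object, Xs)
}

# forward pass on already min-max scaled inputs, returning original-scale y
predict_scaled_bpann <- function(object, Xs) {
  z <- 1 / (1 + exp(-sweep(Xs %*% object$w, 2, object$hidden_bias, `+`)))
  ys <- as.numeric(z %*% object$e + object$output_bias)
  ys * (object$y_max - object$y_min) + object$y_min
}

#' @export
print.bpann <- function(x, ...) {
  cat(sprintf(
    "bpann: %d-%d-1 network; train MSE %.4g (R %.3f), validation MSE %.4g (R %.3f)\n",
    nrow(x$w), x$hidden_units, x$metrics$train$mse, x$metrics$train$r,
    x$metrics$validation$mse, x$metrics$validation$r))
  invisible(x)
}

#' Garson connection-weight sensitivity
#'
#' Relative influence of each input on the single output from the absolute
#' connection weights: each hidden unit's incoming weights are normalized to
#' proportions, weighted by the absolute hidden-output weight, summed over
#' hidden units and normalized over inputs to percentages summing to 100.
#'
#' @param model A `bpann` model (single output).
#' @return Named numeric vector of percentages (sums to 100).
#' @export
garson_sensitivity <- function(model) {
  w <- abs(model$w)            # inputs x hidden
  e <- abs(model$e)            # hidden
  colsum <- colSums(w)
  keep <- colsum > 0
  if (!all(keep)) {
    warning("skipping hidden unit(s) with all-zero incoming weights")
    w <- w[, keep, drop = FALSE]; e <- e[keep]; colsum <- colsum[keep]
  }
  contrib <- as.numeric(sweep(w, 2, colsum, `/`) %*% e)
  p <- 100 * contrib / sum(contrib)
  names(p) <- rownames(model$w)
  p
}

#' Mean impact value of each input
#'
#' Each input column of the (min-max scaled) design matrix is perturbed by
#' +/- `delta` (multiplicatively); the MIV of an input is the mean difference
#' between the network predictions under the upward and downward
#' perturbations, on the original response scale. Against an IC50 response a
#' negative MIV marks a toxicity-increasing compound.
#'
#' @param model A `bpann` model.
#' @param X Matrix of compound areas (original units); defaults to requiring
#'   an explicit matrix so the perturbation set is always stated.
#' @param delta Perturbation fraction in (0, 1), default 0.1.
#' @return Named numeric vector of MIVs.
#' @export
mean_impact_value <- function(model, X, delta = 0.1) {
  if (delta <= 0 || delta >= 1) stop("config error: delta must lie in (0, 1)")
  Xs <- scale(as.matrix(X), center = model$x_min,
              scale = model$x_max - model$x_min)
  miv <- vapply(seq_len(ncol(Xs)), function(a) {
    up <- dn <- Xs
    up[, a] <- up[, a] * (1 + delta)
    dn[, a] <- dn[, a] * (1 - delta)
    mean(predict_scaled_bpann(model, up) - predict_scaled_bpann(model, dn))
  }, numeric(1))
  names(miv) <- rownames(model$w)
  miv
}

#' Select compounds by negative mean impact value
#'
#' With IC50 as the response, compounds whose MIV is negative (abundance up,
#' IC50 down) are flagged as toxicity-associated, ranked by |MIV|.
#'
#' @param miv Named numeric vector from [mean_impact_value()] (or a reported
#'   MIV column).
#' @return Character vector of compounds with `miv < 0`, decreasing |MIV|.
#' @export
select_by_miv <- function(miv) {
  neg <- miv[miv < 0]
  names(neg[order(abs(neg), decreasing = TRUE)])
}
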