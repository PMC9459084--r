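#' Fit a single-response OPLS model
#'
#' Orthogonal projections to latent structures for a single response:
#' variation in `X` uncorrelated with `y` is peeled off into `n_orthogonal`
#' orthogonal components, then one predictive component is fitted. With a
#' binary (+/-1 or 0/1) response this is OPLS-DA. Columns of `X` and `y` are
#' centred and unit-variance scaled internally; reported coefficients act on
#' the standardized scale.
#'
#' @param X Numeric matrix (samples x variables), no constant columns.
#' @param y Numeric response vector (continuous, or binary group coding).
#' @param n_orthogonal Number of orthogonal components, or `"auto"` to pick
#'   the count in `0..max_orthogonal` that maximizes cross-validated Q2.
#' @param max_orthogonal Upper bound used by `"auto"` (default 5).
#' @param cv_folds Folds used for the `"auto"` Q2 search (default 7).
#' @return An object of class `opls` with predictive weights/scores/loading
#'   (`w`, `t`, `p`, `q`), orthogonal blocks (`Wo`, `To`, `Po`),
#'   standardized-scale coefficients `coefficients`, `vip`, explained
#'   variance `R2X`, `R2X_pred`, `R2X_ortho`, `R2Y`, cross-validated `Q2`,
#'   and the centring/scaling vectors.
#' @export
fit_opls <- function(X, y, n_orthogonal = 0L, max_orthogonal = 5L,
                     cv_folds = 7L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("dimension error: nrow(X) != length(y)")
  if (nrow(X) < 5) stop("need at least 5 samples")
  if (stats::sd(y) == 0) stop("fit error: response is constant")
  sx <- apply(X, 2, stats::sd)
  if (any(sx == 0)) {
    stop("fit error: constant variable(s): ",
         paste(colnames(X)[sx == 0], collapse = ", "))
  }
  if (identical(n_orthogonal, "auto")) {
    kmax <- min(max_orthogonal, nrow(X) - 3L, ncol(X) - 1L)
    q2s <- vapply(0:kmax, function(k)
      cross_validate_q2(X, y, folds = cv_folds, n_orthogonal = k), numeric(1))
    n_orthogonal <- which.max(q2s) - 1L
  }
  n_orthogonal <- as.integer(n_orthogonal)
  if (n_orthogonal < 0) stop("n_orthogonal must be >= 0")
  if (n_orthogonal >= min(nrow(X) - 1L, ncol(X))) {
    stop("dimension error: more components than the data rank supports")
  }
  mx <- colMeans(X); my <- mean(y); sy <- stats::sd(y)
  Xs <- scale(X, center = mx, scale = sx)
  ys <- (y - my) / sy
  core <- opls_core(Xs, ys, n_orthogonal)
  q2 <- tryCatch(cross_validate_q2(X, y, folds = min(cv_folds, nrow(X)),
                                   n_orthogonal = n_orthogonal),
                 error = function(e) NA_real_)
  structure(c(core, list(x_center = mx, x_scale = sx, y_center = my,
                         y_scale = sy, n_orthogonal = n_orthogonal, Q2 = q2,
                         var_names = colnames(X))),
            class = "opls")
}

# Core extraction on pre-standardized data. For a single response the
# predictive weight is closed-form (w proportional to X'y), so no NIPALS
# iteration is needed; orthogonal components follow Trygg & Wold's OSC step.
opls_core <- function(Xs, ys, k) {
  p_var <- ncol(Xs)
  ssx <- sum(Xs^2)
  Xd <- Xs
  Wo <- To <- Po <- NULL
  for (i in seq_len(k)) {
    w <- crossprod(Xd, ys)
    w <- w / sqrt(sum(w^2))
    t <- Xd %*% w
    p <- crossprod(Xd, t) / sum(t^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break
    wo <- wo / nwo
    to <- Xd %*% wo
    po <- crossprod(Xd, to) / sum(to^2)
    Xd <- Xd - to %*% t(po)
    Wo <- cbind(Wo, wo); To <- cbind(To, to); Po <- cbind(Po, po)
  }
  w <- crossprod(Xd, ys)
  w <- w / sqrt(sum(w^2))
  t <- Xd %*% w
  p <- crossprod(Xd, t) / sum(t^2)
  q <- sum(ys * t) / sum(t^2)
  fitted_s <- as.numeric(t) * q
  # compose the orthogonal filtering into one coefficient vector:
  # Xd = Xs %*% M with M = prod_i (I - wo_i po_i'), so beta = M w q
  b <- w
  if (!is.null(Wo)) {
    for (i in rev(seq_len(ncol(Wo)))) {
      b <- b - Wo[, i] * as.numeric(crossprod(Po[, i], b))
    }
  }
  b <- as.numeric(b) * q
  r2x_ortho <- if (is.null(To)) 0 else
    sum(vapply(seq_len(ncol(To)),
               function(i) sum(To[, i]^2) * sum(Po[, i]^2), numeric(1))) / ssx
  r2x_pred <- sum(t^2) * sum(p^2) / ssx
  r2y <- 1 - sum((ys - fitted_s)^2) / sum(ys^2)
  vip <- sqrt(p_var) * abs(as.numeric(w))
  names(vip) <- colnames(Xs)
  names(b) <- colnames(Xs)
  list(w = as.numeric(w), t = as.numeric(t), p = as.numeric(p), q = q,
       Wo = Wo, To = To, Po = Po, coefficients = b, vip = vip,
       fitted_std = fitted_s, R2X_pred = r2x_pred, R2X_ortho = r2x_ortho,
       R2X = r2x_pred + r2x_ortho, R2Y = r2y)
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf(
    "OPLS model: 1 predictive + %d orthogonal component(s)\nR2X %.3f  R2Y %.3f  Q2 %.3f\n",
    x$n_orthogonal, x$R2X, x$R2Y, x$Q2))
  invisible(x)
}

#' Predict from a fitted OPLS model
#' @param object An `opls` model.
#' @param newdata Matrix of predictors on the original scale.
#' @param ... Unused.
#' @return Predicted response on the original scale.
#' @export
predict.opls <- function(object, newdata, ...) {
  Xs <- scale(as.matrix(newdata), center = object$x_center,
              scale = object$x_scale)
  as.numeric(Xs %*% object$coefficients) * object$y_scale + object$y_center
}

#' Variable importance in projection
#'
#' VIP on the predictive component only, normalized so that the mean of the
#' squared VIPs equals 1.
#'
#' @param model A fitted `opls` model.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "opls"))
  model$vip
}

#' Cross-validated predictive fraction Q2
#'
#' Q2 = 1 - PRESS/TSS with a venetian-blind (interleaved, deterministic)
#' fold assignment; each fold is predicted from an OPLS model refitted on
#' the remaining samples.
#'
#' @param X,y Data on the original scale.
#' @param folds Number of folds (default 7).
#' @param n_orthogonal Orthogonal component count for each refit.
#' @return Q2 as a scalar (can be negative for uninformative models).
#' @export
cross_validate_q2 <- function(X, y, folds = 7L, n_orthogonal = 0L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2) stop("config error: folds must be >= 2")
  if (folds > n) stop("config error: more folds than samples")
  fold_id <- (seq_len(n) - 1L) %% folds + 1L
  press <- 0
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    Xtr <- X[!hold, , drop = FALSE]
    ytr <- y[!hold]
    mx <- colMeans(Xtr); sx <- apply(Xtr, 2, stats::sd)
    sx[sx == 0] <- 1
    my <- mean(ytr); sy <- stats::sd(ytr)
    core <- opls_core(scale(Xtr, mx, sx), (ytr - my) / sy, n_orthogonal)
    pred <- as.numeric(scale(X[hold, , drop = FALSE], mx, sx) %*%
                         core$coefficients) * sy + my
    press <- press + sum((y[hold] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Response-permutation validation of an OPLS model
#'
#' Refits the model on uniformly permuted responses and compares permuted
#' R2Y/Q2 with the originals. The verdict is "no overfitting" when every
#' permuted Q2 lies below the original Q2 and the intercept of the
#' regression of permuted Q2 on the absolute permutation/original response
#' correlation is at most `intercept_max`.
#'
#' @param X,y Data on the original scale.
#' @param n_permutations Number of random permutations (default 200).
#' @param n_orthogonal Orthogonal component count; `"auto"` (default)
#'   resolves the count once on the unpermuted data by maximizing Q2 and
#'   reuses it for every permutation, so the permuted models mirror the
#'   fitted model's complexity.
#' @param folds CV folds for Q2 (default 7).
#' @param seed Integer seed controlling the permutations.
#' @param intercept_max Q2-intercept pass bound (default 0.05).
#' @return A `permutation_result`: data frame `permutations` with columns
#'   `correlation`, `R2Y`, `Q2` (the original included once as the last row
#'   with correlation 1), plus `R2Y`, `Q2`, `q2_intercept` and logical `pass`.
#' @export
permutation_test <- function(X, y, n_permutations = 200L,
                             n_orthogonal = "auto", folds = 7L, seed = 1L,
                             intercept_max = 0.05) {
  if (n_permutations < 20) warning("fewer than 20 permutations is unreliable")
  X <- as.matrix(X); y <- as.numeric(y)
  if (identical(n_orthogonal, "auto")) {
    n_orthogonal <- fit_opls(X, y, n_orthogonal = "auto",
                             cv_folds = folds)$n_orthogonal
  }
  fit_one <- function(yy) {
    mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
    core <- opls_core(scale(X, mx, sx), (yy - mean(yy)) / stats::sd(yy),
                      n_orthogonal)
    c(R2Y = core$R2Y,
      Q2 = cross_validate_q2(X, yy, folds = folds, n_orthogonal = n_orthogonal))
  }
  orig <- fit_one(y)
  set.seed(seed)
  perm <- t(vapply(seq_len(n_permutations), function(i) {
    yp <- sample(y)
    c(correlation = stats::cor(yp, y), fit_one(yp))
  }, c(correlation = 0, R2Y = 0, Q2 = 0)))
  tab <- rbind(as.data.frame(perm),
               data.frame(correlation = 1, R2Y = orig[["R2Y"]],
                          Q2 = orig[["Q2"]]))
  ic <- stats::coef(stats::lm(Q2 ~ abs(correlation), data = tab))[[1]]
  structure(list(permutations = tab, R2Y = orig[["R2Y"]], Q2 = orig[["Q2"]],
                 q2_intercept = ic,
                 pass = all(perm[, "Q2"] < orig[["Q2"]]) && ic <= intercept_max),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: %d permutations, Q2 %.3f, Q2 intercept %.3f -> %s\n",
              nrow(x$permutations) - 1L, x$Q2, x$q2_intercept,
              if (x$pass) "no overfitting" else "OVERFIT"))
  invisible(x)
}

#' Select toxicity-associated compounds from an OPLS model
#'
#' A compound is retained when its VIP exceeds `vip_min` and its standardized
#' regression coefficient is below `coef_max` (strict inequalities). The
#' negative sign encodes the toxicity direction with IC50 as the response:
#' higher abundance, lower IC50, more toxic.
#'
#' @param model A fitted `opls` model, or a list with elements `vip` and
#'   `coefficients` (so reported score tables can be screened directly).
#' @param vip_min VIP threshold (default 0.7).
#' @param coef_max Coefficient threshold (default -0.1).
#' @return Character vector of selected compound names, ordered by
#'   increasingly negative coefficient.
#' @export
select_by_vip_coefficient <- function(model, vip_min = 0.7, coef_max = -0.1) {
  vip <- model$vip
  b <- model$coefficients
  keep <- vip > vip_min & b < coef_max
  names(sort(b[keep]))
}
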