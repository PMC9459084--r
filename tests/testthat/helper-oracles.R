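# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (loops, no shared code with R/).

# PLS1 regression via classical NIPALS deflation, standardized like fit_opls.
nipals_pls_fitted <- function(X, y, ncomp) {
  X <- as.matrix(X)
  mx <- colMeans(X); sx <- apply(X, 2, sd)
  my <- mean(y); sy <- sd(y)
  E <- scale(X, mx, sx)
  f <- (y - my) / sy
  fitted <- rep(0, nrow(X))
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    q <- sum(f * t) / sum(t^2)
    fitted <- fitted + as.numeric(t) * q
    E <- E - t %*% t(p)
    f <- f - as.numeric(t) * q
  }
  fitted * sy + my
}

# Deng gray relational degrees by direct, unvectorized formula evaluation.
gra_brute_force <- function(reference, comparisons, rho = 0.5) {
  comparisons <- as.matrix(comparisons)
  n <- length(reference)
  m <- ncol(comparisons)
  delta <- matrix(0, n, m)
  for (i in seq_len(m)) {
    for (k in seq_len(n)) {
      delta[k, i] <- abs(reference[k] - comparisons[k, i])
    }
  }
  dmin <- Inf; dmax <- -Inf
  for (i in seq_len(m)) for (k in seq_len(n)) {
    dmin <- min(dmin, delta[k, i]); dmax <- max(dmax, delta[k, i])
  }
  deg <- numeric(m)
  for (i in seq_len(m)) {
    xi <- numeric(n)
    for (k in seq_len(n)) {
      xi[k] <- (dmin + rho * dmax) / (delta[k, i] + rho * dmax)
    }
    deg[i] <- mean(xi)
  }
  names(deg) <- colnames(comparisons)
  deg
}

# Garson percentages by direct loop evaluation of the connection-weight
# formula (w: inputs x hidden, e: hidden weights).
garson_brute_force <- function(w, e) {
  m <- nrow(w); h <- ncol(w)
  contrib <- numeric(m)
  for (a in seq_len(m)) {
    s <- 0
    for (b in seq_len(h)) {
      s <- s + abs(w[a, b]) / sum(abs(w[, b])) * abs(e[b])
    }
    contrib[a] <- s
  }
  100 * contrib / sum(contrib)
}

# Hand-buildable bpann object for weight-based sensitivity tests.
make_bpann <- function(w, e, hidden_bias = rep(0, ncol(w)), output_bias = 0,
                       x_min = rep(0, nrow(w)), x_max = rep(1, nrow(w)),
                       y_min = 0, y_max = 1) {
  structure(list(w = w, hidden_bias = hidden_bias, e = e,
                 output_bias = output_bias,
                 x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 hidden_units = ncol(w), seed = 0L),
            class = "bpann")
}

# Grid-search 4PL refit oracle (coarse but implementation-independent).
fourpl_grid_ic50 <- function(conc, inh) {
  lgrid <- seq(log(min(conc)) - 2, log(max(conc)) + 2, length.out = 200)
  hills <- c(0.5, 0.75, 1, 1.5, 2, 3)
  best <- c(Inf, NA)
  for (l50 in lgrid) for (h in hills) {
    pred <- 100 / (1 + exp(h * (l50 - log(conc))))
    sse <- sum((inh - pred)^2)
    if (sse < best[1]) best <- c(sse, exp(l50))
  }
  best[2]
}

# Noise-free 4PL inhibition curve.
fourpl_curve <- function(conc, ic50, hill = 1, bottom = 0, top = 100) {
  bottom + (top - bottom) / (1 + (ic50 / conc)^hill)
}

# Shared small fixture: quant CSV mirroring the 50-batch cohort layout.
write_cohort_csv <- function(path, n_raw = 50, n_proc = 0, p = 16,
                             seed = 42) {
  set.seed(seed)
  batches <- c(sprintf("S%d", seq_len(n_raw)),
               if (n_proc) sprintf("Z%d", seq_len(n_proc)))
  m <- matrix(round(rlnorm(length(batches) * p, 12, 0.4), 3),
              nrow = length(batches),
              dimnames = list(NULL, paste0("X", seq_len(p))))
  df <- data.frame(batch = batches, m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  df
}
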