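random_xy <- function(n = 30, p = 10, r2 = 0.8, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("V", 1:p)))
  signal <- X %*% rnorm(p)
  noise <- rnorm(n)
  y <- as.numeric(sqrt(r2) * scale(signal) + sqrt(1 - r2) * scale(noise))
  list(X = X, y = y)
}

test_that("a noiseless linear signal is fitted with R2Y = 1", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, dimnames = list(NULL, paste0("V", 1:6)))
  # noise columns orthogonalized against the signal column in-sample, so a
  # single predictive component carries the whole response
  X[, -1] <- apply(X[, -1], 2, function(v) residuals(lm(v ~ X[, 1])))
  y <- X[, 1]
  m <- fit_opls(X, y, n_orthogonal = 0)
  expect_equal(m$R2Y, 1, tolerance = 1e-8)
  expect_equal(unname(which.max(abs(m$coefficients))), 1L)
})

test_that("orthogonal scores are uncorrelated with the response", {
  d <- random_xy(40, 8, r2 = 0.6, seed = 9)
  m <- fit_opls(d$X, d$y, n_orthogonal = 3)
  for (i in seq_len(ncol(m$To))) {
    expect_lt(abs(cor(m$To[, i], d$y)), 1e-10)
  }
})

test_that("OPLS with k orthogonal components predicts like PLS with k+1", {
  for (seed in 1:5) {
    d <- random_xy(30, 10, r2 = 0.7, seed = seed)
    for (k in 0:2) {
      m <- fit_opls(d$X, d$y, n_orthogonal = k)
      expect_equal(predict(m, d$X), nipals_pls_fitted(d$X, d$y, k + 1),
                   tolerance = 1e-8)
    }
  }
})

test_that("VIP normalization and single-variable degenerate case hold", {
  d <- random_xy(25, 7, seed = 3)
  m <- fit_opls(d$X, d$y, n_orthogonal = 2)
  expect_equal(mean(vip_scores(m)^2), 1, tolerance = 1e-10)
  # 2-variable model: VIP ratio equals the weight ratio, scaled to mean(VIP^2)=1
  m2 <- fit_opls(d$X[, 1:2], d$y, n_orthogonal = 0)
  w <- abs(m2$w)
  expect_equal(unname(vip_scores(m2)),
               sqrt(2) * w / sqrt(sum(w^2)), tolerance = 1e-10)
  set.seed(4)
  X1 <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "only"))
  expect_equal(unname(vip_scores(fit_opls(X1, rnorm(20) + X1[, 1]))), 1)
})

test_that("variance decomposes into predictive, orthogonal and residual parts", {
  d <- random_xy(30, 6, seed = 12)
  m <- fit_opls(d$X, d$y, n_orthogonal = 2)
  Xs <- scale(d$X)
  resid <- Xs - m$To %*% t(m$Po) -
    (m$To %*% t(m$Po) * 0 + (Xs - m$To %*% t(m$Po)) %*% m$w %*% t(m$p))
  r2_resid <- sum(resid^2) / sum(Xs^2)
  expect_equal(m$R2X_pred + m$R2X_ortho + r2_resid, 1, tolerance = 1e-8)
})

test_that("Q2 is deterministic, bounded by fold rules, and signal-sensitive", {
  d <- random_xy(35, 8, r2 = 0.9, seed = 21)
  q1 <- cross_validate_q2(d$X, d$y, folds = 7, n_orthogonal = 1)
  q2 <- cross_validate_q2(d$X, d$y, folds = 7, n_orthogonal = 1)
  expect_identical(q1, q2)
  expect_gt(q1, 0.5)
  expect_error(cross_validate_q2(d$X, d$y, folds = 40), "config error")
  # pure noise: Q2 non-positive for most draws
  q2s <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(30 * 8), 30)
    cross_validate_q2(X, rnorm(30), folds = 7, n_orthogonal = 0)
  }, numeric(1))
  expect_lte(median(q2s), 0)
})

test_that("permutation test sizes its table and distinguishes signal from noise", {
  d <- random_xy(40, 8, r2 = 0.7, seed = 31)
  pr <- permutation_test(d$X, d$y, n_permutations = 50, seed = 2)
  expect_equal(nrow(pr$permutations), 51L)
  expect_equal(pr$permutations$correlation[51], 1)
  expect_true(pr$pass)
  set.seed(32)
  pr_noise <- permutation_test(matrix(rnorm(40 * 8), 40), rnorm(40),
                               n_permutations = 50, seed = 2)
  expect_false(pr_noise$pass)
  expect_warning(permutation_test(d$X, d$y, n_permutations = 10, seed = 1),
                 "unreliable")
})

test_that("VIP/coefficient selection rule reproduces the published OPLS sets", {
  scores <- pm_model_scores()
  vip_all <- setNames(rep(1, 16), scores$compound)  # all VIPs reported > 0.7
  sel_l02 <- select_by_vip_coefficient(
    list(vip = vip_all, coefficients = setNames(scores$opls_r_L02,
                                                scores$compound)))
  expect_setequal(sel_l02, c("X2", "X5", "X6", "X7", "X9", "X10", "X11",
                             "X14", "X16"))
  sel_hep <- select_by_vip_coefficient(
    list(vip = vip_all, coefficients = setNames(scores$opls_r_HepG2,
                                                scores$compound)))
  expect_setequal(sel_hep, c("X4", "X5", "X6", "X7", "X9", "X10", "X14",
                             "X15", "X16"))
  # all-positive coefficients select nothing
  expect_length(select_by_vip_coefficient(
    list(vip = vip_all, coefficients = abs(setNames(scores$opls_r_L02,
                                                    scores$compound)))), 0)
})

test_that("selection is invariant to compound and batch reordering", {
  d <- random_xy(30, 8, r2 = 0.8, seed = 77)
  m <- fit_opls(d$X, d$y, n_orthogonal = 1)
  sel <- select_by_vip_coefficient(m)
  perm_c <- sample(ncol(d$X)); perm_r <- sample(nrow(d$X))
  m2 <- fit_opls(d$X[perm_r, perm_c], d$y[perm_r], n_orthogonal = 1)
  expect_setequal(select_by_vip_coefficient(m2), sel)
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- random_xy(20, 5, seed = 8)
  expect_error(fit_opls(d$X, rep(1, 20)), "constant")
  Xc <- d$X; Xc[, 2] <- 3
  expect_error(fit_opls(Xc, d$y), "constant variable")
  expect_error(fit_opls(d$X, d$y, n_orthogonal = 19), "dimension error")
})
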