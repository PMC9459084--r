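linear_training_data <- function(n = 50, p = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p, 1, 10), n, dimnames = list(NULL, paste0("X", 1:p)))
  y <- as.numeric(2 + X %*% c(3, -2, 1, 0.5))
  list(X = X, y = y)
}

test_that("training is reproducible and splits samples as configured", {
  d <- linear_training_data()
  m1 <- train_bpann(d$X, d$y, hidden_units = 4, seed = 7, restarts = 2,
                    maxit = 200)
  m2 <- train_bpann(d$X, d$y, hidden_units = 4, seed = 7, restarts = 2,
                    maxit = 200)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$e, m2$e)
  expect_length(m1$train_idx, 40L)
  expect_length(m1$val_idx, 10L)
})

test_that("a noise-free linear map is learned to high correlation", {
  d <- linear_training_data(seed = 3)
  m <- train_bpann(d$X, d$y, hidden_units = 6, seed = 1, restarts = 3)
  expect_gt(m$metrics$train$r, 0.99)
  expect_gt(m$metrics$validation$r, 0.98)
  # a closed-form linear fit is the lower-bound oracle the network must chase
  lm_r <- cor(d$y, fitted(lm(d$y ~ d$X)))
  expect_gte(lm_r, m$metrics$train$r - 0.01)
})

test_that("manual forward pass matches the trained network predictions", {
  d <- linear_training_data(seed = 5)
  m <- train_bpann(d$X, d$y, hidden_units = 3, seed = 2, restarts = 1,
                   maxit = 200)
  p1 <- predict(m, d$X)
  expect_length(p1, nrow(d$X))
  expect_true(all(is.finite(p1)))
  expect_gt(cor(p1, d$y), 0.9)
})

test_that("garson percentages sum to 100 and respect symmetry", {
  set.seed(11)
  for (i in 1:20) {
    w <- matrix(rnorm(5 * 8), 5)
    e <- rnorm(8)
    p <- garson_sensitivity(make_bpann(w, e))
    expect_equal(sum(p), 100, tolerance = 1e-6)
    expect_true(all(p >= 0))
    expect_equal(unname(p), garson_brute_force(w, e), tolerance = 1e-10)
  }
  # fully symmetric two-input network: equal shares
  w_sym <- matrix(c(1, 1, -2, -2, 0.5, 0.5), nrow = 2)
  p_sym <- garson_sensitivity(make_bpann(w_sym, c(1, 1, 1)))
  expect_equal(unname(p_sym), c(50, 50))
  # the worked toy: w = [[1,0],[0,2]], e = [1,1] -> each input 50%
  p_toy <- garson_sensitivity(make_bpann(matrix(c(1, 0, 0, 2), 2), c(1, 1)))
  expect_equal(unname(p_toy), c(50, 50))
})

test_that("garson is invariant to common positive rescaling of output weights", {
  set.seed(12)
  w <- matrix(rnorm(6 * 4), 6); e <- rnorm(4)
  expect_equal(garson_sensitivity(make_bpann(w, e)),
               garson_sensitivity(make_bpann(w, 7.3 * e)), tolerance = 1e-12)
})

test_that("hidden units with zero incoming weights are skipped with a warning", {
  w <- cbind(c(1, 2), c(0, 0))
  expect_warning(p <- garson_sensitivity(make_bpann(w, c(1, 1))),
                 "all-zero")
  expect_equal(sum(p), 100)
})

test_that("MIV is zero exactly for disconnected inputs and deterministic", {
  w <- rbind(c(1, -1), c(0, 0))  # input 2 disconnected
  rownames(w) <- c("a", "b")
  m <- make_bpann(w, c(0.5, 0.8), x_min = c(0, 0), x_max = c(1, 1))
  X <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  miv <- mean_impact_value(m, X)
  expect_identical(unname(miv["b"]), 0)
  expect_identical(miv, mean_impact_value(m, X))
  expect_error(mean_impact_value(m, X, delta = 1.5), "config error")
})

test_that("MIV sign tracks a monotone generating dependence", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    X <- matrix(runif(40 * 3, 1, 10), 40,
                dimnames = list(NULL, c("up", "down", "null")))
    y <- 5 + 2 * X[, "up"] - 2 * X[, "down"] + rnorm(40, 0, 0.5)
    m <- train_bpann(X, y, hidden_units = 5, seed = s, restarts = 2)
    miv <- mean_impact_value(m, X)
    if (miv[["up"]] > 0 && miv[["down"]] < 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("negative-MIV screening reproduces the published BP-ANN sets", {
  scores <- pm_model_scores()
  sel_l02 <- select_by_miv(setNames(scores$miv_L02, scores$compound))
  expect_setequal(sel_l02, c("X2", "X4", "X6", "X7", "X9", "X10", "X14",
                             "X15", "X16"))
  sel_hep <- select_by_miv(setNames(scores$miv_HepG2, scores$compound))
  expect_setequal(sel_hep, c("X4", "X6", "X7", "X11", "X13", "X14"))
  expect_length(select_by_miv(c(a = 0.1, b = 0.3)), 0)
  # ranking is by |MIV| decreasing
  expect_equal(sel_hep[1], "X7")
})

test_that("training rejects undersized or degenerate inputs", {
  d <- linear_training_data()
  expect_error(train_bpann(d$X[1:10, ], d$y[1:10]), "at least 15")
  expect_error(train_bpann(d$X, rep(1, 50)), "constant response")
  Xb <- d$X; Xb[1, 1] <- NA
  expect_error(train_bpann(Xb, d$y), "data error")
})
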