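test_that("the loss value matches an independent elementwise recomputation", {
  set.seed(11)
  p <- 4; q <- 2; n <- 3
  X <- normalize_columns(matrix(runif(p * q, 0.1, 1), p, q))
  Y <- normalize_columns(matrix(runif(p * n, 0.1, 1), p, n))
  g <- normalize_weights(runif(p, 0.2, 1))
  C <- matrix(runif(q * n, 0, 0.6), q, n)
  C0 <- matrix(runif(q * n, 0, 0.6), q, n)
  x <- normalize_columns(matrix(runif(p), p, 1))[, 1]
  Delta <- matrix(runif(p * q, 0.5, 1.5), p, q)
  expect_equal(adtd_loss(C, x, Delta, X, Y, g, 0.3, 0.7, C0),
               adtd_loss_byhand(C, x, Delta, X, Y, g, 0.3, 0.7, C0),
               tolerance = 1e-12)
})

test_that("the loss is zero at an exact model point and penalties vanish at their priors", {
  set.seed(12)
  p <- 5; q <- 2; n <- 4
  X <- normalize_columns(matrix(runif(p * q, 0.1, 1), p, q))
  Delta_s <- matrix(runif(p * q, 0.6, 1.4), p, q)
  C_s <- matrix(runif(q * n, 0, 0.4), q, n)
  x_s <- normalize_columns(matrix(runif(p), p, 1))[, 1]
  W <- Delta_s * X
  chat <- 1 - colSums(W %*% C_s)
  Y <- W %*% C_s + outer(x_s, chat)
  g <- normalize_weights(rep(1, p))
  expect_equal(adtd_loss(C_s, x_s, Delta_s, X, Y, g, 0, 0, C_s), 0,
               tolerance = 1e-14)
  # all-ones rescaling makes the adaptation penalty exactly zero
  l_with <- adtd_loss(C_s, x_s, matrix(1, p, q), X, Y, g, 0, 1e6, C_s)
  l_without <- adtd_loss(C_s, x_s, matrix(1, p, q), X, Y, g, 0, 0, C_s)
  expect_equal(l_with, l_without)
})

test_that("a dominant composition ridge returns the prior projected to the feasible set", {
  set.seed(13)
  p <- 6; q <- 3; n <- 5
  X <- normalize_columns(matrix(runif(p * q, 0.1, 1), p, q))
  Y <- normalize_columns(matrix(runif(p * n, 0.1, 1), p, n))
  g <- normalize_weights(runif(p, 0.2, 1))
  x <- rep(1 / p, p)
  C0 <- matrix(runif(q * n, 0, 0.3), q, n)   # feasible: colsums well below 1
  C <- adtd_solve_C(Y, X, x, g, 1e12, C0)
  expect_lt(max(abs(C - C0)), 1e-4)
})

test_that("the composition update matches a fine grid search on tiny instances", {
  set.seed(14)
  p <- 4; q <- 2
  X <- normalize_columns(matrix(runif(p * q, 0.1, 1), p, q))
  y <- normalize_columns(matrix(runif(p, 0.1, 1), p, 1))
  g <- normalize_weights(runif(p, 0.3, 1))
  x <- normalize_columns(matrix(runif(p), p, 1))[, 1]
  c0 <- c(0.3, 0.2)
  lambda1 <- 0.05
  cc <- adtd_solve_C(y, X, x, g, lambda1, matrix(c0, q, 1))[, 1]
  obj <- function(c1, c2) {
    ci <- c(c1, c2)
    chat <- 1 - sum(colSums(X) * ci)
    sum((g * (y[, 1] - X %*% ci - x * chat))^2) + lambda1 * sum((ci - c0)^2)
  }
  # feasible grid at resolution 1e-3
  s <- colSums(X)
  grid1 <- seq(0, 1 / s[1], by = 1e-3)
  best <- Inf
  for (c1 in grid1) {
    c2max <- (1 - s[1] * c1) / s[2]
    if (c2max < 0) next
    c2 <- seq(0, c2max, by = 1e-3)
    v <- vapply(c2, function(z) obj(c1, z), 1)
    best <- min(best, min(v))
  }
  expect_lte(obj(cc[1], cc[2]), best + 1e-6)
})

test_that("a noiseless bulk fully explained by the reference yields zero hidden weight", {
  set.seed(15)
  p <- 6; q <- 2
  X <- normalize_columns(matrix(runif(p * q, 0.1, 1), p, q))
  C_s <- matrix(c(0.45, 0.55, 0.3, 0.7), q, 2)   # colsums exactly 1
  Y <- X %*% C_s
  g <- normalize_weights(rep(1, p))
  x <- normalize_columns(matrix(runif(p), p, 1))[, 1]
  C <- adtd_solve_C(Y, X, x, g, 1e-6, C_s)
  chat <- 1 - colSums(X %*% C)
  expect_lt(max(abs(chat)), 1e-6)
  expect_equal(C, C_s, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("the background update copies a single residual bulk exactly", {
  set.seed(16)
  p <- 7
  X <- normalize_columns(matrix(runif(p * 2, 0.1, 1), p, 2))
  y <- normalize_columns(matrix(runif(p, 0.1, 1), p, 1))
  g <- normalize_weights(runif(p, 0.2, 1))
  x <- adtd_solve_x(y, X, matrix(0, 2, 1), g)
  expect_equal(x, y[, 1], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the background update recovers a shared true profile from noiseless samples", {
  set.seed(17)
  p <- 8; q <- 2; n <- 6
  X <- normalize_columns(matrix(runif(p * q, 0.1, 1), p, q))
  x_s <- normalize_columns(matrix(runif(p, 0.1, 1), p, 1))[, 1]
  C_s <- matrix(runif(q * n, 0.05, 0.35), q, n)
  chat <- 1 - colSums(X %*% C_s)
  stopifnot(all(chat > 0))
  Y <- X %*% C_s + outer(x_s, chat)
  g <- normalize_weights(runif(p, 0.2, 1))
  x <- adtd_solve_x(Y, X, C_s, g)
  expect_equal(x, x_s, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sum(x), 1, tolerance = 1e-12)
  expect_true(all(x >= 0))
})

test_that("an all-explained cohort makes the background unidentifiable (uniform + warning)", {
  p <- 5; q <- 2
  X <- normalize_columns(matrix(1:10, p, q))
  C <- matrix(c(0.5, 0.5, 0.2, 0.8), q, 2)  # colsums exactly 1
  Y <- X %*% C
  expect_warning(x <- adtd_solve_x(Y, X, C, rep(1 / sqrt(p), p)),
                 "unidentifiable")
  expect_equal(x, rep(1 / p, p))
})

test_that("a dominant adaptation ridge returns a rescaling row of ones", {
  set.seed(18)
  p <- 6; q <- 3; n <- 4
  X <- normalize_columns(matrix(runif(p * q, 0.1, 1), p, q))
  Y <- normalize_columns(matrix(runif(p * n, 0.1, 1), p, n))
  g <- normalize_weights(runif(p, 0.2, 1))
  C <- matrix(runif(q * n, 0, 0.4), q, n)
  x <- normalize_columns(matrix(runif(p), p, 1))[, 1]
  Delta <- matrix(runif(p * q, 0.5, 1.5), p, q)
  row <- adtd_solve_delta_row(2, Y, X, C, x, g, 1e12, Delta)
  expect_lt(max(abs(row - 1)), 1e-4)
})

test_that("the single-type rescaling row matches its analytic closed form", {
  # q = 1: the row update is a scalar ridge problem with closed form
  set.seed(19)
  p <- 5; n <- 6
  X <- normalize_columns(matrix(runif(p, 0.1, 1), p, 1))
  C <- matrix(runif(n, 0.2, 0.8), 1, n)
  x <- normalize_columns(matrix(runif(p), p, 1))[, 1]
  g <- normalize_weights(runif(p, 0.2, 1))
  Delta <- matrix(runif(p, 0.5, 1.5), p, 1)
  lambda2 <- 0.01
  k <- 3
  row <- adtd_solve_delta_row(k, Y <- normalize_columns(matrix(runif(p * n, 0.1, 1), p, n)),
                              X, C, x, g, lambda2, Delta)
  # scalar quadratic coefficients derived by hand from the residual structure
  b <- X[k, 1] * C[1, ]
  W <- Delta * X; W[k, ] <- 0
  cs_other <- colSums(W %*% C)
  tvec <- 1 - cs_other
  Rj <- Y - W %*% C
  s2_other <- sum((g * x)^2) - (g[k] * x[k])^2
  kap <- g[k]^2 * (1 - x[k])^2 + s2_other
  Ek <- Y[k, ] - x[k] * tvec
  w <- colSums((g^2 * x) * Rj) - g[k]^2 * x[k] * Rj[k, ] - tvec * s2_other
  beta <- g[k]^2 * (1 - x[k]) * Ek - w
  d_unc <- (sum(beta * b) + lambda2) / (kap * sum(b^2) + lambda2)
  expect_equal(row, max(0, d_unc), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a knockout spiked on a type-exclusive gene is recovered by the row update", {
  # gene k expressed by exactly one type; data generated with a known
  # rescaling factor on that gene; everything else at truth
  set.seed(20)
  p <- 6; q <- 2; n <- 8
  X <- matrix(runif(p * q, 0.1, 1), p, q)
  X[1, ] <- c(0.9, 0)                        # gene 1 exclusive to type 1
  X <- normalize_columns(X)
  Delta_s <- matrix(1, p, q)
  Delta_s[1, 1] <- 0.4                       # the spiked factor to recover
  C_s <- matrix(runif(q * n, 0.1, 0.4), q, n)
  W <- Delta_s * X
  Y <- W %*% C_s + outer(normalize_columns(matrix(runif(p), p, 1))[, 1],
                         1 - colSums(W %*% C_s))
  g <- normalize_weights(rep(1, p))
  x_s <- normalize_columns(matrix(runif(p), p, 1))[, 1]
  # re-generate with consistent x
  Y <- W %*% C_s + outer(x_s, 1 - colSums(W %*% C_s))
  start <- matrix(1, p, q)
  row <- adtd_solve_delta_row(1, Y, X, C_s, x_s, g, 1e-10, start)
  expect_equal(row[1], 0.4, tolerance = 0.05 * 0.4)
})
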