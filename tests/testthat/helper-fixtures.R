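# Shared fixtures and independent oracles for the test suite.

# deterministic 3-gene / 2-type toy reference (column-normalized)
toy_reference <- function() {
  X <- cbind(a = c(.5, .3, .2), b = c(.1, .3, .6))
  rownames(X) <- paste0("g", 1:3)
  X
}

# Brute-force weighted NNLS for one bulk column: enumerate every active set
# (subset of coefficients allowed nonzero), solve the weighted least-squares
# on it, keep feasible candidates, return the best.
brute_nnls <- function(X, y, gamma = rep(1, nrow(X))) {
  q <- ncol(X)
  w <- sqrt(gamma)
  Xw <- X * w
  yw <- y * w
  best <- rep(0, q)
  best_obj <- sum(yw^2)
  for (mask in 1:(2^q - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(q) - 1)) > 0)
    Xa <- Xw[, act, drop = FALSE]
    fit <- tryCatch(qr.solve(Xa, yw), error = function(e) NULL)
    if (is.null(fit) || any(fit < 0)) next
    obj <- sum((yw - Xa %*% fit)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- rep(0, q)
      best[act] <- fit
    }
  }
  list(x = best, obj = best_obj)
}

nnls_objective <- function(X, y, cc, gamma = rep(1, nrow(X))) {
  sum(gamma * (y - X %*% cc)^2)
}

# Independent elementwise re-implementation of the full adaptive loss
# (explicit loops; deliberately naive).
adtd_loss_byhand <- function(C, x, Delta, X, Y, g, lambda1, lambda2, C0) {
  p <- nrow(X); q <- ncol(X); n <- ncol(Y)
  total <- 0
  for (i in 1:n) {
    ci <- 1
    for (j in 1:p) for (k in 1:q) ci <- ci - Delta[j, k] * X[j, k] * C[k, i]
    for (j in 1:p) {
      fit <- 0
      for (k in 1:q) fit <- fit + Delta[j, k] * X[j, k] * C[k, i]
      total <- total + (g[j] * (Y[j, i] - fit - x[j] * ci))^2
    }
  }
  if (is.finite(lambda1)) total <- total + lambda1 * sum((C - C0)^2)
  if (is.finite(lambda2)) total <- total + lambda2 * sum((1 - Delta)^2)
  total
}

# Generic constrained minimizer of the full loss: multistart L-BFGS-B with
# box constraints (all parameters >= 0) and ramped quadratic penalties for
# the simplex constraint on x and the per-sample budget constraint. Returns
# the best exactly-feasible objective found. Independent of the
# block-coordinate solver.
penalty_oracle <- function(X, Y, g, lambda1, lambda2, C0, n_starts = 20,
                           seed = 1) {
  p <- nrow(X); q <- ncol(X); n <- ncol(Y)
  unpack <- function(th) {
    list(C = matrix(th[1:(q * n)], q, n),
         x = th[(q * n + 1):(q * n + p)],
         Delta = matrix(th[(q * n + p + 1):(q * n + p + p * q)], p, q))
  }
  feas_obj <- function(th) {
    v <- unpack(th)
    xs <- sum(v$x)
    x <- if (xs > 0) v$x / xs else rep(1 / p, p)
    C <- v$C
    W <- v$Delta * X
    cs <- colSums(W %*% C)
    over <- cs > 1
    if (any(over)) C[, over] <- C[, over] / rep(cs[over], each = q)
    adtd_loss_byhand(C, x, v$Delta, X, Y, g, lambda1, lambda2, C0)
  }
  best <- Inf
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    th <- c(runif(q * n, 0, 1), runif(p, 0, 2 / p), runif(p * q, 0.2, 1.8))
    for (rho in c(1e2, 1e4, 1e6, 1e8)) {
      pen_obj <- function(th) {
        v <- unpack(th)
        W <- v$Delta * X
        cs <- colSums(W %*% v$C)
        adtd_loss_byhand(v$C, v$x, v$Delta, X, Y, g, lambda1, lambda2, C0) +
          rho * (sum(v$x) - 1)^2 + rho * sum(pmax(0, cs - 1)^2)
      }
      opt <- stats::optim(th, pen_obj, method = "L-BFGS-B",
                          lower = 0, control = list(maxit = 500))
      th <- opt$par
    }
    best <- min(best, feas_obj(th))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  best
}

# small random ADTD instance on the simplex scale
random_tiny_instance <- function(p, q, n, seed) {
  set.seed(seed)
  X <- normalize_columns(matrix(runif(p * q, 0.05, 1), p, q))
  Y <- normalize_columns(matrix(runif(p * n, 0.05, 1), p, n))
  g <- normalize_weights(runif(p, 0.2, 1))
  list(X = X, Y = Y, g = g)
}

# Training fixture with informative marker genes plus an uninformative noise
# block: marker rows follow the linear mixing model, noise rows are pure
# noise unrelated to the compositions.
noisy_gene_fixture <- function(p_marker = 30, p_noise = 30, q = 3, n = 300,
                               seed = 1) {
  set.seed(seed)
  p <- p_marker + p_noise
  Xm <- matrix(runif(p_marker * q, 0.05, 0.2), p_marker, q)
  block <- floor(p_marker / q)
  for (k in 1:q) Xm[((k - 1) * block + 1):(k * block), k] <- 1
  Xn <- matrix(runif(p_noise * q, 0.3, 0.7), p_noise, q)  # flat across types
  X <- rbind(Xm, Xn)
  rownames(X) <- paste0("g", 1:p)
  colnames(X) <- paste0("ct", 1:q)
  X <- normalize_columns(X)
  C <- matrix(rgamma(q * n, 2, 1), q, n)
  C <- sweep(C, 2, colSums(C), "/")
  Y <- X %*% C
  Y[1:p_marker, ] <- Y[1:p_marker, ] *
    exp(matrix(rnorm(p_marker * n, 0, 0.05), p_marker, n))
  Y[(p_marker + 1):p, ] <- Y[(p_marker + 1):p, ] *
    exp(matrix(rnorm(p_noise * n, 0, 1), p_noise, n))
  Y <- normalize_columns(Y)
  rownames(Y) <- rownames(X)
  list(X = X, Y = Y, C = C, marker = 1:p_marker, noise = (p_marker + 1):p)
}

# model-generated small instance shared by several solver tests
solver_fixture <- function(seed = 42, p = 12, q = 3, n = 10, noise = 0.05) {
  set.seed(seed)
  X <- normalize_columns(matrix(runif(p * q, 0.05, 1), p, q))
  Delta_s <- matrix(runif(p * q, 0.7, 1.3), p, q)
  C_s <- matrix(runif(q * n, 0.05, 0.3), q, n)
  x_s <- normalize_columns(matrix(runif(p, 0.05, 1), p, 1))[, 1]
  W <- Delta_s * X
  Y <- W %*% C_s + outer(x_s, 1 - colSums(W %*% C_s))
  Y <- normalize_columns(Y * exp(matrix(rnorm(p * n, 0, noise), p, n)))
  g <- normalize_weights(runif(p, 0.3, 1))
  list(X = X, Y = Y, g = g, Delta_s = Delta_s, C_s = C_s, x_s = x_s)
}
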