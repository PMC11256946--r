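#' ADTD loss function
#'
#' Evaluates the full adaptive-deconvolution objective
#' \deqn{\|G(Y - (\Delta\circ X)C - x(J_{1,n} - J_{1,p}(\Delta\circ X)C))\|_F^2
#'   + \lambda_1\|C - C_0\|_F^2 + \lambda_2\|J_{p,q} - \Delta\|_F^2,}
#' where \eqn{G = \mathrm{diag}(g)}, \eqn{\circ} is the Hadamard product and
#' \eqn{J_{a,b}} a matrix of ones. The per-sample hidden weight is the
#' substitution \eqn{c_i = 1 - \sum_j ((\Delta\circ X)C)_{ji}}. An infinite
#' `lambda1` (or `lambda2`) denotes the hard constraint \eqn{C = C_0}
#' (\eqn{\Delta = J}); the corresponding penalty term is then omitted.
#'
#' @param C composition matrix, q x n.
#' @param x background profile, length p (probability vector).
#' @param Delta rescaling matrix, p x q.
#' @param X reference matrix, p x q, column-normalized.
#' @param Y bulk matrix, p x n, column-normalized.
#' @param g gene weights, length p, unit Euclidean norm.
#' @param lambda1 ridge strength pulling `C` toward `C0` (may be `Inf`).
#' @param lambda2 ridge strength pulling `Delta` toward all-ones (may be `Inf`).
#' @param C0 the weighted-NNLS prior composition, q x n.
#' @return The scalar loss.
#' @export
adtd_loss <- function(C, x, Delta, X, Y, g, lambda1, lambda2, C0) {
  W <- Delta * X
  WC <- W %*% C
  chat <- 1 - colSums(WC)
  resid <- Y - WC - outer(x, chat)
  loss <- sum((g * resid)^2)
  if (is.finite(lambda1)) loss <- loss + lambda1 * sum((C - C0)^2)
  if (is.finite(lambda2)) loss <- loss + lambda2 * sum((1 - Delta)^2)
  loss
}

#' Composition update of the ADTD block-coordinate solver
#'
#' With the background `x` and the rescaled reference `X_eff` fixed, the loss
#' is, per sample, a strictly convex quadratic in the composition column,
#' solved exactly under \eqn{C \ge 0} and the budget constraint
#' \eqn{\sum_j (X_{eff} C)_{ji} \le 1} (so that hidden weights stay
#' non-negative).
#'
#' @param Y bulk matrix, p x n.
#' @param X_eff effective (rescaled) reference \eqn{\Delta \circ X}, p x q.
#' @param x background profile, length p.
#' @param g gene weights, length p.
#' @param lambda1 finite non-negative ridge strength toward `C0`.
#' @param C0 prior composition matrix, q x n.
#' @return Updated q x n composition matrix.
#' @export
adtd_solve_C <- function(Y, X_eff, x, g, lambda1, C0) {
  Y <- as.matrix(Y); X_eff <- as.matrix(X_eff); C0 <- as.matrix(C0)
  if (!is.finite(lambda1) || lambda1 < 0)
    stop("adtd_solve_C requires a finite non-negative lambda1")
  q <- ncol(X_eff); n <- ncol(Y)
  s <- colSums(X_eff)
  M <- X_eff - outer(x, s)
  g2 <- g^2
  H <- crossprod(M * g) + diag(lambda1, q)
  R <- .safe_chol(H)
  Mg2 <- t(M * g2)                       # q x p
  C <- matrix(0, q, n, dimnames = dimnames(C0))
  for (i in seq_len(n)) {
    z <- Y[, i] - x
    f <- -(Mg2 %*% z + lambda1 * C0[, i])
    C[, i] <- tryCatch(
      .qp_nonneg_budget(H, as.numeric(f), s, budget = 1, R = R),
      error = function(e) stop("composition update failed for sample ", i,
                               ": ", conditionMessage(e))
    )
  }
  C
}

#' Background-profile update of the ADTD block-coordinate solver
#'
#' With compositions fixed, the residual term is separable across genes in the
#' background profile `x`, giving a separable quadratic over the probability
#' simplex which is solved exactly. When every per-sample hidden weight
#' \eqn{c_i = 1 - \sum_j (X_{eff} C)_{ji}} is (numerically) zero, the
#' background does not enter the loss and is unidentifiable; a uniform
#' profile is returned with a warning.
#'
#' @inheritParams adtd_solve_C
#' @param C composition matrix, q x n.
#' @param tol hidden weights with magnitude below `tol` count as zero for the
#'   identifiability check.
#' @return Length-p background profile on the simplex.
#' @export
adtd_solve_x <- function(Y, X_eff, C, g, tol = 1e-10) {
  Y <- as.matrix(Y)
  p <- nrow(Y)
  WC <- X_eff %*% C
  chat <- 1 - colSums(WC)
  S <- sum(chat^2)
  if (max(abs(chat)) <= tol || S <= tol^2) {
    warning("background profile unidentifiable: all hidden weights are zero; ",
            "returning uniform profile")
    return(rep(1 / p, p))
  }
  Rm <- Y - WC
  Tj <- as.numeric(Rm %*% chat)
  g2 <- g^2
  .simplex_separable_qp(a = g2 * S, b = g2 * Tj)
}

#' Single-row rescaling update of the ADTD block-coordinate solver
#'
#' Minimizes the full loss with respect to one row \eqn{\Delta_{k,\cdot}} of
#' the rescaling matrix, all other rows, `C` and `x` fixed, subject to
#' non-negativity. The row enters the residual both directly (gene k's fitted
#' signal) and through the hidden weights of every sample, so the row
#' subproblem is a dense q-dimensional strictly convex QP; it is reduced to
#' non-negative least squares via Cholesky factorization.
#'
#' @param k gene (row) index to update.
#' @param Y bulk matrix, p x n.
#' @param X reference matrix, p x q (unscaled).
#' @param C composition matrix, q x n.
#' @param x background profile, length p.
#' @param g gene weights, length p.
#' @param lambda2 finite non-negative ridge strength toward one.
#' @param Delta current rescaling matrix, p x q.
#' @return The updated length-q row.
#' @export
adtd_solve_delta_row <- function(k, Y, X, C, x, g, lambda2, Delta) {
  Y <- as.matrix(Y); X <- as.matrix(X); C <- as.matrix(C)
  if (!is.finite(lambda2) || lambda2 < 0)
    stop("adtd_solve_delta_row requires a finite non-negative lambda2")
  W <- Delta * X
  WC <- W %*% C
  Rfull <- Y - WC
  u <- as.numeric(crossprod(g^2 * x, Rfull))
  s2_all <- sum(g^2 * x^2)
  .delta_row_qp(k, Y, X, C, x, g, lambda2, Delta,
                cs = colSums(WC), Rfull = Rfull, u = u, s2_all = s2_all)
}

# Core of the row update, on precomputed aggregates:
#   cs    = colSums((Delta * X) %*% C)      (length n)
#   Rfull = Y - (Delta * X) %*% C           (p x n)
#   u     = t(g^2 * x) %*% Rfull            (length n)
#   s2_all= sum(g^2 * x^2)
.delta_row_qp <- function(k, Y, X, C, x, g, lambda2, Delta,
                          cs, Rfull, u, s2_all) {
  q <- ncol(X)
  B <- C * X[k, ]                          # q x n, columns X_k o C_i
  dold <- Delta[k, ]
  zold <- as.numeric(dold %*% B)           # gene k's current fitted signal
  tvec <- 1 - cs + zold                    # hidden weights with row k removed
  gk2 <- g[k]^2; xk <- x[k]
  s2_other <- s2_all - gk2 * xk^2
  Ek <- Y[k, ] - xk * tvec
  w <- u - gk2 * xk * Rfull[k, ] - tvec * s2_other
  kap <- gk2 * (1 - xk)^2 + s2_other
  beta <- gk2 * (1 - xk) * Ek - w
  H <- kap * tcrossprod(B) + diag(lambda2, q)
  f <- -(as.numeric(B %*% beta) + lambda2 * rep(1, q))
  d <- .qp_nonneg(H, f)
  # The hidden weights c_i(delta) = t_i - delta' b_i must stay non-negative
  # (the per-sample budget constraint, linear in the row). When the
  # unconstrained row minimizer violates it, re-solve with the violated
  # constraints included, so every block update preserves feasibility and
  # the loss decreases monotonically.
  viol <- as.numeric(d %*% B) > tvec + 1e-10
  if (any(viol)) {
    bb <- pmax(tvec, 0)
    sol <- tryCatch(
      pracma::quadprog(H, f, A = t(B), b = bb, lb = rep(0, q)),
      error = function(e) NULL)
    if (!is.null(sol) && all(is.finite(sol$xmin))) {
      d <- pmax(sol$xmin, 0)
    } else {
      # conservative fallback: shrink toward the feasible current row
      lo <- 0; hi <- 1
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        cand <- Delta[k, ] + mid * (d - Delta[k, ])
        if (all(as.numeric(cand %*% B) <= tvec + 1e-12)) lo <- mid else hi <- mid
      }
      d <- Delta[k, ] + lo * (d - Delta[k, ])
    }
  }
  d
}

#' Adaptive digital tissue deconvolution
#'
#' Block-coordinate minimization of [adtd_loss()] over the composition matrix
#' `C`, the hidden background profile `x`, and the reference-rescaling matrix
#' `Delta`, under non-negativity, the per-sample budget
#' \eqn{\sum_j ((\Delta\circ X)C)_{ji} \le 1}, and \eqn{\sum_j x_j = 1}.
#' Each outer iteration updates `C` (exact constrained QP per sample), then
#' `x` (exact simplex QP), then sweeps the rows of `Delta` (exact
#' non-negative QPs), so the loss is non-increasing across every block
#' update. Initialization follows the naive solution: `C = C0` (weighted
#' NNLS with weights \eqn{g_j^2}), `Delta` all ones, `x` uniform.
#'
#' The limits of the two ridge penalties recover simpler estimators:
#' `lambda1 = Inf` freezes `C = C0` (the plain weighted-NNLS composition) and
#' `lambda2 = Inf` (or `adapt_reference = FALSE`) freezes `Delta` at one,
#' i.e. background estimation without reference adaptation.
#'
#' @param X reference matrix, p genes x q cell types, column-normalized
#'   (small drift is re-normalized, see [normalize_columns()]).
#' @param Y bulk matrix, p x n, column-normalized.
#' @param g gene weights, length p; normalized to unit Euclidean norm
#'   internally. Default: uniform weights.
#' @param lambda1 ridge strength toward the naive composition `C0`;
#'   default 0.1. `Inf` enforces `C = C0` exactly.
#' @param lambda2 ridge strength pulling `Delta` toward all-ones; default
#'   1e-8. `Inf` (or `adapt_reference = FALSE`) disables adaptation.
#' @param adapt_reference logical; `FALSE` is shorthand for `lambda2 = Inf`.
#' @param max_iter maximum number of outer iterations (default 1000).
#' @param tol relative loss-change convergence tolerance (default 1e-7).
#' @param C0 optional precomputed prior composition; computed internally by
#'   [weighted_nnls()] with weights `g^2` when missing.
#' @param x0 initialization of the background profile: `"residual"` (default)
#'   starts from the normalized positive part of the mean naive residual
#'   `Y - X C0` (falling back to uniform when that residual has no positive
#'   part), `"uniform"` starts from `1/p`, or a length-p non-negative vector.
#'   The residual start matters: from an uninformative profile the first
#'   composition update can saturate the budget constraint, which zeroes all
#'   hidden weights and leaves the background unidentifiable.
#' @param verbose print the loss every 25 iterations.
#' @return An object of class `adtd_fit`: list with elements `C` (q x n),
#'   `x` (length p), `Delta` (p x q), `c` (hidden weights, clipped to
#'   \[0, 1\]), `c_raw`, `C0`, `loss` (final), `loss_trace` (per outer
#'   iteration), `block_trace` (loss after every block update, for
#'   monotonicity diagnostics), `converged`, `iterations`, and the
#'   hyperparameters used.
#' @examples
#' X <- normalize_columns(matrix(c(5, 1, 1, 1, 1, 5, 1, 1), 4))
#' C <- matrix(c(.3, .5, .6, .2), 2)
#' Y <- normalize_columns(X %*% C + 0.05)
#' fit <- fit_adtd(X, Y, lambda1 = 0.1, lambda2 = 1e-4, max_iter = 50)
#' fit$c
#' @export
fit_adtd <- function(X, Y, g = NULL, lambda1 = 0.1, lambda2 = 1e-8,
                     adapt_reference = TRUE, max_iter = 1000, tol = 1e-7,
                     C0 = NULL, x0 = "residual", verbose = FALSE) {
  # first step of the procedure: put reference and bulks on the proportion
  # scale (idempotent for already-normalized input)
  X <- normalize_columns(as.matrix(X))
  Y <- normalize_columns(as.matrix(Y))
  if (nrow(X) != nrow(Y)) stop("X and Y must share the gene space (rows)")
  p <- nrow(X); q <- ncol(X); n <- ncol(Y)
  if (is.null(g)) g <- rep(1, p)
  if (length(g) != p) stop("gene weights g must have length nrow(X)")
  g <- normalize_weights(g)
  if (!adapt_reference) lambda2 <- Inf
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be non-negative")
  if (is.finite(lambda1) && is.finite(lambda2) &&
      lambda1 < 1e-7 && lambda2 < 1e-7) {
    warning("both lambda1 and lambda2 are below 1e-7; ",
            "estimates of Delta and C may overfit")
  }
  if (is.null(C0)) C0 <- weighted_nnls(X, Y, g^2)
  C0 <- as.matrix(C0)

  C <- C0
  Delta <- matrix(1, p, q, dimnames = dimnames(X))
  if (is.numeric(x0)) {
    if (length(x0) != p || any(x0 < 0) || sum(x0) == 0)
      stop("numeric x0 must be a length-p non-negative vector with positive sum")
    x <- x0 / sum(x0)
  } else {
    x0 <- match.arg(x0, c("residual", "uniform"))
    x <- rep(1 / p, p)
    if (x0 == "residual") {
      res <- pmax(rowMeans(Y - X %*% C0), 0)
      if (sum(res) > 0) x <- res / sum(res)
    }
  }
  names(x) <- rownames(X)

  loss <- adtd_loss(C, x, Delta, X, Y, g, lambda1, lambda2, C0)
  loss_trace <- numeric(0)
  block_step <- character(0)
  block_loss <- numeric(0)
  converged <- FALSE
  it <- 0

  while (it < max_iter) {
    it <- it + 1
    loss_prev <- loss
    W <- Delta * X

    if (is.finite(lambda1)) {
      C <- adtd_solve_C(Y, W, x, g, lambda1, C0)
      loss <- adtd_loss(C, x, Delta, X, Y, g, lambda1, lambda2, C0)
      block_step <- c(block_step, "C"); block_loss <- c(block_loss, loss)
    }

    x <- withCallingHandlers(
      adtd_solve_x(Y, W, C, g),
      warning = function(wrn) {
        if (it > 1) invokeRestart("muffleWarning")
      })
    names(x) <- rownames(X)
    loss <- adtd_loss(C, x, Delta, X, Y, g, lambda1, lambda2, C0)
    block_step <- c(block_step, "x"); block_loss <- c(block_loss, loss)

    if (is.finite(lambda2)) {
      Delta <- .delta_sweep(Y, X, C, x, g, lambda2, Delta)
      loss <- adtd_loss(C, x, Delta, X, Y, g, lambda1, lambda2, C0)
      block_step <- c(block_step, "Delta"); block_loss <- c(block_loss, loss)
    }

    loss_trace <- c(loss_trace, loss)
    if (verbose && it %% 25 == 0)
      message(sprintf("iteration %d: loss %.8g", it, loss))
    if (abs(loss_prev - loss) <= tol * max(1, abs(loss_prev))) {
      converged <- TRUE
      break
    }
  }

  # A closing composition update (after the last Delta sweep) restores exact
  # feasibility of the budget constraint with respect to the final reference.
  if (is.finite(lambda1) && is.finite(lambda2)) {
    C <- adtd_solve_C(Y, Delta * X, x, g, lambda1, C0)
    loss <- adtd_loss(C, x, Delta, X, Y, g, lambda1, lambda2, C0)
    block_step <- c(block_step, "C"); block_loss <- c(block_loss, loss)
  }

  c_raw <- 1 - colSums((Delta * X) %*% C)
  names(c_raw) <- colnames(Y)
  structure(list(
    C = C, x = x, Delta = Delta,
    c = pmin(1, pmax(0, c_raw)), c_raw = c_raw,
    C0 = C0, g = g,
    loss = loss, loss_trace = loss_trace,
    block_trace = data.frame(step = block_step, loss = block_loss),
    converged = converged, iterations = it,
    lambda1 = lambda1, lambda2 = lambda2, tol = tol
  ), class = "adtd_fit")
}

# One full row sweep over Delta with incremental bookkeeping of the fitted
# signal, residuals and their weighted aggregates (the naive per-row
# recomputation would cost O(p^2 q n) per sweep; this is O(p q n)).
.delta_sweep <- function(Y, X, C, x, g, lambda2, Delta) {
  p <- nrow(X)
  W <- Delta * X
  WC <- W %*% C
  cs <- colSums(WC)
  Rfull <- Y - WC
  g2x <- g^2 * x
  u <- as.numeric(crossprod(g2x, Rfull))
  s2_all <- sum(g^2 * x^2)
  for (k in seq_len(p)) {
    dnew <- tryCatch(
      .delta_row_qp(k, Y, X, C, x, g, lambda2, Delta,
                    cs = cs, Rfull = Rfull, u = u, s2_all = s2_all),
      error = function(e) {
        warning("rescaling update failed for gene ",
                if (!is.null(rownames(X))) rownames(X)[k] else k,
                "; keeping previous row")
        Delta[k, ]
      })
    B <- C * X[k, ]
    znew <- as.numeric(dnew %*% B)
    zold <- as.numeric(Delta[k, ] %*% B)
    dz <- znew - zold
    cs <- cs + dz
    rk_new <- Rfull[k, ] - dz
    u <- u + g2x[k] * (rk_new - Rfull[k, ])
    Rfull[k, ] <- rk_new
    Delta[k, ] <- dnew
  }
  Delta
}

#' @export
print.adtd_fit <- function(x, ...) {
  cat("Adaptive digital tissue deconvolution fit\n")
  cat(sprintf("  genes: %d, cell types: %d, samples: %d\n",
              nrow(x$Delta), ncol(x$Delta), ncol(x$C)))
  cat(sprintf("  lambda1 = %g, lambda2 = %g\n", x$lambda1, x$lambda2))
  cat(sprintf("  %s after %d iterations, final loss %.6g\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$loss))
  cat(sprintf("  hidden weights: mean %.3f (range %.3f-%.3f)\n",
              mean(x$c), min(x$c), max(x$c)))
  invisible(x)
}
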