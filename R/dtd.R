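#' Outer loss for gene-weight learning
#'
#' The training objective for digital tissue deconvolution: the negative sum
#' of per-cell-type Pearson correlations between known training compositions
#' and the compositions recovered by weighted non-negative least squares with
#' gene weights `g`,
#' \deqn{L(g) = -\sum_j \mathrm{cor}(C_{j,\cdot}, \hat C_{j,\cdot}(g)),
#'   \qquad \|g\|_2 = 1 .}
#' Minimizing it maximizes recovery of all cell types simultaneously.
#' Cell types whose true or estimated proportions have zero variance have an
#' undefined correlation; they contribute zero to the sum (with a message).
#'
#' @param g gene weights, length p, non-negative; normalized internally.
#' @param X reference matrix, p x q.
#' @param Y_train training bulk matrix, p x n.
#' @param C_train known training compositions, q x n.
#' @return Scalar loss in \[-q, q\]; the per-type correlations are attached
#'   as attribute `"correlations"`.
#' @export
dtd_outer_loss <- function(g, X, Y_train, C_train) {
  g <- normalize_weights(g)
  C_hat <- weighted_nnls(X, Y_train, g^2)
  r <- .rowwise_pearson(as.matrix(C_train), C_hat)
  und <- is.na(r)
  if (any(und)) {
    message("dtd_outer_loss: ", sum(und),
            " cell type(s) with zero-variance proportions contribute 0")
    r[und] <- 0
  }
  structure(-sum(r), correlations = r)
}

# Pearson correlation row by row; NA where either row is (numerically)
# constant.
.rowwise_pearson <- function(A, B) {
  stopifnot(dim(A) == dim(B))
  vapply(seq_len(nrow(A)), function(j) {
    a <- A[j, ]; b <- B[j, ]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
}

#' Learn gene weights from training mixtures
#'
#' Minimizes [dtd_outer_loss()] over non-negative unit-norm gene weights by
#' gradient descent on a smooth surrogate: the weights are parametrized as
#' \eqn{g = \mathrm{softplus}(u)} (scale is irrelevant, the inner fit is
#' invariant to rescaling the weights) and the gradient is taken through the
#' *unconstrained* weighted-least-squares inner solution, which admits an
#' analytic derivative. The true outer loss, with the non-negative inner fit,
#' is evaluated at the initialization and at regular checkpoints of the
#' optimization, and the best iterate under the true loss is returned -- so
#' the returned weights never do worse than the starting point.
#'
#' Cell types with zero-variance training proportions are excluded from the
#' objective (Pearson is undefined for them).
#'
#' The returned weights are shrunk toward uniform: the squared weights are
#' blended as `(1 - shrinkage) * g^2 + shrinkage / p`. Training mixtures
#' contain only the reference cell types, so fully trusting the learned
#' weights would discard genes that carry no information about those types
#' but may identify contributions the training never saw (the hidden
#' background); the floor keeps every gene minimally weighted. Candidate
#' selection operates on the shrunk weights, so the guarantee above holds
#' for what is actually returned.
#'
#' @param X reference matrix, p x q.
#' @param Y_train training bulk matrix, p x n (n at least q + 2).
#' @param C_train known training compositions, q x n.
#' @param shrinkage blending weight toward uniform squared weights, in
#'   \[0, 1\] (default 0.5; 0 disables the floor).
#' @param max_iter total L-BFGS iteration budget (default 5000).
#' @param n_checkpoints number of segments at whose ends the true outer loss
#'   is evaluated (default 10).
#' @param rel_tol stop when the relative change of the surrogate loss between
#'   checkpoints falls below this (default 1e-6).
#' @param seed integer; recorded for provenance (the optimizer itself is
#'   deterministic from the uniform start).
#' @return Object of class `dtd_weights`: list with `g` (unit-norm weights,
#'   named by gene), `loss` (outer loss of `g`), `loss_init` (outer loss of
#'   uniform weights), `correlations` (per cell type at `g`), `converged`,
#'   and `trace` (outer loss at each checkpoint).
#' @export
fit_gene_weights <- function(X, Y_train, C_train, shrinkage = 0.5,
                             max_iter = 5000,
                             n_checkpoints = 10, rel_tol = 1e-6, seed = 1L) {
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  X <- as.matrix(X); Y_train <- as.matrix(Y_train); C_train <- as.matrix(C_train)
  p <- nrow(X); q <- ncol(X); n <- ncol(Y_train)
  if (nrow(Y_train) != p) stop("X and Y_train must share the gene space")
  if (ncol(C_train) != n || nrow(C_train) != q)
    stop("C_train must be q x n, matching X and Y_train")
  if (n < q + 2) stop("need at least q + 2 training mixtures")
  keep <- apply(C_train, 1, stats::sd) > 1e-12
  if (!all(keep)) {
    message("fit_gene_weights: excluding ", sum(!keep),
            " cell type(s) with constant training proportions from the loss")
  }
  Ct <- C_train[keep, , drop = FALSE]
  Ctc <- Ct - rowMeans(Ct)                       # centered truth rows
  Ctn <- sqrt(rowSums(Ctc^2))

  # surrogate loss and analytic gradient in the softplus parametrization
  sp <- function(u) ifelse(u > 30, u, log1p(exp(u)))
  surrogate <- function(u) {
    g2 <- sp(u)^2
    A <- crossprod(X * g2, X)
    diag(A) <- diag(A) + 1e-12 * (mean(diag(A)) + 1)
    Ai <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ai)) return(list(value = 0, grad = rep(0, p)))
    Bm <- crossprod(X * g2, Y_train)
    Chat <- Ai %*% Bm
    Ch <- Chat[keep, , drop = FALSE]
    Chc <- Ch - rowMeans(Ch)
    Chn <- sqrt(rowSums(Chc^2))
    ok <- Chn > 1e-12
    cr <- rep(0, nrow(Ch))
    cr[ok] <- rowSums(Ctc * Chc)[ok] / (Ctn * Chn)[ok]
    # d(-sum cor)/dChat, row-wise; zero for degenerate rows
    D <- matrix(0, q, n)
    idx <- which(keep)[ok]
    D[idx, ] <- -(Ctc[ok, , drop = FALSE] / (Ctn[ok] * Chn[ok]) -
                    cr[ok] * Chc[ok, , drop = FALSE] / Chn[ok]^2)
    Rm <- Y_train - X %*% Chat
    AiXt <- Ai %*% t(X)                          # q x p
    grad_g2 <- colSums(AiXt * (D %*% t(Rm)))
    grad_u <- grad_g2 * 2 * sp(u) * stats::plogis(u)
    list(value = -sum(cr), grad = grad_u)
  }

  shrink <- function(g) {
    g <- normalize_weights(g)
    normalize_weights(sqrt((1 - shrinkage) * g^2 + shrinkage / length(g)))
  }
  outer_loss_of <- function(u) {
    as.numeric(dtd_outer_loss_masked(shrink(sp(u)), X, Y_train, Ct, keep))
  }

  u <- rep(log(expm1(1)), p)                     # softplus(u) = 1: uniform start
  best_u <- u
  best_loss <- outer_loss_of(u)
  loss_init <- best_loss
  trace <- best_loss
  chunk <- max(1, ceiling(max_iter / n_checkpoints))
  prev_val <- surrogate(u)$value
  converged <- FALSE
  for (ck in seq_len(n_checkpoints)) {
    opt <- stats::optim(u, fn = function(u) surrogate(u)$value,
                        gr = function(u) surrogate(u)$grad,
                        method = "L-BFGS-B",
                        control = list(maxit = chunk))
    u <- opt$par
    ol <- outer_loss_of(u)
    trace <- c(trace, ol)
    if (ol < best_loss) { best_loss <- ol; best_u <- u }
    if (abs(prev_val - opt$value) <= rel_tol * max(1, abs(prev_val))) {
      converged <- TRUE
      break
    }
    prev_val <- opt$value
  }
  if (!converged && length(trace) >= 2 &&
      abs(trace[length(trace)] - trace[length(trace) - 1]) <=
        rel_tol * max(1, abs(trace[length(trace) - 1]))) {
    converged <- TRUE
  }
  if (!converged)
    warning("fit_gene_weights: iteration budget exhausted before convergence; ",
            "returning best iterate")
  g <- shrink(sp(best_u))
  names(g) <- rownames(X)
  final <- dtd_outer_loss(g, X, Y_train, C_train)
  structure(list(g = g, loss = as.numeric(final),
                 correlations = attr(final, "correlations"),
                 loss_init = loss_init, trace = trace,
                 converged = converged, seed = seed),
            class = "dtd_weights")
}

# outer loss restricted to cell types with variable training proportions
dtd_outer_loss_masked <- function(g, X, Y_train, Ct, keep) {
  C_hat <- weighted_nnls(X, Y_train, g^2)[keep, , drop = FALSE]
  r <- .rowwise_pearson(Ct, C_hat)
  r[is.na(r)] <- 0
  -sum(r)
}

#' @export
print.dtd_weights <- function(x, ...) {
  cat("Learned deconvolution gene weights\n")
  cat(sprintf("  genes: %d; outer loss %.4f (uniform start: %.4f)\n",
              length(x$g), x$loss, x$loss_init))
  r <- x$correlations
  cat("  per-type training correlations: ",
      paste(sprintf("%.3f", r), collapse = ", "), "\n")
  invisible(x)
}
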