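# Internal convex-QP helpers.
#
# All ADTD block updates are strictly convex quadratic programs with simple
# constraint sets, and are reduced to forms with exact finite solvers:
#   * non-negativity only: Cholesky factorization turns the QP into a
#     non-negative least-squares problem (Lawson-Hanson, exact KKT);
#   * non-negativity plus one linear budget inequality: bisection on the
#     budget's Lagrange multiplier, each trial point an NNLS solve;
#   * separable quadratic over the probability simplex: bisection on the
#     simplex multiplier (the solution is piecewise linear in it).

# Cholesky with escalating jitter for numerically semi-definite H.
.safe_chol <- function(H) {
  R <- tryCatch(chol(H), error = function(e) NULL)
  jit <- mean(diag(H)) + 1
  for (eps in c(1e-12, 1e-10, 1e-8)) {
    if (!is.null(R)) return(R)
    R <- tryCatch(chol(H + diag(eps * jit, nrow(H))), error = function(e) NULL)
  }
  stop("Cholesky factorization failed: quadratic form is not positive definite")
}

# min 0.5 c'Hc + f'c  s.t.  c >= 0
.qp_nonneg <- function(H, f, R = NULL) {
  if (is.null(R)) R <- .safe_chol(H)
  d <- backsolve(R, -f, transpose = TRUE)
  pracma::lsqnonneg(R, d)$x
}

# min 0.5 c'Hc + f'c  s.t.  c >= 0, s'c <= budget
# Bisection on the multiplier mu >= 0 of the budget constraint: the solution
# of the relaxed problem with f + mu*s has s'c(mu) non-increasing in mu.
.qp_nonneg_budget <- function(H, f, s, budget = 1, tol = 1e-11, R = NULL) {
  if (is.null(R)) R <- .safe_chol(H)
  cc <- .qp_nonneg(H, f, R = R)
  if (sum(s * cc) <= budget + tol) return(cc)
  mu_lo <- 0
  mu_hi <- 1
  for (i in 1:80) {
    cc <- .qp_nonneg(H, f + mu_hi * s, R = R)
    if (sum(s * cc) <= budget) break
    mu_lo <- mu_hi
    mu_hi <- mu_hi * 4
  }
  for (i in 1:100) {
    mu <- (mu_lo + mu_hi) / 2
    cc <- .qp_nonneg(H, f + mu * s, R = R)
    v <- sum(s * cc)
    if (abs(v - budget) <= tol) break
    if (v > budget) mu_lo <- mu else mu_hi <- mu
  }
  if (sum(s * cc) > budget + 1e-9) {
    # fall back to the upper bracket (feasible side)
    cc <- .qp_nonneg(H, f + mu_hi * s, R = R)
  }
  # polish: exact KKT solve on the active set identified by the bisection
  act <- cc > 1e-12
  if (any(act)) {
    nA <- sum(act)
    K <- rbind(cbind(H[act, act, drop = FALSE], s[act]),
               c(s[act], 0))
    rhs <- c(-f[act], budget)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      cA <- sol[seq_len(nA)]
      nu <- sol[nA + 1]
      cand <- numeric(length(cc))
      cand[act] <- cA
      grad_in <- (H %*% cand + f + nu * s)[!act]
      if (nu >= -1e-10 && all(cA >= -1e-12) &&
          (!length(grad_in) || all(grad_in >= -1e-8))) {
        cand[cand < 0] <- 0
        obj <- function(v) 0.5 * sum(v * (H %*% v)) + sum(f * v)
        if (obj(cand) <= obj(cc) && sum(s * cand) <= budget + 1e-9) cc <- cand
      }
    }
  }
  cc
}

# min sum_j (a_j x_j^2 - 2 b_j x_j)  s.t.  x >= 0, sum(x) = 1
# a_j >= 0; entries with a_j == 0 (zero-weight genes) are pinned to zero.
# Stationarity for x_j > 0: x_j = (b_j - mu/2) / a_j, and sum_j x_j(mu) = 1
# is solved for mu by bisection (monotone, piecewise linear).
.simplex_separable_qp <- function(a, b) {
  act <- a > 0
  if (!any(act)) stop("simplex QP: all quadratic coefficients are zero")
  aa <- a[act]; bb <- b[act]
  xs <- function(mu) pmax(0, (bb - mu / 2) / aa)
  mu_hi <- 2 * max(bb)            # all coordinates at zero
  mu_lo <- 2 * min(bb - aa)       # at least one coordinate >= 1
  for (i in 1:200) {
    mu <- (mu_lo + mu_hi) / 2
    s <- sum(xs(mu))
    if (s > 1) mu_lo <- mu else mu_hi <- mu
    if (mu_hi - mu_lo < 1e-15 * (abs(mu_hi) + 1)) break
  }
  x <- numeric(length(a))
  xv <- xs((mu_lo + mu_hi) / 2)
  x[act] <- xv / sum(xv)          # polish the simplex constraint exactly
  x
}
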