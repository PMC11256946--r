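#' Normalize matrix columns to unit sum
#'
#' Divides every column of a non-negative matrix by its column sum, so that
#' each column describes per-gene fractions of the total signal. Both the
#' reference matrix and the bulk matrix are normalized this way before any
#' deconvolution, which puts cell-type weights and hidden weights on a common
#' proportion scale.
#'
#' @param M Numeric matrix with non-negative entries; columns are samples or
#'   cell types, rows are genes.
#' @return A matrix of the same shape whose columns sum to one.
#' @examples
#' normalize_columns(matrix(c(2, 2, 1, 3), nrow = 2))
#' @export
normalize_columns <- function(M) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("normalize_columns: matrix contains negative entries")
  cs <- colSums(M)
  if (any(cs == 0)) {
    bad <- which(cs == 0)
    nm <- colnames(M)[bad]
    lab <- if (is.null(nm)) paste(bad, collapse = ", ") else paste(nm, collapse = ", ")
    stop("normalize_columns: column(s) sum to zero: ", lab)
  }
  sweep(M, 2, cs, "/")
}

#' Check that columns sum to one, re-normalizing small drift
#'
#' File round-tripping perturbs column sums slightly; sums within `soft_tol`
#' of one are silently re-normalized, larger deviations raise an error.
#'
#' @param M numeric matrix.
#' @param tol absolute tolerance considered already normalized.
#' @param soft_tol deviation up to which silent re-normalization is applied.
#' @return Matrix with columns summing to one.
#' @keywords internal
ensure_normalized <- function(M, tol = 1e-8, soft_tol = 1e-4) {
  cs <- colSums(M)
  dev <- abs(cs - 1)
  if (all(dev <= tol)) return(M)
  if (any(dev > soft_tol)) {
    stop("matrix columns do not sum to 1 (max deviation ",
         format(max(dev)), "); normalize with normalize_columns() first")
  }
  normalize_columns(M)
}

#' Align a reference and a bulk matrix on shared genes
#'
#' Intersects the row names of the two matrices and returns both restricted to
#' the shared genes, in the order of the reference matrix.
#'
#' @param X reference matrix (genes x cell types) with row names.
#' @param Y bulk matrix (genes x samples) with row names.
#' @return List with elements `X` and `Y` on the common gene space.
#' @export
align_genes <- function(X, Y) {
  if (is.null(rownames(X)) || is.null(rownames(Y)))
    stop("align_genes: both matrices need gene identifiers as row names")
  common <- intersect(rownames(X), rownames(Y))
  if (length(common) == 0) stop("align_genes: no shared genes")
  list(X = X[common, , drop = FALSE], Y = Y[common, , drop = FALSE])
}

#' Weighted non-negative least squares deconvolution
#'
#' Estimates cellular weights C by minimizing, per bulk sample i,
#' \deqn{\sum_j \gamma_j (Y_{ji} - \sum_k X_{jk} C_{ki})^2 \quad
#'   \mathrm{s.t.}\ C \ge 0,}
#' i.e. non-negative least squares with per-gene weights \eqn{\gamma_j}
#' (typically the squared learned gene weights, \eqn{\gamma_j = g_j^2}).
#'
#' @param X reference matrix, p genes x q cell types.
#' @param Y bulk matrix, p genes x n samples (a vector is treated as one
#'   sample).
#' @param gamma length-p vector of non-negative gene weights; a single value
#'   is recycled. Default 1 (unweighted NNLS).
#' @return A q x n matrix of non-negative cellular weights, with cell-type
#'   row names taken from `colnames(X)`.
#' @examples
#' X <- cbind(a = c(.5, .3, .2), b = c(.1, .3, .6))
#' C <- matrix(c(.4, .6), 2)
#' weighted_nnls(X, X %*% C)
#' @export
weighted_nnls <- function(X, Y, gamma = 1) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    stop("weighted_nnls: X and Y must have the same number of genes (rows)")
  p <- nrow(X); q <- ncol(X); n <- ncol(Y)
  if (length(gamma) == 1) gamma <- rep(gamma, p)
  if (length(gamma) != p) stop("weighted_nnls: gamma must have length nrow(X)")
  if (any(gamma < 0)) stop("weighted_nnls: gamma must be non-negative")
  C <- matrix(0, q, n, dimnames = list(colnames(X), colnames(Y)))
  if (all(gamma == 0)) {
    warning("weighted_nnls: all gene weights are zero; returning all-zero composition")
    return(C)
  }
  w <- sqrt(gamma)
  Xw <- X * w
  Yw <- Y * w
  for (i in seq_len(n)) {
    C[, i] <- pracma::lsqnonneg(Xw, Yw[, i])$x
  }
  C
}

#' Naive hidden-cell proportion
#'
#' The EPIC-style estimate of the hidden (background) proportion per sample:
#' one minus the summed estimated cell-type weights, clipped at zero,
#' \eqn{\hat c_i = \max\{0, 1 - \sum_k \hat C_{ki}\}}. Valid when both the
#' reference and the bulks are column-normalized to sum one.
#'
#' @param C_hat estimated composition matrix (q cell types x n samples),
#'   non-negative.
#' @return Length-n vector of hidden proportions in \[0, 1\].
#' @export
naive_hidden_proportion <- function(C_hat) {
  C_hat <- as.matrix(C_hat)
  if (any(C_hat < 0)) stop("naive_hidden_proportion: C_hat must be non-negative")
  pmax(0, 1 - colSums(C_hat))
}

#' Gene-wise rescaling of a bulk matrix onto a reference platform
#'
#' Compensates systematic cross-platform differences between bulk data and the
#' (e.g. single-cell derived) training data: every gene row of the bulk matrix
#' is multiplied by the ratio of the mean expression in the training
#' pseudo-bulks to the mean expression in matched control bulks. Genes whose
#' control mean is zero cannot be rescaled and are dropped (with a message).
#'
#' @param Y_bulk bulk matrix, genes x samples, with gene row names.
#' @param train_pseudobulk_mean length-p per-gene mean of the training
#'   pseudo-bulks, same gene order as `Y_bulk`.
#' @param control_mean length-p per-gene mean of the control bulks.
#' @return Rescaled bulk matrix; rows with zero control mean removed.
#' @export
rescale_bulk_to_reference <- function(Y_bulk, train_pseudobulk_mean, control_mean) {
  Y_bulk <- as.matrix(Y_bulk)
  p <- nrow(Y_bulk)
  if (length(train_pseudobulk_mean) != p || length(control_mean) != p)
    stop("rescale_bulk_to_reference: mean vectors must match nrow(Y_bulk)")
  keep <- control_mean != 0
  if (!all(keep)) {
    message("rescale_bulk_to_reference: dropping ", sum(!keep),
            " gene(s) with zero control mean")
  }
  factors <- train_pseudobulk_mean[keep] / control_mean[keep]
  Y_bulk[keep, , drop = FALSE] * factors
}

#' Normalize a gene-weight vector
#'
#' Gene weights are defined up to scale (only the relative weighting matters
#' for the fits), and are stored with unit Euclidean norm.
#'
#' @param g non-negative numeric vector.
#' @return `g / sqrt(sum(g^2))`.
#' @export
normalize_weights <- function(g) {
  if (any(g < 0)) stop("gene weights must be non-negative")
  nrm <- sqrt(sum(g^2))
  if (nrm == 0) stop("gene weights are all zero")
  g / nrm
}
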