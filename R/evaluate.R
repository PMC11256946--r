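#' Per-cell-type recovery correlations
#'
#' Pearson correlation between true and estimated proportions, computed per
#' cell type across samples, plus their unweighted mean. Cell types whose
#' true or estimated proportions are constant have an undefined correlation;
#' they are reported as `NA` and excluded from the mean (with a warning).
#'
#' @param C_true true composition matrix, q x n.
#' @param C_hat estimated composition matrix, q x n.
#' @return List with `per_type` (named correlation vector) and `mean_r`.
#' @export
recovery_correlations <- function(C_true, C_hat) {
  C_true <- as.matrix(C_true); C_hat <- as.matrix(C_hat)
  if (!all(dim(C_true) == dim(C_hat)))
    stop("C_true and C_hat must have matching dimensions")
  r <- .rowwise_pearson(C_true, C_hat)
  names(r) <- rownames(C_true)
  if (anyNA(r)) {
    warning("undefined correlation for cell type(s) ",
            paste(which(is.na(r)), collapse = ", "),
            " (zero variance); excluded from the mean")
  }
  list(per_type = r, mean_r = mean(r, na.rm = TRUE))
}

#' Recovery of hidden proportions and of the hidden profile
#'
#' Pearson correlation between a true and an estimated vector (per-sample
#' hidden proportions, or the per-gene hidden background profile). Constant
#' vectors give `NA` with a warning.
#'
#' @param truth,estimate numeric vectors of equal length.
#' @return Scalar correlation (or `NA`).
#' @export
hidden_recovery <- function(truth, estimate) {
  if (length(truth) != length(estimate)) stop("length mismatch")
  if (stats::sd(truth) < 1e-12 || stats::sd(estimate) < 1e-12) {
    warning("correlation undefined: constant vector")
    return(NA_real_)
  }
  stats::cor(truth, estimate)
}

#' @rdname hidden_recovery
#' @export
profile_recovery <- hidden_recovery

# Mann-Whitney AUC with midrank tie handling.
.rank_auc <- function(score, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Regulation-detection AUC
#'
#' Measures how well deviations of the estimated rescaling matrix from one
#' separate the spiked (regulated) (gene, cell type) entries from the
#' unspiked ones. Up-regulated entries (factor > 0) are scored by
#' \eqn{\Delta_{jk} - 1}, down-regulated entries (factor < 0) by
#' \eqn{1 - \Delta_{jk}}; in both directions the negatives are the unspiked
#' entries (by default every unspiked (gene, type) pair of the matrix). The
#' returned value is the mean of the up- and down-AUCs; if only one
#' direction was spiked, that single AUC is returned with a warning.
#'
#' @param Delta_hat estimated rescaling matrix, p x q.
#' @param spec the `regulation_spec` used to generate the data.
#' @param negatives `"all_unspiked"` (default) uses every unspiked
#'   (gene, type) entry as negatives; `"unspiked_genes"` restricts negatives
#'   to entries of genes never spiked in any type.
#' @return Scalar AUC in \[0, 1\], with attributes `auc_up` and `auc_down`.
#' @export
regulation_auc <- function(Delta_hat, spec,
                           negatives = c("all_unspiked", "unspiked_genes")) {
  negatives <- match.arg(negatives)
  Delta_hat <- as.matrix(Delta_hat)
  lab <- matrix(0, nrow(Delta_hat), ncol(Delta_hat))
  ci <- match(spec$celltype, colnames(Delta_hat))
  if (anyNA(ci)) stop("spec cell types not found in Delta_hat columns")
  lab[cbind(spec$gene, ci)] <- sign(spec$factor)
  neg <- if (negatives == "all_unspiked") lab == 0 else {
    spiked_gene <- seq_len(nrow(lab)) %in% spec$gene
    lab == 0 & !spiked_gene
  }
  dev <- Delta_hat - 1
  auc_dir <- function(pos_lab, score) {
    pos <- lab == pos_lab
    if (!any(pos)) return(NA_real_)
    use <- pos | neg
    .rank_auc(score[use], pos[use])
  }
  auc_up <- auc_dir(1, dev)
  auc_down <- auc_dir(-1, -dev)
  if (is.na(auc_up) || is.na(auc_down)) {
    warning("only one regulation direction present; returning its AUC alone")
  }
  structure(mean(c(auc_up, auc_down), na.rm = TRUE),
            auc_up = auc_up, auc_down = auc_down)
}

#' Rank genes by the strength of inferred regulation
#'
#' Orders genes by the largest deviation of their rescaling factors from one,
#' \eqn{\max_k |\Delta_{jk} - 1|}, ties broken by ascending gene index, and
#' reports the cell type attaining the maximum.
#'
#' @param Delta_hat estimated rescaling matrix with gene row names.
#' @return Data frame with columns `gene`, `score`, `celltype`, ordered by
#'   decreasing score.
#' @export
rank_regulated_genes <- function(Delta_hat) {
  Delta_hat <- as.matrix(Delta_hat)
  if (is.null(colnames(Delta_hat)))
    colnames(Delta_hat) <- paste0("ct", seq_len(ncol(Delta_hat)))
  dev <- abs(Delta_hat - 1)
  k <- apply(dev, 1, which.max)
  score <- dev[cbind(seq_len(nrow(dev)), k)]
  genes <- rownames(Delta_hat)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(Delta_hat)))
  ord <- order(-score, seq_along(score))
  data.frame(gene = genes[ord], score = score[ord],
             celltype = colnames(Delta_hat)[k][ord], row.names = NULL)
}

#' Overlap of top regulated genes across sample groups
#'
#' Computes the Venn-style intersection structure of the top `top_n` genes of
#' several rankings (e.g. one per disease subtype).
#'
#' @param rankings named list of rankings; each element either a character
#'   vector of genes (best first) or a data frame from
#'   [rank_regulated_genes()].
#' @param top_n genes taken from the head of each ranking (default 10).
#' @return Data frame with one row per non-empty group combination: `combo`
#'   (group names joined by `&`), `count`, and `genes` (comma separated).
#' @export
top_gene_overlap <- function(rankings, top_n = 10) {
  if (length(rankings) < 2) stop("need at least two rankings")
  tops <- lapply(rankings, function(r) {
    g <- if (is.data.frame(r)) r$gene else r
    utils::head(as.character(g), top_n)
  })
  groups <- names(tops)
  if (is.null(groups)) groups <- paste0("group", seq_along(tops))
  all_genes <- unique(unlist(tops))
  membership <- vapply(tops, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes),
                       dimnames = list(all_genes, groups))
  combo <- apply(membership, 1, function(m) paste(groups[m], collapse = "&"))
  parts <- split(all_genes, combo)
  out <- data.frame(combo = names(parts),
                    count = lengths(parts),
                    genes = vapply(parts, function(gs)
                      paste(sort(gs), collapse = ","), character(1)),
                    row.names = NULL)
  out[order(-out$count), ]
}

#' Evaluate a deconvolution fit against simulation ground truth
#'
#' Bundles all study metrics: per-cell-type and mean Pearson correlation of
#' the compositions, correlation of the hidden proportions and of the hidden
#' profile, and (when a regulation specification is given and the fit
#' adapted the reference) the regulation-detection AUC.
#'
#' @param fit an `adtd_fit`.
#' @param truth a truth list as produced by [sample_mixtures()] /
#'   [simulate_deconvolution_study()] (`C_true`, `hidden_true`, `x_true`,
#'   optionally `spec`).
#' @return List of class `adtd_evaluation` with `per_type_r`, `mean_r`,
#'   `hidden_r`, `profile_r`, `regulation_auc`.
#' @export
evaluate_fit <- function(fit, truth) {
  rc <- recovery_correlations(truth$C_true, fit$C)
  hr <- hidden_recovery(truth$hidden_true, fit$c)
  pr <- if (!is.null(truth$x_true)) profile_recovery(truth$x_true, fit$x)
        else NA_real_
  auc <- if (!is.null(truth$spec) && is.finite(fit$lambda2))
    as.numeric(regulation_auc(fit$Delta, truth$spec)) else NA_real_
  structure(list(per_type_r = rc$per_type, mean_r = rc$mean_r,
                 hidden_r = hr, profile_r = pr, regulation_auc = auc),
            class = "adtd_evaluation")
}

#' @export
print.adtd_evaluation <- function(x, ...) {
  cat("Deconvolution evaluation\n")
  cat("  per-type r: ",
      paste(sprintf("%s=%.3f", names(x$per_type_r), x$per_type_r),
            collapse = ", "), "\n")
  cat(sprintf("  mean r: %.3f | hidden r: %.3f | profile r: %.3f | AUC: %.3f\n",
              x$mean_r, x$hidden_r, x$profile_r, x$regulation_auc))
  invisible(x)
}
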