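#' Configuration for an end-to-end deconvolution study
#'
#' Collects the hyperparameters and simulation settings for
#' [run_pipeline()]. The defaults mirror the reference study design: ridge
#' strengths `lambda1 = 0.1` and `lambda2 = 1e-8`, mixtures of 100 cells, a
#' ~15% hidden population, and 30 + 30 regulated genes with factors drawn
#' from \{-1, -0.5, 1, 2\}.
#'
#' @param p,q,n,n_train simulation sizes (genes, cell types, evaluation and
#'   training mixtures).
#' @param lambda1,lambda2,max_iter,tol solver settings, see [fit_adtd()].
#' @param cells_per_mixture,hidden_fraction,separation,noise_dispersion
#'   generator settings, see [simulate_deconvolution_study()].
#' @param n_specific,n_unspecific,factors regulation design.
#' @param weight_iter iteration budget for [fit_gene_weights()].
#' @param seed integer seed driving every random draw of the run.
#' @return A list of class `adtd_config`.
#' @export
adtd_config <- function(p = 200, q = 4, n = 5000, n_train = 1000,
                        lambda1 = 0.1, lambda2 = 1e-8,
                        max_iter = 1000, tol = 1e-7,
                        cells_per_mixture = 100, hidden_fraction = 0.15,
                        hidden_sd = 0.06,
                        separation = 4, noise_dispersion = 0.35,
                        type_divergence = 0.5, hidden_divergence = 0.8,
                        n_specific = 30, n_unspecific = 30,
                        factors = c(-1, -0.5, 1, 2),
                        weight_iter = 500, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "adtd_config")
}

#' Run the full simulate / train / deconvolve / evaluate pipeline
#'
#' Generates a synthetic study ([simulate_deconvolution_study()]), learns
#' gene weights on the clean training mixtures ([fit_gene_weights()]), runs
#' the adaptive deconvolution on the regulated validation mixtures with a
#' hidden population ([fit_adtd()]), and evaluates against the ground truth
#' ([evaluate_fit()]). The result is a deterministic function of the
#' configuration (including its seed). When `out_dir` is given, all matrices
#' are written as TSV together with a manifest recording the configuration
#' and seed.
#'
#' @param config an [adtd_config()].
#' @param out_dir optional directory for artifacts.
#' @return List with `evaluation`, `fit`, `weights`, `data`, `config`.
#' @export
run_pipeline <- function(config = adtd_config(), out_dir = NULL) {
  stopifnot(inherits(config, "adtd_config"))
  data <- simulate_deconvolution_study(
    p = config$p, q = config$q, n = config$n, n_train = config$n_train,
    cells_per_mixture = config$cells_per_mixture,
    hidden_fraction = config$hidden_fraction, hidden_sd = config$hidden_sd,
    separation = config$separation,
    noise_dispersion = config$noise_dispersion,
    type_divergence = config$type_divergence,
    hidden_divergence = config$hidden_divergence,
    n_specific = config$n_specific, n_unspecific = config$n_unspecific,
    factors = config$factors, seed = config$seed)
  weights <- fit_gene_weights(data$X, data$train$Y, data$train$C_true,
                              max_iter = config$weight_iter,
                              seed = config$seed)
  fit <- fit_adtd(data$X, data$Y, weights$g,
                  lambda1 = config$lambda1, lambda2 = config$lambda2,
                  max_iter = config$max_iter, tol = config$tol)
  evaluation <- evaluate_fit(fit, data$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_expression_matrix(data$X, file.path(out_dir, "X.tsv"))
    write_expression_matrix(data$Y, file.path(out_dir, "Y.tsv"))
    write_expression_matrix(data$truth$C_true, file.path(out_dir, "C_true.tsv"))
    write_gene_weights(weights$g, file.path(out_dir, "g.tsv"))
    write_expression_matrix(fit$C, file.path(out_dir, "C.tsv"))
    write_expression_matrix(fit$Delta, file.path(out_dir, "Delta.tsv"))
    write_expression_matrix(t(as.matrix(fit$c)), file.path(out_dir, "hidden.tsv"))
    write_expression_matrix(as.matrix(fit$x), file.path(out_dir, "x.tsv"))
    manifest <- c(
      sprintf("seed: %d", config$seed),
      sprintf("package_version: %s",
              as.character(utils::packageVersion("adtd"))),
      "config:",
      paste0("  ", names(unclass(config)), ": ",
             vapply(unclass(config), function(v)
               paste(format(v, digits = 15), collapse = ","), character(1))))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  list(evaluation = evaluation, fit = fit, weights = weights,
       data = data, config = config)
}

#' Evaluate a hyperparameter grid on one simulated dataset
#'
#' Fits the adaptive deconvolution for every combination of the supplied
#' ridge strengths on the same generated data (gene weights are learned
#' once) and tabulates the evaluation metrics. `Inf` is accepted in either
#' list and denotes the corresponding hard limit (`C = C0`, respectively no
#' reference adaptation). A failing cell is recorded and the grid continues.
#'
#' @param config an [adtd_config()]; `config$lambda1` / `lambda2` are
#'   ignored in favor of the grids.
#' @param lambda1_list,lambda2_list numeric vectors of ridge strengths
#'   (`Inf` allowed).
#' @return Data frame with columns `lambda1`, `lambda2`, `mean_r`,
#'   `hidden_r`, `profile_r`, `regulation_auc`, `converged`, `error`.
#' @export
hyperparameter_grid <- function(config, lambda1_list, lambda2_list) {
  stopifnot(length(lambda1_list) > 0, length(lambda2_list) > 0)
  data <- simulate_deconvolution_study(
    p = config$p, q = config$q, n = config$n, n_train = config$n_train,
    cells_per_mixture = config$cells_per_mixture,
    hidden_fraction = config$hidden_fraction, hidden_sd = config$hidden_sd,
    separation = config$separation,
    noise_dispersion = config$noise_dispersion,
    type_divergence = config$type_divergence,
    hidden_divergence = config$hidden_divergence,
    n_specific = config$n_specific, n_unspecific = config$n_unspecific,
    factors = config$factors, seed = config$seed)
  weights <- fit_gene_weights(data$X, data$train$Y, data$train$C_true,
                              max_iter = config$weight_iter,
                              seed = config$seed)
  grid <- expand.grid(lambda1 = lambda1_list, lambda2 = lambda2_list)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    l1 <- grid$lambda1[i]; l2 <- grid$lambda2[i]
    res <- tryCatch({
      fit <- suppressWarnings(
        fit_adtd(data$X, data$Y, weights$g, lambda1 = l1, lambda2 = l2,
                 max_iter = config$max_iter, tol = config$tol))
      ev <- suppressWarnings(evaluate_fit(fit, data$truth))
      data.frame(lambda1 = l1, lambda2 = l2, mean_r = ev$mean_r,
                 hidden_r = ev$hidden_r, profile_r = ev$profile_r,
                 regulation_auc = ev$regulation_auc,
                 converged = fit$converged, error = NA_character_)
    }, error = function(e) {
      data.frame(lambda1 = l1, lambda2 = l2, mean_r = NA, hidden_r = NA,
                 profile_r = NA, regulation_auc = NA, converged = NA,
                 error = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}

#' Per-group ridge scaling for comparable reference adaptation
#'
#' When rescaling matrices are estimated separately per sample group (e.g.
#' disease subtypes of different size) and compared, the adaptation penalty
#' must grow with the group size to regularize each fit equally; this
#' returns `base * n_i / 1000` for each group.
#'
#' @param n_samples integer vector of per-group sample counts.
#' @param base base ridge strength (default 1e-5).
#' @return Numeric vector of per-group `lambda2` values.
#' @export
lambda2_for_groups <- function(n_samples, base = 1e-5) {
  base * n_samples / 1000
}
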