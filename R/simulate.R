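# Pseudo-bulk simulator: single-cell-like profiles for a set of declared cell
# types plus an optional hidden population, 100-cell mixtures with known
# compositions, and spiked cell-type-specific regulation. Serves as the fully
# controlled stand-in for mixture generation from real single-cell data.

# run `expr` under a fixed RNG state without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic single-cell population
#'
#' Builds per-cell-type mean expression profiles and draws single cells
#' around them as transcript counts. Each type's mean is a shared log-normal
#' baseline with (i) a dedicated marker block elevated by the factor
#' `1 + separation` and (ii) a transcriptome-wide log-normal divergence that
#' scales with `separation`, so that types differ globally -- as distinct
#' cell lineages do -- and not only in a handful of markers. The optional
#' hidden population models cells that will be present in mixtures but
#' absent from the reference matrix; its divergence is broader
#' (`hidden_divergence`), emulating a lineage such as malignant cells whose
#' whole expression program deviates from the reference types. Cells are
#' drawn with per-cell biological log-normal noise followed by Poisson
#' count sampling at a fixed expected library size, which reproduces the
#' depth-dependent technical noise of single-cell data (low-expression genes
#' are sampling-noise dominated).
#'
#' With `separation = 0` all divergences vanish and every type shares the
#' same mean profile.
#'
#' @param p number of genes (at least 10 per population).
#' @param celltypes character vector of reference cell-type names.
#' @param hidden logical; add a hidden population (default `TRUE`).
#' @param cells_per_type number of cells per population (default 300).
#' @param separation marker elevation factor; 0 makes all type means
#'   identical (default 4).
#' @param noise_dispersion standard deviation of the per-cell biological
#'   log-normal noise on the log scale (default 0.35).
#' @param type_divergence breadth of the per-type transcriptome-wide
#'   divergence: each type's mean is multiplied, gene-wise, by
#'   `exp(log1p(separation) * type_divergence * z)` with standard-normal
#'   `z` (default 0.5).
#' @param hidden_divergence divergence breadth of the hidden lineage
#'   (default 0.8; applied instead of `type_divergence`).
#' @param library_size expected transcript counts per cell over the `p`
#'   genes (default 5000, a deeply sequenced curated panel).
#' @param max_type_cor cap on the pairwise Pearson correlation between the
#'   mean profiles of any two populations (including the hidden one); the
#'   divergence draws are repeated until the cap holds, enforcing the
#'   premise that populations are mutually distinguishable lineages.
#'   Default 0.5; set to 1 to disable. Ignored when `separation = 0`
#'   (all means are identical then by construction).
#' @param max_hidden_mass cap on the total non-negative-least-squares
#'   coefficient mass of the (normalized) hidden mean profile regressed on
#'   the normalized reference means. When this mass is near 1 the hidden
#'   lineage is a convex-combination lookalike of the references: mixtures
#'   absorb it completely into the composition and no background signal
#'   remains, contradicting the premise of a distinct hidden population.
#'   Draws violating the cap are rejected like `max_type_cor` violations.
#'   Default 0.85; set to `Inf` to disable.
#' @param seed integer RNG seed; the population is a deterministic function
#'   of the arguments and the seed.
#' @return Object of class `cell_population`: list with `profiles` (p x
#'   total-cells count matrix), `labels` (cell-type per cell, hidden cells
#'   labeled `"hidden"`), `celltypes`, `means` (p x types mean profiles),
#'   `hidden` flag and `seed`.
#' @export
generate_population <- function(p, celltypes = paste0("ct", 1:4), hidden = TRUE,
                                cells_per_type = 300, separation = 4,
                                noise_dispersion = 0.35,
                                type_divergence = 0.5, hidden_divergence = 0.8,
                                library_size = 5000, max_type_cor = 0.5,
                                max_hidden_mass = 0.85, seed = 1L) {
  q_all <- length(celltypes) + hidden
  if (p < 10 * q_all) stop("need at least 10 genes per population (p >= 10 * q)")
  if (separation < 0) stop("separation must be non-negative")
  if ("hidden" %in% celltypes) stop("'hidden' is a reserved cell-type label")
  all_types <- c(celltypes, if (hidden) "hidden")
  .with_seed(seed, {
    base <- stats::rlnorm(p, meanlog = 0, sdlog = 1)
    block <- max(3L, floor(p / (3 * q_all)))
    means <- matrix(base, p, q_all, dimnames = list(paste0("gene", seq_len(p)),
                                                    all_types))
    for (k in seq_len(q_all)) {
      idx <- ((k - 1) * block + 1):(k * block)
      means[idx, k] <- means[idx, k] * (1 + separation)
    }
    base_means <- means
    for (attempt in 1:100) {
      for (k in seq_len(q_all)) {
        div <- if (hidden && k == q_all) hidden_divergence else type_divergence
        means[, k] <- base_means[, k] *
          exp(log1p(separation) * div * stats::rnorm(p))
      }
      if (separation == 0 || q_all == 1) break
      cm <- stats::cor(means)
      ok_cor <- max(cm[upper.tri(cm)]) < max_type_cor
      ok_mass <- TRUE
      if (hidden && is.finite(max_hidden_mass)) {
        Xm <- normalize_columns(means[, -q_all, drop = FALSE])
        xm <- means[, q_all] / sum(means[, q_all])
        ok_mass <- sum(pracma::lsqnonneg(Xm, xm)$x) <= max_hidden_mass
      }
      if (ok_cor && ok_mass) break
      if (attempt == 100)
        warning("could not reach max_type_cor in 100 redraws; ",
                "keeping last draw")
    }
    m <- q_all * cells_per_type
    labels <- rep(all_types, each = cells_per_type)
    noise <- matrix(stats::rnorm(p * m, mean = -noise_dispersion^2 / 2,
                                 sd = noise_dispersion), p, m)
    lam <- means[, rep(seq_len(q_all), each = cells_per_type)] * exp(noise)
    lam <- sweep(lam, 2, colSums(lam), "/") * library_size
    profiles <- matrix(stats::rpois(p * m, lam), p, m)
    dimnames(profiles) <- list(rownames(means), paste0("cell", seq_len(m)))
    structure(list(profiles = profiles, labels = labels,
                   celltypes = celltypes, means = means,
                   hidden = hidden, seed = seed),
              class = "cell_population")
  })
}

#' Build a reference matrix from a cell population
#'
#' Averages the single-cell profiles of each declared (non-hidden) cell type
#' and column-normalizes the result; hidden-labeled cells never contribute.
#'
#' @param pop a `cell_population` from [generate_population()].
#' @return Column-normalized reference matrix, p genes x q cell types.
#' @export
build_reference <- function(pop) {
  stopifnot(inherits(pop, "cell_population"))
  X <- vapply(pop$celltypes, function(ct) {
    sel <- pop$labels == ct
    if (!any(sel)) stop("cell type '", ct, "' has no cells")
    rowMeans(pop$profiles[, sel, drop = FALSE])
  }, numeric(nrow(pop$profiles)))
  normalize_columns(X)
}

#' Sample pseudo-bulk mixtures from a cell population
#'
#' Each mixture averages `cells_per_mixture` single-cell profiles drawn with
#' replacement. The hidden population's sampling probability is
#' `hidden_fraction` on average; with `hidden_sd > 0` the per-mixture
#' probability is drawn from a Beta distribution with that mean and standard
#' deviation (beta-binomial cell sampling), emulating cohorts whose hidden
#' content -- e.g. tumor purity -- varies across specimens. With
#' `hidden_sd = 0` the hidden share follows the plain binomial draw implied
#' by cell sampling. Declared types share the remaining probability
#' uniformly per cell. Bulk columns are normalized to sum one.
#'
#' @param pop a `cell_population`.
#' @param n number of mixtures.
#' @param cells_per_mixture cells per mixture (default 100).
#' @param hidden_fraction mean hidden-cell share (default 0.15; must be 0
#'   when the population has no hidden cells).
#' @param hidden_sd across-mixture standard deviation of the hidden share
#'   (default 0.06; ignored when `hidden_fraction` is 0).
#' @param seed integer RNG seed.
#' @return List with `Y` (normalized p x n bulk matrix) and `truth`, a list
#'   holding `C_true` (q x n drawn-cell fractions of the declared types),
#'   `hidden_true` (length-n hidden-cell fractions), and `x_true` (the
#'   normalized mean profile of all hidden cells, or `NULL`).
#' @export
sample_mixtures <- function(pop, n, cells_per_mixture = 100,
                            hidden_fraction = 0.15, hidden_sd = 0.06,
                            seed = 1L) {
  stopifnot(inherits(pop, "cell_population"))
  if (hidden_fraction < 0 || hidden_fraction > 1)
    stop("hidden_fraction must be in [0, 1]")
  is_hidden <- pop$labels == "hidden"
  if (!any(is_hidden) && hidden_fraction > 0)
    stop("population has no hidden cells; use hidden_fraction = 0")
  if (hidden_fraction > 0 && hidden_sd > 0) {
    if (hidden_sd^2 >= hidden_fraction * (1 - hidden_fraction))
      stop("hidden_sd too large for a Beta distribution with this mean")
    ab <- hidden_fraction * (1 - hidden_fraction) / hidden_sd^2 - 1
    beta_a <- hidden_fraction * ab
    beta_b <- (1 - hidden_fraction) * ab
  }
  q <- length(pop$celltypes)
  .with_seed(seed, {
    Y <- matrix(0, nrow(pop$profiles), n,
                dimnames = list(rownames(pop$profiles), paste0("mix", seq_len(n))))
    C_true <- matrix(0, q, n, dimnames = list(pop$celltypes, colnames(Y)))
    hidden_true <- numeric(n)
    w <- numeric(length(pop$labels))
    for (i in seq_len(n)) {
      hf <- if (hidden_fraction > 0 && hidden_sd > 0)
        stats::rbeta(1, beta_a, beta_b) else hidden_fraction
      if (any(is_hidden)) w[is_hidden] <- hf / sum(is_hidden)
      w[!is_hidden] <- (1 - hf) / sum(!is_hidden)
      cells <- sample.int(length(pop$labels), cells_per_mixture,
                          replace = TRUE, prob = w)
      Y[, i] <- rowMeans(pop$profiles[, cells, drop = FALSE])
      tab <- table(factor(pop$labels[cells], levels = c(pop$celltypes, "hidden")))
      C_true[, i] <- tab[pop$celltypes] / cells_per_mixture
      hidden_true[i] <- tab[["hidden"]] / cells_per_mixture
    }
    x_true <- if (any(is_hidden)) {
      xt <- rowMeans(pop$profiles[, is_hidden, drop = FALSE])
      xt / sum(xt)
    } else NULL
    names(hidden_true) <- colnames(Y)
    list(Y = normalize_columns(Y),
         truth = list(C_true = C_true, hidden_true = hidden_true,
                      x_true = x_true))
  })
}

#' Select the most cell-type-specific genes
#'
#' Scores every gene by \eqn{\max_k X_{jk} / \mathrm{mean}(X_{j,\cdot})} and
#' returns, for each cell type, the `top_per_type` genes for which that type
#' attains the maximum, ranked by the ratio (ties broken by ascending gene
#' index).
#'
#' @param X column-normalized reference matrix.
#' @param top_per_type genes kept per cell type (default 20).
#' @return Data frame with columns `gene` (row index), `celltype`, `score`.
#' @export
select_specific_genes <- function(X, top_per_type = 20) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("ct", seq_len(ncol(X)))
  rmean <- rowMeans(X)
  ratio <- X / rmean
  argmax <- apply(ratio, 1, which.max)
  score <- ratio[cbind(seq_len(nrow(X)), argmax)]
  out <- lapply(seq_len(ncol(X)), function(k) {
    cand <- which(argmax == k)
    cand <- cand[order(-score[cand], cand)]
    cand <- utils::head(cand, top_per_type)
    if (!length(cand)) return(NULL)
    data.frame(gene = cand, celltype = colnames(X)[k], score = score[cand])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select the least cell-type-specific genes
#'
#' Returns the `pool_size` genes with the smallest variance-to-mean ratio of
#' their reference row (ties broken by ascending gene index); genes with zero
#' mean are excluded.
#'
#' @param X column-normalized reference matrix.
#' @param pool_size number of genes to return (default 120).
#' @return Integer vector of gene (row) indices.
#' @export
select_unspecific_genes <- function(X, pool_size = 120) {
  X <- as.matrix(X)
  rmean <- rowMeans(X)
  eligible <- which(rmean > 0)
  vmr <- apply(X[eligible, , drop = FALSE], 1, stats::var) / rmean[eligible]
  eligible[order(vmr, eligible)][seq_len(min(pool_size, length(eligible)))]
}

#' Draw a cell-type-specific regulation specification
#'
#' Picks genes to regulate and the cell type and modification factor for
#' each: `n_specific` genes from the pool of the most cell-type-specific
#' genes (target = the type they are specific for) and `n_unspecific` genes
#' from the pool of the least specific genes (target drawn uniformly), with
#' factors drawn from `factors`. A factor `a` multiplies the targeted type's
#' contribution by `1 + a`, so the implied ground-truth rescaling is
#' \eqn{\Delta_{jk} = 1 + a} (e.g. `a = -1` is a full knockout, `a = 1` a
#' doubling).
#'
#' @param X column-normalized reference matrix.
#' @param n_specific,n_unspecific genes drawn from each pool (default 30
#'   each).
#' @param factors candidate modification factors (default
#'   `c(-1, -0.5, 1, 2)`).
#' @param top_per_type,unspecific_pool pool sizes passed to
#'   [select_specific_genes()] and [select_unspecific_genes()].
#' @param seed integer RNG seed.
#' @return Object of class `regulation_spec`: data frame with columns
#'   `gene`, `celltype`, `factor`.
#' @export
make_regulation_spec <- function(X, n_specific = 30, n_unspecific = 30,
                                 factors = c(-1, -0.5, 1, 2),
                                 top_per_type = 20, unspecific_pool = 120,
                                 seed = 1L) {
  X <- as.matrix(X)
  spec_pool <- select_specific_genes(X, top_per_type)
  unspec_pool <- select_unspecific_genes(X, unspecific_pool)
  unspec_pool <- setdiff(unspec_pool, spec_pool$gene)
  if (nrow(spec_pool) < n_specific)
    stop("specific gene pool smaller than n_specific")
  if (length(unspec_pool) < n_unspecific)
    stop("unspecific gene pool smaller than n_unspecific")
  .with_seed(seed, {
    si <- sample(seq_len(nrow(spec_pool)), n_specific)
    spec <- data.frame(gene = spec_pool$gene[si],
                       celltype = spec_pool$celltype[si])
    ui <- sample(unspec_pool, n_unspecific)
    unspec <- data.frame(gene = ui,
                         celltype = sample(colnames(X), n_unspecific,
                                           replace = TRUE))
    out <- rbind(spec, unspec)
    out$factor <- sample(factors, nrow(out), replace = TRUE)
    structure(out, class = c("regulation_spec", "data.frame"))
  })
}

#' Spike cell-type-specific regulation into pseudo-bulk mixtures
#'
#' For each entry (gene j, target type k, factor a) of the specification the
#' expression becomes \eqn{Y'_{ji} = \max(0, Y_{ji} + a X_{jk} C_{ki})} in
#' every mixture i: the targeted type's contribution to that gene is scaled
#' by `1 + a`. The matrix is not re-normalized afterwards, so the implied
#' ground truth \eqn{\Delta_{jk} = 1 + a} is preserved exactly.
#'
#' @param Y normalized bulk matrix, p x n.
#' @param X normalized reference matrix, p x q.
#' @param C_true true composition fractions, q x n.
#' @param spec a `regulation_spec` (or data frame with columns `gene`,
#'   `celltype`, `factor`).
#' @return The modified bulk matrix.
#' @export
spike_regulation <- function(Y, X, C_true, spec) {
  Y <- as.matrix(Y); X <- as.matrix(X); C_true <- as.matrix(C_true)
  if (nrow(spec) == 0) return(Y)
  for (r in seq_len(nrow(spec))) {
    j <- spec$gene[r]
    k <- spec$celltype[r]
    Y[j, ] <- Y[j, ] + spec$factor[r] * X[j, k] * C_true[k, ]
  }
  pmax(Y, 0)
}

#' Ground-truth rescaling matrix implied by a regulation specification
#'
#' @param spec a `regulation_spec`.
#' @param X the reference matrix the spec refers to (provides dimensions and
#'   names).
#' @return A p x q matrix equal to one everywhere except `1 + factor` at the
#'   spiked (gene, cell type) entries.
#' @export
delta_truth <- function(spec, X) {
  D <- matrix(1, nrow(X), ncol(X), dimnames = dimnames(X))
  for (r in seq_len(nrow(spec))) {
    D[spec$gene[r], spec$celltype[r]] <- 1 + spec$factor[r]
  }
  D
}

#' Simulate a complete deconvolution study
#'
#' Convenience wrapper reproducing the full validation design: a synthetic
#' cell population with a hidden cell type, a reference matrix built from the
#' declared types only, training mixtures without hidden contributions or
#' regulation (for gene-weight learning), and validation mixtures with ~15%
#' hidden cells and spiked cell-type-specific regulation.
#'
#' @param p genes (default 200).
#' @param q declared cell types (default 4).
#' @param n validation mixtures (default 200).
#' @param n_train training mixtures (default 1000).
#' @param cells_per_mixture cells per mixture (default 100).
#' @param hidden_fraction mean hidden-cell share in validation mixtures
#'   (default 0.15).
#' @param hidden_sd across-mixture standard deviation of the hidden share
#'   (default 0.06), see [sample_mixtures()].
#' @param separation marker elevation (default 4).
#' @param noise_dispersion per-cell biological log-normal noise (default
#'   0.35).
#' @param type_divergence,hidden_divergence transcriptome-wide divergence
#'   breadths, see [generate_population()].
#' @param n_specific,n_unspecific,factors regulation design, see
#'   [make_regulation_spec()].
#' @param top_per_type,unspecific_pool regulation gene pools.
#' @param seed integer RNG seed.
#' @return List with `pop`, `X`, `train` (list `Y`, `C_true`), `Y`
#'   (regulated validation bulks), `truth` (with `C_true`, `hidden_true`,
#'   `x_true`, `spec`, `Delta_true`).
#' @export
simulate_deconvolution_study <- function(p = 200, q = 4, n = 200, n_train = 1000,
                                         cells_per_mixture = 100,
                                         hidden_fraction = 0.15, hidden_sd = 0.06,
                                         separation = 4, noise_dispersion = 0.35,
                                         type_divergence = 0.5,
                                         hidden_divergence = 0.8,
                                         n_specific = 30, n_unspecific = 30,
                                         factors = c(-1, -0.5, 1, 2),
                                         top_per_type = 20, unspecific_pool = 120,
                                         seed = 1L) {
  pop <- generate_population(p, paste0("ct", seq_len(q)), hidden = TRUE,
                             separation = separation,
                             noise_dispersion = noise_dispersion,
                             type_divergence = type_divergence,
                             hidden_divergence = hidden_divergence, seed = seed)
  X <- build_reference(pop)
  train <- sample_mixtures(pop, n_train, cells_per_mixture,
                           hidden_fraction = 0, seed = seed + 1000L)
  val <- sample_mixtures(pop, n, cells_per_mixture,
                         hidden_fraction = hidden_fraction,
                         hidden_sd = hidden_sd, seed = seed + 2000L)
  spec <- make_regulation_spec(X, n_specific, n_unspecific, factors,
                               top_per_type, unspecific_pool,
                               seed = seed + 3000L)
  Yv <- spike_regulation(val$Y, X, val$truth$C_true, spec)
  list(pop = pop, X = X,
       train = list(Y = train$Y, C_true = train$truth$C_true),
       Y = Yv,
       truth = c(val$truth, list(spec = spec, Delta_true = delta_truth(spec, X))))
}
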