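test_that("populations are deterministic under a seed and sensitive to it", {
  p1 <- generate_population(60, paste0("ct", 1:2), cells_per_type = 20, seed = 3)
  p2 <- generate_population(60, paste0("ct", 1:2), cells_per_type = 20, seed = 3)
  p3 <- generate_population(60, paste0("ct", 1:2), cells_per_type = 20, seed = 4)
  expect_identical(p1$profiles, p2$profiles)
  expect_false(identical(p1$profiles, p3$profiles))
})

test_that("zero separation collapses all mean profiles onto the baseline", {
  pop <- generate_population(80, paste0("ct", 1:3), cells_per_type = 5,
                             separation = 0, seed = 1)
  expect_equal(pop$means[, 1], pop$means[, 2])
  expect_equal(pop$means[, 1], pop$means[, "hidden"])
})

test_that("reference columns are distinct, normalized, and ignore hidden cells", {
  pop <- generate_population(90, paste0("ct", 1:3), cells_per_type = 50,
                             separation = 5, seed = 2)
  X <- build_reference(pop)
  expect_equal(colSums(X), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-12)
  cm <- cor(X)
  expect_lt(max(cm[upper.tri(cm)]), 0.5)
  # hidden cells never contribute: zeroing them leaves X unchanged
  pop2 <- pop
  pop2$profiles[, pop2$labels == "hidden"] <- 0
  expect_identical(build_reference(pop2), X)
  # a population without hidden cells gives the same kind of reference
  popnh <- generate_population(90, paste0("ct", 1:3), hidden = FALSE,
                               cells_per_type = 5, seed = 2)
  expect_equal(colSums(build_reference(popnh)), rep(1, 3), ignore_attr = TRUE)
})

test_that("a single cell per type yields reference columns proportional to those cells", {
  pop <- generate_population(60, paste0("ct", 1:2), cells_per_type = 1, seed = 5)
  X <- build_reference(pop)
  for (k in 1:2) {
    cell <- pop$profiles[, pop$labels == pop$celltypes[k]]
    expect_equal(X[, k], cell / sum(cell), ignore_attr = TRUE)
  }
})

test_that("mixtures without hidden cells have complete known compositions", {
  pop <- generate_population(60, paste0("ct", 1:2), cells_per_type = 30, seed = 6)
  mx <- sample_mixtures(pop, 25, cells_per_mixture = 50, hidden_fraction = 0,
                        seed = 7)
  expect_true(all(mx$truth$hidden_true == 0))
  expect_equal(colSums(mx$truth$C_true), rep(1, 25), ignore_attr = TRUE)
  expect_equal(colSums(mx$Y), rep(1, 25), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("hidden shares are centered on the requested fraction", {
  pop <- generate_population(60, paste0("ct", 1:2), cells_per_type = 30, seed = 8)
  mx <- sample_mixtures(pop, 5000, cells_per_mixture = 100, seed = 9)
  expect_lt(abs(mean(mx$truth$hidden_true) - 0.15), 0.02)
  # known + hidden fractions always sum to one
  expect_equal(colSums(mx$truth$C_true) + mx$truth$hidden_true,
               rep(1, 5000), ignore_attr = TRUE)
  # beta-binomial draws spread more than plain binomial ones
  mx0 <- sample_mixtures(pop, 2000, cells_per_mixture = 100, hidden_sd = 0,
                         seed = 10)
  expect_gt(sd(mx$truth$hidden_true), sd(mx0$truth$hidden_true))
  expect_lt(abs(mean(mx0$truth$hidden_true) - 0.15), 0.02)
})

test_that("mixture generation is deterministic and rejects invalid hidden settings", {
  pop <- generate_population(60, paste0("ct", 1:2), cells_per_type = 10, seed = 11)
  m1 <- sample_mixtures(pop, 5, seed = 12)
  m2 <- sample_mixtures(pop, 5, seed = 12)
  expect_identical(m1, m2)
  popnh <- generate_population(60, paste0("ct", 1:2), hidden = FALSE,
                               cells_per_type = 10, seed = 11)
  expect_error(sample_mixtures(popnh, 5, hidden_fraction = 0.15), "no hidden")
  expect_error(sample_mixtures(pop, 5, hidden_fraction = 0.5, hidden_sd = 0.6),
               "too large")
})

test_that("re-simulating from the recorded ground truth approximates the bulks", {
  # reconstruction from (type means, C_true, hidden_true) matches the
  # generated bulks, with error shrinking as mixtures average more cells
  pop <- generate_population(80, paste0("ct", 1:2), cells_per_type = 200, seed = 13)
  type_means <- vapply(c(pop$celltypes, "hidden"), function(ct)
    rowMeans(pop$profiles[, pop$labels == ct, drop = FALSE]),
    numeric(nrow(pop$profiles)))
  recon_err <- function(cells) {
    mx <- sample_mixtures(pop, 20, cells_per_mixture = cells, seed = 14)
    Yhat <- type_means %*% rbind(mx$truth$C_true, mx$truth$hidden_true)
    Yhat <- normalize_columns(Yhat)
    mean(abs(Yhat - mx$Y))
  }
  e100 <- recon_err(100)
  e10000 <- recon_err(10000)
  expect_lt(e10000, e100 / 3)
})

test_that("specific-gene selection matches hand-computed rankings", {
  # 6-gene toy with known ratios X_jk / mean(X_j, .)
  X <- rbind(c(0.9, 0.1),   # ratio 1.8 for type 1
             c(0.6, 0.4),   # ratio 1.2 for type 1
             c(0.5, 0.5),   # uniform, ratio 1
             c(0.2, 0.8),   # ratio 1.6 for type 2
             c(0.05, 0.95), # ratio 1.9 for type 2
             c(0.45, 0.55))
  colnames(X) <- c("a", "b")
  sel <- select_specific_genes(X, top_per_type = 2)
  expect_equal(sel$gene[sel$celltype == "a"], c(1, 2))
  expect_equal(sel$gene[sel$celltype == "b"], c(5, 4))
  # a gene expressed by exactly one of q types attains the maximal ratio q
  X2 <- rbind(c(1, 0, 0), c(0.4, 0.3, 0.3))
  s2 <- select_specific_genes(X2, top_per_type = 1)
  expect_equal(s2$score[s2$gene == 1], 3)
  # the uniform gene is never selected while any marker exists
  expect_false(3 %in% select_specific_genes(X, top_per_type = 2)$gene)
})

test_that("unspecific-gene selection ranks by variance-to-mean ratio", {
  X <- rbind(c(0.5, 0.5),    # var 0
             c(0.9, 0.1),    # high var
             c(0.45, 0.55),  # low var
             c(0, 0))        # zero mean: excluded
  expect_equal(select_unspecific_genes(X, pool_size = 2), c(1, 3))
  expect_false(4 %in% select_unspecific_genes(X, pool_size = 10))
  expect_false(2 %in% select_unspecific_genes(X, pool_size = 2))
})

test_that("regulation spiking applies the stated arithmetic and nothing else", {
  set.seed(15)
  X <- normalize_columns(matrix(runif(12, 0.1, 1), 6, 2,
                                dimnames = list(paste0("g", 1:6), c("a", "b"))))
  C <- matrix(runif(6, 0.2, 0.5), 2, 3, dimnames = list(c("a", "b"), NULL))
  Y <- normalize_columns(matrix(runif(18, 0.1, 1), 6, 3,
                                dimnames = list(rownames(X), NULL)))
  # empty spec is the identity
  empty <- data.frame(gene = integer(), celltype = character(),
                      factor = numeric())
  expect_identical(spike_regulation(Y, X, C, empty), Y)
  spec <- data.frame(gene = c(2, 5), celltype = c("a", "b"),
                     factor = c(-1, 1))
  Ys <- spike_regulation(Y, X, C, spec)
  expect_equal(Ys[2, ], pmax(0, Y[2, ] - X[2, "a"] * C["a", ]))
  expect_equal(Ys[5, ], Y[5, ] + X[5, "b"] * C["b", ])
  untouched <- setdiff(1:6, spec$gene)
  expect_identical(Ys[untouched, ], Y[untouched, ])
  # implied ground-truth rescaling
  D <- delta_truth(spec, X)
  expect_equal(D[2, "a"], 0)   # a = -1: full knockout
  expect_equal(D[5, "b"], 2)   # a = +1: doubling
  expect_equal(sum(D != 1), 2)
})

test_that("a knockout zeroes a gene exclusive to the target type in a pure mixture", {
  X <- normalize_columns(rbind(c(0.5, 0), c(0.25, 0.6), c(0.25, 0.4)))
  colnames(X) <- c("a", "b")
  rownames(X) <- paste0("g", 1:3)
  C <- matrix(c(1, 0), 2, 1, dimnames = list(c("a", "b"), NULL))
  Y <- X %*% C
  spec <- data.frame(gene = 1, celltype = "a", factor = -1)
  Ys <- spike_regulation(Y, X, C, spec)
  expect_equal(Ys[1, 1], 0, ignore_attr = TRUE)
})

test_that("drawn regulation specs respect the pool structure and factor set", {
  pop <- generate_population(200, paste0("ct", 1:4), cells_per_type = 20, seed = 16)
  X <- build_reference(pop)
  spec <- make_regulation_spec(X, seed = 17)
  expect_equal(nrow(spec), 60)
  expect_true(all(spec$factor %in% c(-1, -0.5, 1, 2)))
  expect_true(all(spec$celltype %in% colnames(X)))
  expect_false(anyDuplicated(spec[c("gene", "celltype")]) > 0)
  # the first 30 entries come from the specific pools with matching target
  spool <- select_specific_genes(X, 20)
  m <- merge(spec[1:30, ], spool, by = c("gene", "celltype"))
  expect_equal(nrow(m), 30)
  expect_identical(make_regulation_spec(X, seed = 17), spec)
})

test_that("the full study bundle is coherent", {
  sim <- simulate_deconvolution_study(p = 100, q = 3, n = 30, n_train = 40,
                                      seed = 21)
  expect_equal(dim(sim$X), c(100, 3))
  expect_equal(dim(sim$Y), c(100, 30))
  expect_equal(dim(sim$train$Y), c(100, 40))
  expect_true(all(sim$train$C_true >= 0))
  expect_equal(colSums(sim$truth$C_true) + sim$truth$hidden_true,
               rep(1, 30), ignore_attr = TRUE)
  expect_equal(sum(sim$truth$x_true), 1)
  expect_equal(dim(sim$truth$Delta_true), dim(sim$X))
})
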