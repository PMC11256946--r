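# adtd — adaptive digital tissue deconvolution

Bulk transcriptomes are linear mixtures of the expression programs of the
cells they contain: `Y = XC + ε`, with a reference matrix `X` (p genes × q
cell types, one archetypal profile per column) and non-negative cellular
weights `C`. Plain reference-based deconvolution breaks in two common ways:
specimens contain cells that no column of `X` represents (in tumors, the
malignant cells themselves), and the reference profiles, measured in a
different context, are per-gene miscalibrated for the tissue at hand.

This package estimates, jointly for a cohort of bulks:

* the cell-type weights `C`,
* one consensus **hidden background profile** `x` (a probability vector
  over genes) with per-sample weights `c_i`,
* a **rescaling matrix** `Δ` (p × q) adapting `X` multiplicatively, whose
  deviations from 1 are read as cell-type-specific gene regulation,

by minimizing

```
‖G(Y − (Δ∘X)C − x(1 − 1ᵀ(Δ∘X)C))‖²_F + λ₁‖C − C₀‖²_F + λ₂‖J − Δ‖²_F
```

subject to `C ≥ 0`, `x ≥ 0`, `Σ_j x_j = 1`, `Δ ≥ 0`, and the per-sample
budget `1ᵀ(Δ∘X)C ≤ 1` (equivalently `c_i ≥ 0`). `G = diag(g)` holds
per-gene weights learned from training mixtures of known composition
(`fit_gene_weights()`, maximizing per-cell-type Pearson recovery), and
`C₀` is the naive weighted-NNLS composition. The solver
(`fit_adtd()`) is an exact block-coordinate scheme — constrained quadratic
programs for `C`, `x`, and each row of `Δ` — with a provably non-increasing
loss. The limits recover simpler estimators: `λ₁ = Inf` gives plain
weighted NNLS with clipped-complement hidden weights; `λ₂ = Inf` disables
reference adaptation.

A pseudo-bulk simulator (`simulate_deconvolution_study()`) provides fully
controlled ground truth — single-cell-like count profiles, a hidden lineage
absent from the reference, and spiked regulation with known `Δ` — and
`evaluate_fit()` computes the recovery metrics (per-type Pearson, hidden
proportion/profile correlations, regulation-detection AUC).

## Worked example

```r
library(adtd)

sim <- simulate_deconvolution_study(p = 200, q = 4, n = 200, seed = 1)
w   <- fit_gene_weights(sim$X, sim$train$Y, sim$train$C_true)
#> Learned deconvolution gene weights
#>   genes: 200; outer loss -3.9250 (uniform start: -3.9129)
#>   per-type training correlations:  0.988, 0.980, 0.984, 0.973

fit <- fit_adtd(sim$X, sim$Y, w$g, lambda1 = 0.1, lambda2 = 1e-8)
#> Adaptive digital tissue deconvolution fit
#>   genes: 200, cell types: 4, samples: 200
#>   lambda1 = 0.1, lambda2 = 1e-08
#>   converged after 23 iterations, final loss 4.83668e-05
#>   hidden weights: mean 0.072 (range 0.020-0.172)

evaluate_fit(fit, sim$truth)
#> Deconvolution evaluation
#>   per-type r:  ct1=0.857, ct2=0.985, ct3=0.920, ct4=0.850
#>   mean r: 0.903 | hidden r: 0.958 | profile r: 0.960 | AUC: 0.845

head(rank_regulated_genes(fit$Delta), 3)
#>      gene    score celltype
#> 1 gene164 5.513193      ct4
#> 2  gene51 5.243160      ct4
#> 3 gene115 4.180978      ct4
```

The outer loss of `-3.93` means the learned weights recover all four
training cell types with correlations near 1 (`-q = -4` would be perfect).
On the validation mixtures — which contain a hidden population (~15% of
cells, absent from `X`) and 60 genes with spiked cell-type-specific
regulation — the fit recovers the compositions (mean per-type r 0.90), the
per-sample hidden proportions (r 0.96), the hidden profile itself (r 0.96),
and separates regulated from unregulated (gene, cell type) pairs with AUC
0.85. The top-ranked genes by `max_k |Δ_jk − 1|` are the spiked ones.

For real data, `align_genes()` intersects reference and bulk gene spaces,
`rescale_bulk_to_reference()` compensates cross-platform gene-wise scale
differences against matched controls, and `lambda2_for_groups()` scales the
adaptation penalty when several cohorts of different size are compared.

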