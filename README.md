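# scHoML

Joint clustering of **parallel multi-omics single-cell data** by multi-modal
high-order neighborhood Laplacian matrix optimization.

Assays such as CITE-seq (RNA + surface-protein ADT counts) and scM&T-seq
(methylome + transcriptome) measure several omics layers in the *same*
cells. Each layer is noisy and sparse in its own way, and no single one
fully reveals the cell states. scHoML integrates the layers at the level of
cell-cell similarity graphs: it fuses first- and second-order graph
Laplacians across modalities into one low-rank operator, learns a common
low-dimensional embedding of the cells, and clusters them hierarchically
with automatic selection of the cluster number. The package is aimed at
analysts of paired single-cell multi-omics experiments and at
methods developers who need a reproducible graph-fusion baseline with
built-in benchmark simulators.

## Model

For each modality `p = 1..V` (a cells × features matrix, z-scored and
PCA-reduced), a KNN graph with Gaussian edge weights
`w_jk = exp(-||x_j - x_k||² / 2σ²)` gives the first-order adjacency
`W_p⁽¹⁾`; a second-order adjacency `W_p⁽²⁾` connects cells with similar
adjacency rows (shared neighborhoods). Each adjacency yields the symmetric
normalized Laplacian `L = I - D^{-1/2} W D^{-1/2}`.

The fused Laplacian is approximated by a low-rank factorization
`I - WΛWᵀ` (with `WᵀW = I_c`, `0 ≤ Λ_kk ≤ 1`), fitted jointly with the
embedding `H` (`HᵀH = I_c`) by

```
min  tr(Hᵀ(I - WΛWᵀ)H) + || I - WΛWᵀ - (λ L_μ⁽¹⁾ + (1-λ) L_μ⁽²⁾) ||_F²
```

where `L_μ⁽ⁱ⁾ = Σ_p μ_p L_p⁽ⁱ⁾` mixes modalities with simplex weights `μ`
and `λ ∈ [0,1]` mixes the two orders. The five blocks (λ, W, Λ, H, μ) are
updated cyclically, each by its exact minimizer (closed forms for λ and Λ,
eigenvector problems for W and H, a simplex quadratic program for μ), so
the objective decreases monotonically to a local optimum.

Cells are then clustered by average-linkage agglomerative clustering on a
distance between embedding rows (1 − Pearson correlation by default, L1
optional). The cluster number is chosen from a candidate set by the mean
silhouette width for small data sets (n ≤ 500) and by the variance-ratio
(Calinski–Harabasz) criterion for large ones.

## Worked example

Simulate the built-in 500-cell two-modality benchmark (four cell types;
modality 2 binarized, both modalities with dropout and additive noise) and
run the full pipeline:

```r
library(scHoML)

ds  <- simulate_dataset2(seed = 11)        # X1: 500x5000, X2: 500x2000 (binary)
fit <- schoml(list(ds$X1, ds$X2), c = 4)   # embed into 4 dimensions, cluster
fit
#> scHoML fit: 500 cells, 2 modalities, embedding dimension 4
#>   optimizer: 11 iteration(s), converged; objective 12.8505 -> 0.438564
#>   modality weights mu: 0.8943, 0.1057 ; order weight lambda: 0.002212
#>   clusters: 4 (selected by silhouette criterion)
#> cluster
#>   1   2   3   4
#> 125 125 125 125

ari(ds$labels, fit$labels)
#> [1] 1
nmi(ds$labels, fit$labels)
#> [1] 1
```

The fit reports that the optimizer converged in 11 cycles, leaned mostly on
modality 1 (`mu ≈ 0.89/0.11`), relied almost entirely on the second-order
graphs (`lambda ≈ 0`), and recovered the four planted types exactly
(ARI = NMI = 1) with the cluster number selected automatically from 2–10.
`coef(fit)` returns the learned `(λ, μ, Λ)`, `plot(fit)` shows the
embedding colored by cluster, and `fit$embedding` is the n × c matrix `H`.

Lower-level steps (`knn_affinity()`, `normalized_laplacian()`,
`laplacian_stack()`, `fuse_laplacians()`, `cluster_embedding()`, file
readers/writers) are exported individually; `inst/cli/schoml.R` is a thin
command-line wrapper (`simulate` / `fit` / `evaluate`).

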