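# scirt

Dropout imputation and dimensionality reduction for single-cell RNA-seq
expression matrices.

Single-cell RNA-seq measurements are riddled with *dropouts*: zeros caused by
failed mRNA capture rather than true absence of expression. At high dropout
rates, distances between cells degrade and clustering into cell types falls
apart. `scirt` recovers the structure with a multi-layer scheme that combines
three ingredients:

1. **Ensemble cell similarity.** For each of several distance metrics
   (euclidean, 1 − Pearson, 1 − Spearman, 1 − cosine by default), the y × y
   dissimilarity matrix `DIS^n` is converted row-wise into an ordinal matrix
   `R^n` (self-rank 1, next most similar cell rank 2, ...), and the rank
   matrices are aggregated with per-metric weights `t_n` (all 1 by default)
   into a consensus matrix `M = Σ_n t_n R^n`. A smaller consensus entry means
   a more similar cell; rank aggregation makes the ensemble immune to the
   metrics' different scales.

2. **Randomly weighted imputation (SMOTE-style).** Each cell `a_i` is updated
   as the convex blend `a_i* = (1 − RE)·a_i + Σ_{j≠i} f_ij·a_j`, where the
   external mass `Σ f_ij = RE` (default 0.9) and the raw weights come from
   the geometric probability mass `P(X = x) = (1 − p)^(x−1) p` evaluated
   along the consensus similarity ordering — the nearest cell tends to get
   the largest weight, but weights are shuffled within small blocks of
   neighbouring ranks so similarity is not over-trusted. The layer schedule
   sets `p = 1/2, 1/4, ...` so that successive layers draw on an expected
   `1/p = 2, 4, ...` neighbours, up to `mean_number = floor(log2(y/nc))`
   layers with a flat top layer at `p = nc/y`.

3. **NMF denoising.** After every layer, the imputed matrix is replaced by
   its rank-k non-negative factorization reconstruction `Z·H` (Lee–Seung
   multiplicative updates, Frobenius or generalized-KL objective), and one
   final factorization yields the imputed **high-dimensional** matrix
   `Z·H` (cells × genes) and the **low-dimensional** representation `Z`
   (cells × k) used for clustering.

The package also ships a negative-binomial cluster-structured count
simulator with an exact-count dropout masking protocol, and the evaluation
metrics used throughout (ARI, NMI, silhouette, Davies–Bouldin, and `corr2`,
the Pearson correlation of two flattened matrices).

## Worked example

```r
library(scirt)

sim    <- simulate_counts(n_cells = 100, n_genes = 200, n_clusters = 3, seed = 7)
masked <- apply_dropout(sim$matrix, rate = 0.6, seed = 7)   # 60% of entries zeroed
res    <- run_scirt(masked$matrix, nc = 3, seed = 7)
res
#> <scirt_result> 100 cells x 200 genes imputed; low-dim rank 3
#>   5 layer(s); per-layer RMS residual: 4.031 0.01703 0.008826 0.005139 0.001935
tidy(res)
#> # A tibble: 5 × 4
#>   layer times      p rms_residual
#>   <int> <dbl>  <dbl>        <dbl>
#> 1     1     2 0.5         4.03
#> 2     2     4 0.25        0.0170
#> 3     3     8 0.125       0.00883
#> 4     4    16 0.0625      0.00514
#> 5     5    32 0.03        0.00193
```

Five layers were built for 100 cells and 3 expected types
(`floor(log2(100/3)) = 5`); the residual column shows how little each
layer's NMF reconstruction deviates from its imputed matrix after the first
layer. Clustering the low-dimensional matrix recovers the simulated cell
types that the masked matrix has lost:

```r
cl_raw <- kmeans_cluster(masked$matrix, k = 3, seed = 7)
cl_imp <- kmeans_cluster(res$low_dim,   k = 3, seed = 7)
adjusted_rand_index(cl_raw$assignments, sim$labels)   # 0.057
adjusted_rand_index(cl_imp$assignments, sim$labels)   # 0.555
corr2(masked$matrix, sim$matrix)                      # 0.570
corr2(res$high_dim,  sim$matrix)                      # 0.585
```

An ARI of 0.057 on the masked counts means k-means is near random; on the
pipeline's low-dimensional matrix it climbs to 0.555, and the imputed
matrix is also structurally closer to the unmasked truth (`corr2` 0.585 vs
0.570).

## Command line

A thin Rscript front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "scirt.R", package = "scirt"))')" \
  impute --input counts.csv --orientation genes_by_cells \
  --clusters 3 --seed 7 --out-prefix out/run
```

writing `out/run.highdim`, `out/run.lowdim`, a per-layer residual log and a
JSON manifest of the full configuration. `simulate` and `evaluate`
subcommands generate benchmark data and score clusterings.

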