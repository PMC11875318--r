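# smoothpca

Spatially aware dimensionality reduction for spatial transcriptomics (ST),
built from fast linear pieces: randomized PCA of the sparse location-by-gene
matrix, spatial smoothing of the component scores with a sparse
k-nearest-neighbour inverse-distance operator, an optional second PCA stage
that integrates location-level covariates, and reduced-rank reconstruction
of de-noised gene expression. The package also provides graph and
model-based clustering of the smoothed components, the standard evaluation
metrics (adjusted Rand index, Moran's I, CHAOS), a parameter-sweep harness,
and a reference-free zero-inflated negative binomial tissue simulator with
ground-truth domains.

## Who this is for

Analysts of ST data — Visium spots through subcellular MERFISH / Xenium /
Stereo-seq — who want spatial domain detection and spatially de-noised gene
signatures on datasets with 10^4–10^5+ locations, where graph-autoencoder
and Bayesian alternatives become impractically slow or memory-bound.

## The method

Given normalized expression $X \in \mathbb{R}^{n \times m}$ and coordinates
$C \in \mathbb{R}^{n \times 2}$:

1. $W, P$: top-$p$ loadings and scores of column-centered $X$ by randomized
   SVD (Gaussian sketch, oversampling 10, two power iterations; centering is
   implicit so sparse input stays sparse).
2. $D_I$: sparse weight operator from $C$ — keep each location's `threshold`
   nearest neighbours, set the diagonal to the row-minimum distance
   $\alpha$, weight $w = 1/d^{\beta}$ (default $\beta = 2$; gaussian and
   quadratic kernels available), then divide each column by its maximum.
3. $P_s = D_I P$: spatially smoothed scores, a weighted sum over each
   location's neighbourhood.
4. Optionally, standardized covariates $Y$ (library size, cell volume,
   local density, ...) are smoothed per-covariate and appended, and a second
   randomized PCA of $[P_s, Y_s]$ gives covariate-integrated scores $P_c$ —
   a two-stage design that keeps a handful of covariates from being diluted
   among thousands of genes.
5. Reduced-rank reconstruction: $X_r = P_s W^\top + \bar{x}$, followed by
   per-gene adaptive thresholding (values below the gene's $q$-quantile
   magnitude cutoff revert to the observed value or to exact zero) and
   optional rescaling to the observed nonzero variance.

Clustering of $P_s$ / $P_c$ uses a kNN graph in embedding space with
Louvain, Leiden or Walktrap, or a Gaussian mixture on the scores.

## Worked example

Simulate a laminar tissue (eight vertical stripe domains, 2,000 cells,
150 genes, zero-inflated negative binomial counts), run the pipeline, and
compare the detected domains with the ground truth:

```r
library(smoothpca)

sim <- simulate_tissue("stripes", n_cells = 2000, seed = 1)
#> simulated_tissue (stripes): 2000 cells x 150 genes, 8 domains, replicate 1

filtered <- qc_filter(as_spatial_counts(sim))
attr(filtered, "qc_removed")
#> mito_ribo min_reads mad_upper
#>         0         4        99

norm <- normalize_counts(filtered)
emb <- smoothed_pca(norm, p = 20, threshold = 30, beta = 0, seed = 1)
emb
#> spca_embedding (two_stage): 1897 locations, 20 smoothed components
#>   smoothing: threshold = 30, beta = 0

labels <- cluster_embedding(emb$Ps, "leiden", graph_neighbors = 30,
                            target_k = 8, seed = 1)
truth <- sim$domain_labels[match(filtered$location_ids,
                                 rownames(sim$counts))]
round(adjusted_rand_index(labels, truth), 3)
#> [1] 0.783
round(morans_i(labels, norm$coords, is_labels = TRUE), 3)
#> [1] 0.888
round(chaos_score(labels, norm$coords), 3)
#> [1] 0.041
```

The ARI of 0.783 says the eight stripes are recovered nearly cell-for-cell
(1.0 is perfect, 0 is chance); at the full study scale of 10,000 cells the
same configuration reaches above 0.85 because the smoothing radius shrinks
relative to the stripe width. Moran's I near 0.9 and the low CHAOS score
confirm the labels are spatially coherent and compact. De-noised expression
comes from the same embedding:

```r
rec <- reconstruct_expression(norm$X, emb, q = 0.3, scale = TRUE)
head(rec$audit[, c("gene", "cutoff", "kept", "replaced", "zeroed", "s")], 3)
#>       gene     cutoff kept replaced zeroed         s
#> 1 low_d1_1 -1.0936603 1339      153    405 0.7329719
#> 2 low_d2_2 -1.0113746 1299      161    437 0.5181564
#> 3 low_d3_3 -0.8756627 1363      145    389 0.3966176
```

Per gene, the audit records the quantile cutoff, how many values were kept
from the reconstruction, replaced by the observed value, or set to exact
zero, and the variance-matching factor `s`.

A thin command-line front-end over the same functions lives at
`inst/scripts/smoothpca-cli.R`
(`simulate | preprocess | transform | reconstruct | cluster | sweep`, YAML
config plus flag overrides); see `run_pipeline()`.

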