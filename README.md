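# scAFTV

Cell-type discovery from single-cell RNA-seq by **adaptive fractional-order
total-variation regularised low-rank representation (AFTV-LRR)**: learn a
nonnegative low-rank cell–cell coefficient matrix, then cluster cells
spectrally on the symmetrised similarity it induces. The package is aimed at
computational biologists who want a subspace-structure-based alternative to
neighbourhood-graph clustering that is robust to dropout noise, together
with the surrounding plumbing: preprocessing, partition metrics, marker-gene
ranking, and a seeded synthetic-data generator for testing.

## The model

For a preprocessed genes × cells matrix $X \in \mathbb{R}^{m \times n}$,
AFTV-LRR solves

$$\min_{R \ge 0}\ \tfrac12\lVert X - XR\rVert_F^2
 \;+\; \alpha\lVert R\rVert_*
 \;+\; \lambda_{tv}\,\mathrm{AFTV}(XR),$$

where $\lVert R\rVert_*$ is the nuclear norm (convex surrogate for rank:
cells from a union of low-dimensional subspaces admit a low-rank
representation whose support identifies the subspaces), and
$\mathrm{AFTV}(\cdot)$ is an adaptive fractional-order total variation of
the reconstruction $XR$, built from Grünwald–Letnikov differences
$(D^\beta H)_i = \sum_{k<K} (-1)^k\binom{\beta}{k} H_{i-k}$ with a spatially
varying exponent $l(x,y)\in(1,2)$ that smooths flat regions strongly and
preserves sharp transitions. The problem is solved by ADMM: an SPD linear
system for $R$ (the TV term handled by lagged diffusivity with a
preconditioned conjugate-gradient solve), singular value thresholding for
the nuclear-norm block, and a scaled dual update. Cells are clustered by
normalised spectral clustering on $S = (R + R^\top)/2$, and partitions are
scored with ARI / NMI. Details and design rationale are in the vignette
(`vignettes/aftv-lrr-methods.Rmd`).

## Worked example

```r
library(scAFTV)

sce <- standardFixture()                    # 200 genes x 90 cells, 3 clusters,
                                            # 30% dropout, seed 1
X   <- preprocessCells(SummarizedExperiment::assay(sce, 1))
fit <- fitAFTVLRR(X)                        # alpha 0.5, mu 0.25, beta 1.3, K 3
fit
#> AFTVFit on 90 cells: 84 iterations (converged)
#>   objective 20.4215 | primal 9.65e-06 | dual 1.32e-05 | change 2.07e-05

cl <- spectralClustering(fit, k = 3, seed = 1)
cl
#> SpectralClustering: 90 cells in 3 clusters (sizes: 29, 31, 30)

truth <- SummarizedExperiment::colData(sce)$cluster
unlist(clusterMetrics(truth, clusterLabels(cl))[c("ari", "nmi")])
#>       ari       nmi
#> 0.9664753 0.9554817

head(rankMarkerGenes(X, clusterLabels(cl), topN = 3), 6)
#>   cluster rank    gene t_score mean_in mean_out
#> 1       1    1 gene_13   10.41  0.1107   0.0312
#> 2       1    2  gene_4    8.44  0.1067   0.0331
#> 3       1    3  gene_1    7.07  0.0977   0.0282
#> 4       2    1 gene_13   -6.96  0.0242   0.0739
#> 5       2    2 gene_11    6.52  0.0933   0.0282
#> 6       2    3  gene_6    -6.37  0.0120   0.0532
```

The solver converged in 84 iterations with the primal residual
($\lVert R-Q\rVert_F$) at 1e-5. An ARI of 0.966 on this 30%-dropout
fixture means the partition matches the generator's ground truth up to a
single reassigned cell (on the noise-free variant of the fixture both
metrics are exactly 1). The top-ranked genes of cluster 1 — `gene_1`,
`gene_4`, `gene_13` — are planted markers of that cluster, with positive
Welch $t$ indicating in-cluster enrichment; the same genes reappear with
negative $t$ for other clusters, as exclusive markers should.

Everything can also be driven from the shell through
`inst/scripts/aftv-lrr.R` (subcommands `run`, `simulate`, `preprocess`,
`eval`, `markers`), e.g.

```sh
Rscript inst/scripts/aftv-lrr.R simulate --out data
Rscript inst/scripts/aftv-lrr.R run --input data/expr.csv -k 3 \
    --labels data/labels.txt --out results
```

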