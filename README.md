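# caspectral

A spectral toolkit for contingency tables and presence–absence incidence
matrices viewed as bipartite networks, for ecologists doing gradient
analysis and bioregionalization, economists working with co-occurrence
complexity indices, and anyone clustering or embedding one-mode projections
of bipartite data.

## The method

Given a nonnegative table *A* (rows × columns, e.g. species × sites) with
row margins *r*, column margins *c*, degree matrices *D_r*, *D_c* and total
*n*, simple correspondence analysis (CA) solves

    D_r^{-1} A D_c^{-1} A^T v = λ v        (and its transpose for u)

with spectrum 1 = λ₁ > λ₂ ≥ … ≥ 0 on a connected network. The package
exposes the same eigendecomposition under its three equivalent readings:

- **Ordination** — the scores maximize the Pearson correlation of row and
  column scores along the edges of the bipartite network; per axis,
  λ_k = corr²(y_r, y_c). Smooth axes are latent gradients.
- **Spectral clustering** — the eigenvectors are relaxed normalized-cut
  labels of the similarity network S_r = A D_c⁻¹ Aᵀ obtained by stochastic
  complementation, with generalized Laplacian eigenvalues λ̃ = 1 − λ. The
  multiplicity of λ = 1 counts connected components; mean(λ₁…λ_K) scores a
  K-way partition.
- **Graph embedding** — principal coordinates x_k = √λ_k · v_k embed the
  similarity network; λ_k / Σ_{j≥2} λ_j is each axis's variation share.

On top of the decomposition sit the eigengap heuristic for choosing the
cluster count, seeded k-means on the spectral embedding, a recursive
cluster-then-ordinate procedure for data mixing clusters and gradients, an
arch-effect diagnostic, stylized bipartite generators with planted ground
truth, Balassa-rule (RCA) binarization for weighted tables, and a
reproducible file-based pipeline with a thin CLI
(`inst/cli/caspectral.R`: `generate`, `spectrum`, `run`, `plot`).

## Worked example

Two weakly connected clusters, each hiding its own gradient — the case
where naive ordination fails and cluster-then-ordinate succeeds:

```r
library(caspectral)

tab <- blocks_with_gradients(seed = 6)  # 60 x 80, planted truth attached
spectrum <- ca_spectrum(tab)
tidy(spectrum)
#>   eigenvector ca_axis eigenvalue sqrt_eigenvalue variation_share
#> 1           1      NA     1                1             NA
#> 2           2       1     0.919            0.959          0.357
#> 3           3       2     0.479            0.692          0.186
#> 4           4       3     0.470            0.685          0.182
#> 5           5       4     0.0658           0.256          0.0255
```

Four eigenvalues stand clear of the bulk: two near-unit cluster
eigenvalues (1, 0.919) and one gradient eigenvalue per block (0.479,
0.470). The eigengap after position 2 says "two clusters", so the
recursive procedure splits once and ordinates within each leaf:

```r
tree <- recursive_scca(tab, seed = 7)
tree
#> <scca_tree> 3 node(s), 2 leaf/leaves (seed 7, max_k 20, min_size 3)
#>   - node 1 [split]: 60 rows, K = 2, quality = 0.960
#>     - node 2 [leaf]: 30 rows, K = 1, quality = 1.000
#>     - node 3 [leaf]: 30 rows, K = 1, quality = 1.000

scca_assignments(tree)
#>   label  leaf axis1_score
#> 1 r001      2       1.32
#> 2 r002      2       1.18
#> 3 r003      2       1.06
#> 4 r004      2       0.957
```

Each leaf is one planted block (quality 1.000 means its K = 1 spectrum is
led by a single unit eigenvalue), and the leaf's first CA axis descends
monotonically along the planted within-block order — the recovered
gradient (Spearman |ρ| > 0.99 against the truth). `autoplot(spectrum)`
draws the scree with the eigengap marked; `autoplot(ca_embed(spectrum, 2))`
draws the correspondence plot.

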