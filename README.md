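# simplexDeconv

Reference-free deconvolution of spatial transcriptomics data by
minimum-volume simplex identification.

Most spatial transcriptomics platforms capture several cells per spot, so
each measured profile is a mixture over cell types. Reference-based
deconvolution methods resolve such mixtures with an annotated single-cell
reference — which is often unavailable, or mismatched to the tissue at
hand. `simplexDeconv` estimates per-spot cell-type proportions, per-type
expression profiles and ranked marker genes from the spatial matrix
alone. It is aimed at analysts working with Spatial Transcriptomics /
Visium-style genes-by-spots count matrices who want compositions without
committing to a reference panel.

## The model

With $L$ genes, $S$ spots and $K$ cell types,

$$Y = MH,\qquad M \in \mathbb{R}^{L\times K}_{\ge 0},\quad
H \in \mathbb{R}^{K\times S}_{\ge 0},\quad \mathbf 1^\top H = \mathbf 1^\top .$$

Row-normalizing $Y$ makes every gene a convex combination of the $K$
normalized rows of $H$: the gene cloud spans a $(K-1)$-simplex whose
corners are the pure cell types' proportion signatures. The pipeline:

1. **K selection** — corrected AIC
   $\mathrm{AIC}_K = LS\ln(\mathrm{SSR}_K/LS) + 2p + 2p(p{+}1)/(LS{-}p{-}1)$
   with $p = K(L+S)$, minimized over a candidate grid
   (`selectK`);
2. **cell-type-specific gene selection** — iterate a constrained
   alternating-NNLS factorization ("deconf") with proportion-driven
   marker re-selection until the reconstruction RMSE converges, keeping
   fewer than 1,000 genes (`iterateSelection`);
3. **corner identification** — project the row-normalized genes onto
   their $(K-1)$-dimensional affine hull and fit the minimum-volume
   enclosing simplex with a split augmented-Lagrangian solver
   (`affineProject`, `sisalFit`):
   $\min_Q -\log|\det Q| + \tau\sum \mathrm{hinge}(-QX)$;
4. **proportions and profiles** — rescale the recovered corners to a
   column-stochastic $H$ via the least-squares coefficients of
   $\alpha^\top H_p = \mathbf 1^\top$, recover $M$ by row-wise NNLS, rank
   markers by projected corner distance (`solveAlpha`, `rescaleH`,
   `estimateM`, `rankMarkers`);
5. optionally **assign labels** against an annotated reference panel by
   the mean of Pearson correlation and a Gaussian Naive-Bayes posterior
   (`assignLabels`).

A simulator with region-dominant mixtures and a tunable heterogeneity
rate (`makeReference`, `simulateSpots`) and evaluation metrics with
cell-type alignment (`alignTypes`, `proportionMetrics`) round out the
package.

## Worked example

```r
library(simplexDeconv)

ref <- makeReference(K = 4, L = 2000, seed = 7)
sim <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 40,
                     hetRate = 0.2, seed = 7)
res <- simplexDeconvolve(sim@Y, K = 4, seed = 7)
res
#> DeconvResult: 4 cell types x 120 spots over 389 selected genes
#>   reconstruction RMSE 6.089; clipped negative mass 2.88
proportionMetrics(proportions(res), trueProportions(sim))
#> EvalReport: RMSE 0.0318  MAE 0.0218  JSD 0.0024  PCC 0.9924
```

The `DeconvResult` line reports the working gene set after iterative
selection and the residual of the final fit; the clipped mass is the
total negative pseudo-proportion removed when the soft-constrained
corners were rescaled (small values mean the fitted simplex covers the
spots well). The evaluation line compares estimated against true
proportions after optimal cell-type alignment: a per-matrix Pearson
correlation above 0.99 and mean absolute error near 0.02 mean the
composition of every spot is recovered almost exactly at this noise
level. (The reconstruction RMSE is on the library-scaled expression
scale of the 389 selected genes, so its units are counts, not
proportions.)

`proportions(res)`, `profiles(res)`, `markers(res)` and
`selectedGenes(res)` access the individual results; `assignLabels(res,
referenceMatrix)` names the anonymous types when a labeled panel exists.

A command-line wrapper with `simulate`, `select-k`, `deconvolve`,
`annotate`, `evaluate` and `smoke` subcommands is installed at
`inst/cli/simplex-deconv.R`; all logic sits behind `runCli()`.

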