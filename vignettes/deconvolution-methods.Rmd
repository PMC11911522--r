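---
title: "Reference-free deconvolution of spatial transcriptomics by minimum-volume simplex identification"
author: "simplexDeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free deconvolution by simplex identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simplexDeconv)
```

## The problem and the model

Spatial transcriptomics measures expression at capture spots that each
contain a handful of cells, so every observed spot profile is a mixture
over cell types. With `L` genes, `S` spots and `K` cell types, the model
is

$$Y = M H, \qquad Y \in \mathbb{R}_{\ge 0}^{L \times S},\;
M \in \mathbb{R}_{\ge 0}^{L \times K},\;
H \in \mathbb{R}_{\ge 0}^{K \times S},\; \mathbf{1}^\top H = \mathbf{1}^\top,$$

where `M` holds per-type expression profiles and each column of `H` is the
cell-type composition of one spot. The package estimates `K`, `M` and `H`
from `Y` alone — no annotated single-cell reference is required — by
exploiting the geometry of the model: after dividing every gene row by its
sum, each gene becomes a point in `S`-dimensional space that is a *convex
combination* of the `K` row-normalized rows of `H`. The gene cloud
therefore lies in a `(K-1)`-dimensional simplex whose corners are, up to
per-row scaling, the proportion signatures of the pure cell types.
Recovering those corners recovers `H`; `M` then follows by non-negative
least squares, and the genes projecting closest to a corner are that
type's markers.

This genes-as-points orientation is the one reading under which the
corner matrix ("pseudo-proportions" `Hp`, a `K x S` matrix) can be
rescaled into a column-stochastic `H`: the coefficients `alpha` solve the
least-squares system `alpha' Hp = 1'`, and `H = diag(alpha) Hp` after
clipping small soft-constraint negatives (the clipped mass is reported in
the diagnostics, as a fit-quality signal).

## Pipeline stages

`simplexDeconvolve()` composes the stages; each is exported on its own.

1. **Preprocessing** (`filterGenes`, `scaleLibrary`, optionally
   `logNormalize`): genes detected in more than `minFrac` (default 5%)
   but less than `maxFrac` (default 100%) of spots are kept, both bounds
   strict. Detection means a strictly positive value. Missing values
   become zeros at load time. The factorization runs on the raw (linear)
   scale by default because the mixture model is linear in expression,
   with spot columns scaled to a common library size first: spots capture
   different numbers of cells, and without that scaling the
   column-stochastic factorization would have to absorb a purely
   technical depth factor, which degrades both the fit and the
   proportion-driven gene re-selection built on it. Proportions are
   within-spot ratios, so the scaling changes no estimand. `useLog = TRUE` switches to log-normalized values for
   users who want variance compression.
2. **Model-order selection** (`selectK`): see below.
3. **Cell-type-specific gene selection** (`iterateSelection`): an initial
   list of the `nInit` highest-CV genes is refined by alternating a
   constrained factorization (`deconf`) with a proportion-driven
   re-selection (`celltypeSpecificFeatures`), until the reconstruction
   RMSE moves by at most `rmseTol` (default 1e-4) between rounds. The
   working list always stays below 1,000 genes (round-robin truncation
   across the per-type lists, which keeps types balanced). Re-selection
   *replaces* the list rather than augmenting it, so genes that stop
   looking type-specific can drop back out.
4. **Corner identification** (`affineProject` + `sisalFit`): the
   row-normalized gene points are projected onto their `(K-1)`-dimensional
   affine hull (top right singular vectors of the centered cloud) and the
   minimum-volume enclosing simplex is fitted by a split
   augmented-Lagrangian scheme (below).
5. **Rescaling and outputs** (`solveAlpha`, `rescaleH`, `estimateM`,
   `rankMarkers`): proportions, profiles and per-corner marker rankings.
6. **Optional label assignment** (`assignLabels`) against an annotated
   reference panel.

## The inner factorization

`deconf()` is an alternating constrained least-squares factorization.
Given `H`, every row of `M` solves a non-negative least-squares problem
(all rows share the Gram matrix `H H'` — the fast-combinatorial
formulation, implemented in compiled code with an active-set solver on the
normal equations). Given `M`, every column of `H` solves a non-negative
least-squares problem with a weighted sum-to-one row appended, followed by
an exact renormalization. The weighted-row formulation was chosen over
clip-and-renormalize projection because it approximates the exact
simplex-constrained solve and keeps the error trace monotone in practice.
`H` is initialized with flat-Dirichlet columns under the caller's seed and
`M` from one NNLS pass, so fits are bit-reproducible. Iteration stops when
the count reaches `maxIter` (default 1,000) or the Frobenius residual
falls below `tolA` (default `1e-6 * ||Y||_F`; the tolerance is exposed
because no universal constant is meaningful across data scales). Collapsed
rows or columns (all-zero) are re-seeded with a small uniform mass and
counted in a message — this prevents silent rank collapse.

## Choosing the number of cell types

`selectK()` computes, for every candidate `K`, the corrected AIC

$$\mathrm{AIC}_K = L S \ln\!\frac{\mathrm{SSR}_K}{L S} + 2p
+ \frac{2p(p+1)}{LS - p - 1}, \qquad p = K(L+S),$$

and returns the argmin (ties to the smaller `K`) together with the whole
curve, which `plot()` displays for knee inspection.

Two design points matter and were settled empirically:

* **Residual scale.** The SSR is measured on the *row-normalized* gene
  subset — the same scale on which the simplex geometry is defined. On raw
  counts the residual is dominated by a few highly expressed genes whose
  negative-binomial noise is large in absolute terms, and on log values
  the mixture manifold is curved, so in both cases extra components keep
  harvesting structured residual and the argmin drifts above the true
  order. Row normalization equalizes gene scales and leaves the signal
  exactly rank `K`.
* **Constraint set.** The per-`K` fits run with unconstrained non-negative
  `H` (`sumToOne = FALSE`): `p(K) = K(L+S)` counts all entries of `M` and
  `H` as free, and the unconstrained fit is the one whose residual that
  count describes. It also absorbs per-spot total variation (spots hold
  different numbers of cells), which a column-stochastic fit would
  otherwise push into spurious extra components.

The criterion needs `L` appreciably larger than `S` to have margin over
noise — the same `K < S \ll L` regime the corner geometry itself assumes —
so `selectK` keeps all filtered genes by default for the AIC stage
(`nInit` caps the count if runtime matters; values below roughly 10–20x
`S` blunt the criterion). With very few genes the AIC can keep decreasing
past the knee; the curve is always returned so the knee remains
inspectable.

## The corner solver

The minimum-volume problem is solved in the projected coordinates
augmented with a constant-1 row. Writing `Q` for the inverse of the
corner matrix, the objective is

$$\min_Q\; -\log\lvert\det Q\rvert + \tau \sum_{i,j}
\max(0, -(QX)_{ij}) \quad \text{s.t.}\quad \mathbf{1}^\top Q = e_K^\top,$$

whose equality constraint pins the barycentric coordinates of every data
point to sum to one (without it the objective is unbounded under scaling).
Each outer step linearizes the log-determinant at the current `Q` with a
proximal trust weight chosen by backtracking line search, and solves the
resulting convex hinge-regularized quadratic by ADMM with the splitting
`Z = QX`; the equality constraint has a closed-form Lagrange update inside
the ADMM `Q`-step. Only objective-decreasing steps are accepted, so the
objective trace is non-increasing by construction.

Initialization is a vertex-component-style greedy pick of extreme data
points (successive orthogonal projections), which is deterministic up to
seeded tie-breaking and lands exactly on the true corners when they are
present in the data. The hinge weight `tau` (default 1.0) balances volume
against points left outside: small values tolerate noise, large values
approach the hard enclosing constraint; on noiseless data any `tau`
of order 1 or above recovers exact corners. `maxIter` defaults to 100
outer steps; the inner ADMM runs 60 iterations with unit step, which is
far past convergence for the `K x K` problems arising here. Corner order
is canonicalized by descending first projected coordinate so repeated
runs agree.

## Label assignment

When an annotated reference panel is available, `assignLabels()` scores
every (estimated type, reference type) pair by the mean of (i) the Pearson
correlation of the `log1p` profiles over shared genes and (ii) the
posterior probability of the reference label under a Gaussian Naive-Bayes
classifier trained on pseudo-replicates of the reference profiles.
Posteriors are computed in log space with log-sum-exp — products of
hundreds of per-gene densities underflow double precision otherwise — and
the training set includes one diffuse *background* class built from the
across-type mean and spread. The background class calibrates the
posterior: a profile resembling no reference type is captured by the
background and receives a near-zero posterior for every real type, so its
composite score falls below the assignment threshold. Without it,
normalized posteriors would hand even a nonsense profile a posterior near
1 for whichever class is least distant, and composite scores could never
fall much below 0.5. Assignment is greedy — repeatedly take the global
maximum of the score matrix and delete its row and column — and estimated
types whose best remaining score is below `threshold` (default 0.3, a
deliberate round number in the gap we observe between genuine matches,
which score near 1, and mismatches, which score near 0) are returned as
`"unassigned"`.

## The simulator

`makeReference()` + `simulateSpots()` generate the synthetic data used
throughout the tests. The generator emulates a tissue with region-dominant
cell types:

* per-type mean profiles with log-normal baselines (meanlog `log(1.5)`,
  sdlog 1 — spanning the two-orders-of-magnitude expression range typical
  of single-cell data) and 20 exclusive markers per type, elevated 6-fold
  in their own type and suppressed to 10% of baseline elsewhere (markers
  in single-cell references are near on/off);
* a default gene pool of 18,263 genes, the size of the mouse
  nervous-system single-cell data this protocol mirrors; the detection
  filter then leaves a few thousand usable genes, preserving the
  `K < S \ll L` regime the method assumes;
* per region a distinct dominant type; per spot a number of co-occurring
  types drawn uniformly from {2, ..., min(6, K)}, flat-Dirichlet
  proportions over them, and dominance enforced by swapping the largest
  coordinate onto the dominant type (the gentlest intervention that
  realizes region dominance without distorting the rest of the draw);
* a heterogeneity rate `hetRate` in [0, 0.6] marking spots whose
  proportions carry no dominance constraint;
* spot expression as the sum of 5–15 single cells, each negative binomial
  (dispersion 0.3) around its type's mean profile; a sum of `n` such
  cells is drawn as NB(`n mu`, `n/dispersion`). The recorded ground truth
  is the *realized* cell-count fraction, not the Dirichlet draw, because
  the expression actually generated is a finite-cell sum.

What the simulator does **not** emulate: spatial autocorrelation within
regions (spots are exchangeable within a region), platform-specific
artifacts (spot bleeding, segmentation errors, zero inflation beyond the
negative binomial), mismatched or absent reference panels, and continuous
gradients between cell states. Passing the simulation-based tests
therefore demonstrates correct recovery under the stated mixture model,
not robustness to every failure mode of real tissue sections.

## Numerical choices and degenerate inputs

* Detection is strictly positive expression; both filter bounds strict.
* `affineProject` refuses data whose centered rank is below `K-1`
  (relative singular-value threshold 1e-8) — asking for more corners than
  the cloud spans is a modeling error, not something to paper over.
* A singular corner initialization restarts from a jittered seed at most
  3 times before erring.
* Negative pseudo-proportion mass is clipped and reported per spot; an
  entirely non-positive column ("simplex does not cover spot") is an
  error.
* Ties in CV ranking and marker distances break lexicographically by gene
  id; corner order by descending first coordinate — all outputs are
  deterministic under a seed, and a single pipeline seed derives
  per-stage substreams.
* `K = 1` degenerates gracefully in `deconf` (H is the all-ones row); the
  corner stages require `K >= 2`.

## Problem sizes in the shipped tests

Unit tests run on small matrices (tens to hundreds of genes, 20–50
spots). The acceptance-style tests and `scripts/acceptance.R` use the
study-scale configuration — 18,263-gene pool, 3 regions x 80 spots,
heterogeneity 0.3, ten seeds where replication matters — chosen to mirror
the simulation protocol the generator emulates.

## Known limitations

* Minimum-volume recovery needs near-pure genes per type: if no gene is
  close to a corner, the enclosing simplex of the gene cloud is strictly
  inside the true one and proportions shrink toward uniformity. The
  iterative marker selection exists precisely to enrich the gene set
  toward corners.
* The AIC stage inherits the local-optimum noise of the inner
  factorization; `reps > 1` takes the best of several restarts when a
  smoother curve is needed.
* Very large spot counts (`S` in the thousands) erode the `S \ll L`
  assumption after filtering; the pipeline warns when the selected gene
  count does not exceed `S`.

## A compact worked example

```{r example, eval = FALSE}
ref <- makeReference(K = 4, L = 2000, seed = 7)
sim <- simulateSpots(ref, nRegions = 3, spotsPerRegion = 40,
                     hetRate = 0.2, seed = 7)
res <- simplexDeconvolve(sim@Y, K = 4, seed = 7)
proportionMetrics(proportions(res), trueProportions(sim))
```
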