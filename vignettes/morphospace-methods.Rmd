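---
title: "Methods: building and visualising morphospaces with shapescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and visualising morphospaces with shapescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapescape)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the parameters that matter, the
numerical choices, and — importantly — what the synthetic data generators
do and do not emulate, hence what a green test suite does and does not
demonstrate about real data.

## Shape representations

Two families of shape data are supported, with a common flattened
currency.

*Landmark configurations* are `n × k × m` arrays (`m` = 2 or 3). After
generalized Procrustes alignment the configurations are dimensionless:
centred at the origin and scaled to unit centroid size
(CS = √Σᵢ‖xᵢ − x̄‖², the standard geometric-morphometric size measure).
Flattening is landmark-major, coordinate-minor (x₁, y₁[, z₁], x₂, …);
the order is recorded in the `shape_matrix` so ordination loadings
un-flatten unambiguously.

*Closed outlines* are represented by elliptic Fourier coefficients: per
harmonic j the quadruple (aⱼ, bⱼ, cⱼ, dⱼ), flattened harmonic-major.
Decomposition uses cumulative chord-length parameterisation. **No
starting-point or rotation normalisation is applied**: inputs are assumed
pre-normalised upstream if such invariance is required. This matches the
common situation where coefficients arrive already standardised from the
acquisition pipeline; applying a second normalisation silently would
change the data. The offset terms (A₀, C₀) are carried separately and are
not part of the shape variables.

## Procrustes alignment

GPA here is the "full" variant: every configuration is centred, scaled to
unit centroid size, and rotated onto the consensus by the SVD solution
with a determinant correction that forbids reflections. The consensus is
initialised with the first specimen, recomputed as the average of the
rotated configurations (re-centred, re-scaled to unit size), and
iteration stops when the consensus moves by less than 1e-10 in Frobenius
norm, or after 100 iterations. No partial-Procrustes (size-preserving)
option is offered. The summed squared distance of configurations to the
consensus is recorded per iteration (`ss_trace`) and is non-increasing —
a cheap sanity check on convergence. Degenerate configurations (zero
centroid size) abort with the offending specimen named.

## Thin-plate splines

`tps_fit` solves the standard bordered linear system with radial kernel
U(r) = r² log r² (U(0) = 0) in 2D and U(r) = r in 3D. The 3D kernel
follows the convention common in morphometric practice; conventions
differ across software in sign and scaling, which changes the
coefficients but not the interpolant. The map is exact at the source
landmarks and reproduces affine transforms with zero non-affine weights;
the reported bending energy is the quadratic form of the weights in the
kernel matrix (sign-adjusted in 3D, where the kernel is conditionally
negative definite) and is clamped to zero when it is negative within
1e-8, i.e. within round-off of an affine map. Repeated source landmarks
and collinear (2D) / coplanar (3D) sources are rejected — the bordered
system is singular there.

The same machinery interpolates scalar fields: a `k × 1` target turns
the TPS into the surface interpolator behind performance landscapes.

## Refinement

Nuisance variation is removed by ordinary least squares over the shape
variables: fit `fit_shape_regression` on a design matrix (factors
dummy-coded against a first-level reference — the coding matters when
interpreting `expected_shapes` rows), keep the residuals, and add back
either the grand mean (default) or the model prediction at a chosen
design row (`displace_to`), e.g. the shape predicted at maximum size when
the target of inference is adult, "static" morphology.

Group-wise refinement (`detrend_by_group`) loops the same machinery over
groups with a shared formula. Each group's shapes are displaced back to
*that group's own* mean (or its own `displace_at` prediction): the
between-group structure is deliberately preserved while within-group
nuisance variation is stripped. Re-centring globally instead would mix
the group contrasts into the residuals.

The Burnaby filter removes the span of explicit nuisance directions F by
the orthogonal projector P = I − F(FᵀF)⁻¹Fᵀ applied to centred data; the
projector is checked for idempotency at fit time, filtered data have
exactly zero variance along every column of F, and filtering twice equals
filtering once.

## Ordinations

All six ordinations return the same container and satisfy one affine
contract, `scores = (x − center)·loadings`, with unit-norm loading
columns. A deterministic sign convention — each loading column is flipped
so its largest-magnitude entry is positive — makes repeated runs
bit-identical.

- **PCA**: eigendecomposition of the sample covariance via SVD of the
  centred data; `explained` holds eigenvalues, which sum to the total
  variance.
- **Between-groups PCA**: PCA of the `g × p` matrix of group means (each
  group counting once — the method's standard definition; size-weighted
  centring is an option), then projection of all observations; at most
  g − 1 axes. With `loocv = TRUE`, each observation's scores come from
  axes recomputed with that observation removed from its own group mean
  (the group structure otherwise intact; a group reduced to zero members
  is an error). LOOCV axes have their signs aligned to the full-sample
  axes so cross-validated scores are comparable. This is the standard
  guard against the spurious separation bgPCA produces when variables
  outnumber observations.
- **Two-block PLS**: SVD of the cross-covariance of the centred blocks;
  paired singular vectors, min(p, p_y, n−1) axes, singular values in
  `explained`. A zero cross-covariance matrix warns and returns zero
  singular values rather than failing.
- **Burnaby ordination**: when covariates are supplied, the removed
  directions are the regression coefficient vectors of shapes on those
  covariates; PCA is then performed in the orthogonal complement, so all
  scores are exactly uncorrelated with the removed directions.
- **pPCA**: covariance mode (not correlation). The root state is the GLS
  estimate a = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹X with C the Brownian tip covariance; the
  evolutionary covariance R = (X−1aᵀ)ᵀC⁻¹(X−1aᵀ)/(s−1) is
  eigendecomposed and GLS-centred data are projected on its eigenvectors.
  All eigenvectors spanning the data are kept, so the full score set is a
  rigid rotation of the centred data: inter-specimen distances are
  preserved, and analyses of disparity or separation in the full space
  still require phylogenetic correction.
- **PACA**: axes are the eigenvectors of XcᵀCXc (Xc GLS-centred), so the
  first axis maximises the covariation between scores and the
  phylogenetic structure over all unit directions. The literature admits
  more than one algebraic presentation of phylogenetically aligned
  components; this one is pinned by that maximisation property (verified
  against 1,000 random directions in the tests) rather than by matching
  a particular printed equation.

Ancestral states under Brownian motion are the maximum-likelihood/GLS
estimates from the joint tip-plus-node covariance: with Cfull the
shared-path-length matrix over all vertices, node states are
a + C_nt C_tt⁻¹(X − 1aᵀ). The implementation is hand-written (the solve
is a few lines) and cross-checked in the tests against an independent ML
implementation (`phytools::fastAnc`) and against a brute-force joint GLS
on a four-tip tree. Non-Brownian models (OU, EB, multi-rate) are out of
scope.

## The canvas and its layers

`build_canvas` computes background shape models on a regular grid over
the plotted axis pair — by default 6 × 5 models with 5% range padding.
The model at grid position (s_i, s_j) is `center + s_i·v_i + s_j·v_j`:
**non-plotted axes are held at zero**, so background models visualise
only the plotted plane's variation. (Holding them at per-cell conditional
means would entangle the display with the sample's covariance structure;
zero is the interpretable choice and is stated here because software
differs.) Rendering dispatches on the representation: outline models are
drawn as silhouettes via inverse elliptic Fourier reconstruction,
landmark models as point clouds/wireframes, optionally with a template
polyline warped by TPS from the mean shape.

Projection layers never mutate the canvas's ordination; each `proj_*`
call returns a new canvas with the layer appended, and all layer geometry
(scores, hull vertices, ellipse polygons, node positions, front indices)
is exportable as CSV by the pipeline, independent of any plotting device.

Group ellipses are *data ellipses* by default: centred on the group mean
with axes from the 2 × 2 score covariance scaled by √χ²₂(level), so for
bivariate normal scores they contain ≈ `level` of the population (the
Monte-Carlo coverage test uses n = 20,000). The alternative reading of a
"confidence ellipse" — uncertainty of the group *mean* — is available via
`mean_ellipse = TRUE`, which scales the covariance by 1/n. Both are
offered because either can be meant in practice; the data ellipse is the
default since it describes the sample's occupation of morphospace.

Performance landscapes interpolate measured values over the canvas by
TPS (exact at supports, reproducing affine surfaces); when the support
configuration makes the TPS system singular, inverse-distance weighting
is used instead and the landscape records which interpolator ran.
"Empirical" and "theoretical" modes differ only in provenance annotation:
in theoretical mode the supports are typically an `extract_shapes` grid
whose shapes were scored externally.

Pareto optimality over two (or more) competing performance metrics uses
iterative front peeling: rank 1 is the non-dominated set, which is
removed, and so on. The normalised rank 1 − (rank−1)/max(rank) is the
optimality score that `proj_landscape` can interpolate into an
optimality surface. The front construction is pinned by an O(q²)
domination oracle in the tests rather than by any particular published
formulation of the surface.

Phenograms place every vertex of a time-calibrated tree at (node height,
axis score), with internal scores estimated under Brownian motion when
not supplied, and draw straight parent-child segments (no curvature or
attraction smoothing). Hybrid views pair one ordination axis with a
non-shape variable — scatter for continuous covariates, box/violin
summaries per level for categorical ones — optionally with margin shape
models computed exactly as `extract_shapes` along that single axis.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* of three common
study designs at the paper-scale sizes used throughout the tests:

- `make_outline_dataset` (default 137 outlines, 4 species, 7 harmonics):
  a shared base ellipse, species mean offsets that are nearly collinear —
  a dominant elongation contrast on the first-harmonic d coefficient
  plus small orthogonal perturbations per species (closely related
  congeners typically differ along few directions) — log-size-linked
  coefficient drift along a fixed unit direction (slope 0.04), and iid
  coefficient noise (sd 0.01).
- `make_landmark_dataset` (default 7 species × 10 individuals × 4
  measurements = 280 shapes of 9 2D landmarks): a template polygon plus
  species offsets (0.05), a smooth elongation-like allometric direction
  (slope 0.08 per unit log size), individual effects (0.02), locality
  and age nuisance shifts (0.03, 0.02), coordinate noise (0.01), and —
  so that alignment is actually exercised — a random similarity
  transform per configuration.
- `make_bm_tips`: independent Brownian traits on a tree via the Cholesky
  factor of the phylogenetic covariance; `make_fixture_tree` supplies a
  reproducible 13-tip ultrametric tree of unit height.

All generators are pure functions of their arguments and seed. The
injected effects are recoverable by the corresponding estimators — that
is the module's reason to exist, and the tests verify slope and offset
recovery within three standard errors.

What they do **not** emulate: real outlines and landmarks live on
non-linear shape manifolds (the generators are additive in the flattened
space); real allometry is rarely exactly linear in log size; measurement
error is spatially correlated, not iid; and no attempt is made to match
the parameter values of any real dataset — only its design. Green tests
therefore demonstrate that the estimators recover what was injected under
the stated model, not that any biological claim holds for real shells,
ontogenies or tails.

## Numerical choices and degenerate inputs

- GPA convergence 1e-10 / 100 iterations; first specimen initialises the
  consensus.
- Eigenvalue/axis retention: axes with eigenvalue below 1e-12 of the
  largest are dropped (they are numerically null directions, e.g. the
  four degrees of freedom GPA fixes in 2D).
- LOOCV sign alignment by dot product with the full-sample axes.
- The TPS-based landscape falls back to inverse-distance weighting only
  when the TPS solve fails; collinear supports are an error with a hint
  to add coverage, since no 2D surface is identified by them.
- Degenerate groups in `proj_groups` (fewer than 3 points, collinear
  points for hulls/ellipses) are skipped with a warning naming the group
  rather than failing the whole layer.
- CSV artifacts use '.' decimals and UTF-8; landmark indices are 1-based
  in user-facing files, 0-based internally.

One quantitative subtlety worth recording: the elliptic Fourier
round-trip error of a side-1 square at 20 harmonics is 0.0101 (maximum
deviation of the reconstructed curve from the square's boundary). This
is the true truncation error of the Fourier series — verified against
dense numerical integration of the exact coefficients — not an
implementation artefact; reconstruction error decreases monotonically
with the harmonic count.

## Problem sizes

The test suite and the acceptance script run at desk scale by design:
137/280-specimen fixtures, 13-tip trees, a 999-replicate permutation
null for the LOOCV check, 2,000 Monte-Carlo replicates for the
Brownian-motion covariance check, and 20,000 points for ellipse
coverage. These sizes give the distributional checks enough resolution
while keeping a full run under a minute on one CPU.

## Known limitations

Semilandmark sliding, mesh (OBJ/PLY) warping, symmetric/asymmetric and
uniform/non-uniform decompositions, Fourier normalisation, non-Brownian
evolutionary models, and axis-retention criteria (Horn's, Bookstein's)
are out of scope; upstream tools provide them and their outputs are
accepted as inputs here. Ordinations are linear throughout: curved shape
trajectories are only approximated by their projections.
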