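---
title: "Elastic and linear shape analysis of planar outlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic and linear shape analysis of planar outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(elastishape)
```

## The problem

Many scientific classification problems — species of leaves, genera of
gastropod shells, typologies of ancient pottery — rest on the *shape* of an
object's outline: its form stripped of position, scale and orientation.
This package implements two families of shape distances over such outlines
and everything needed to use them in a classification study:

* **Eigenshapes** (linear geometric morphometrics): outlines are resampled
  to equally spaced semi-landmarks, superimposed by generalized Procrustes
  analysis, reduced by PCA, and compared by Euclidean distance in the
  truncated score space.
* **Elastic (SRVF) analysis**: outlines are mapped to square-root velocity
  functions, where after unit-norm scaling every shape is a point on an
  infinite-dimensional sphere, and the distance between two shapes is the
  great-circle arc after optimizing away rotation, the starting vertex
  (closed curves) and a monotone reparametrization.

Downstream, the package provides a distance-matrix k-nearest-neighbour
classifier with stratified replicates and weighted F1 scoring, class-average
distance matrices, neighbour-joining trees, Karcher (intrinsic) and linear
mean shapes, and geodesic shape-transformation series.

## The square-root velocity representation

A planar curve $c(t)$, $t \in [0,1]$, is represented by
$$q(t) = \frac{\dot c(t)}{\sqrt{\lVert \dot c(t)\rVert}}.$$
Differentiation removes translation; dividing by the $L^2$ norm of $q$
removes scale. The remaining nuisance group — rotation $R \in SO(2)$, cyclic
start point (closed curves) and orientation-preserving reparametrizations
$\gamma$ — acts by isometries, so the shape distance is
$$d(c_1, c_2) \;=\; \arccos \Big( \max_{R,\,s,\,\gamma}\,
  \big\langle q_1,\; R\,(q_2 \circ \gamma)\sqrt{\dot\gamma}\,
  \big\rangle \Big) \in [0, \pi].$$
Unlike a PCA score distance this metric is sensitive to *where along the
curve* features occur but not to how densely they happen to be sampled —
the "bending and stretching" view of shape difference.

`srvf_transform()` estimates $\dot c$ by analytic differentiation of the
interpolating cubic spline (periodic knots for closed curves). Finite
differences were rejected: their curvature-dependent error does not cancel
between two differently parametrized copies of the same curve and shows up
directly as a spurious shape distance. `inverse_srvf()` integrates
$q\lVert q\rVert$ back to a curve; for closed curves the small closure
defect of the discrete integral is removed by subtracting the linear drift.

## How the optimization works

The maximization over $(R, s, \gamma)$ in `align_closed()` is organized in
stages, each of which only ever *improves* the normalized inner product:

1. **Seed search.** Every `seed_stride`-th start vertex of the second curve
   is a candidate (optionally pre-screened by a cheap rotation-only score
   when `top > 0`). For each candidate, rotation (closed-form 2-D orthogonal
   Procrustes) and reparametrization are alternated `rot_iters` times, the
   reparametrization coming from dynamic programming over a monotone
   lattice with slope moves $\{(a,b): 1 \le a,b \le 3,\ \gcd(a,b)=1\}$ —
   local warp slopes between 1/3 and 3, which bounds pinching.
2. **Multiscale refinement.** The DP path is quantized to lattice slopes;
   `cpp_refine_gamma` runs coarse-to-fine block moves (each coarse node is
   golden-section line-searched with its window interpolated linearly),
   then per-node polish. The objective is the *normalized* inner product
   $\langle q_1, \tilde q_2\rangle / \lVert \tilde q_2 \rVert$: the
   discrete warp does not preserve the norm exactly, and optimizing the
   unnormalized product visibly biases $\gamma$.
3. **Continuous start point.** An integer seed plus an endpoint-pinned
   $\gamma$ cannot represent a warp whose optimal cyclic offset falls
   between vertices. Candidate sub-vertex offsets are therefore re-matched
   explicitly, and a golden-section search polishes the offset.
4. **Banded micro-DP.** Finally, every node position may move within a
   shrinking band (radius 0.5, 0.2, 0.08 vertices); the best monotone
   offset path with equal first/last offset is found exactly by a small DP,
   maximizing a Dinkelbach linearization of the normalized inner product.
   Unlike coordinate descent this step is globally optimal within the band
   and does not stall on correlated node moves.

All refinement stages keep local warp slopes inside [1/4, 4]. This is not
cosmetic: without the bound the normalized objective can be gamed by
pinching ($\dot\gamma \to 0$), which deletes mismatched features from
the second curve instead of matching them. The bound also delimits the
method's operating envelope — pairs whose optimal correspondence needs
more extreme slopes are matched against the nearest admissible warp, and
their distances carry a correspondingly larger optimization error.

The depth of stages 2–3 scales with the `refine` argument: `refine >= 5`
(the single-pair default) runs the full offset-candidate sweep and eight
polish rounds; smaller values, used by the pairwise-matrix driver where
thousands of alignments are needed, skip the explicit offset candidates —
the micro-DP band of half a vertex covers the same offsets at a fraction of
the cost. On reference synthetic data (see below), a full-nuisance copy of
a shape — rotated, scaled, translated, start-shifted and smoothly
reparametrized — sits at distance below $10^{-2}$ from its original, with
self-distances at numerical zero.

Open curves (`align_open()`) need no seed search. Endpoints are pinned by
default — this is the landmark-constrained mode, where the two curve ends
are homologous points (e.g. shell apices) — and rotation is *not* searched:
with fixed, ordered endpoints the orientation carries information.
The free-endpoint variant (`fix_endpoints = FALSE`) lets the match start
and end anywhere on the second curve.

## Geodesics, means, transformation series

Because aligned shapes live on a sphere, the geodesic between them is the
great circle
$q(\tau) = [\sin((1-\tau)\theta) q_1 + \sin(\tau\theta) q_2^*]/\sin\theta$.
Three details make the discrete version behave:

* The aligned representative $q_2^*$ is built at the *outline* level — the
  second curve's spline is resampled at the matched positions and
  re-transformed — because warping in q-space does not preserve closure
  exactly, and the drift then distorts the intermediate shapes.
* Closed intermediates are projected back onto the closure constraint
  $\int q\lVert q\rVert\,dt = 0$ by a few Newton steps before
  integration.
* Each step is reparametrized so that its vertex distribution interpolates
  between the two endpoint parametrizations (the shape itself is
  untouched). Without this, every step inherits the first curve's
  parametrization, and measuring a step against the second endpoint
  carries the full warp — on typical class-template pairs that inflates
  the midpoint's distance asymmetry from about 1% to about 30%.

The `path_energy()` of a series is the sum of consecutive elastic
distances, each re-optimized from scratch; because every measurement
overestimates its own true distance by a slightly different amount, the
sum lands within a few percent of the endpoint measurement on either side
(the tests check the two-sided 5% band).

`karcher_mean()` computes the intrinsic mean by the standard fixed-point
iteration: align every curve to the current estimate (at the outline
level, as above), average the log-map (shooting) vectors, move along the
exponential map with step size 0.5, stop when the update norm falls below
`tol` ($10^{-4}$ by default, at most 50 iterations). It is initialized at
the normalized extrinsic average of the curves aligned to the first one —
averaging unaligned SRVFs would start from a meaningless point. For a
mild pair (the axis-aligned ellipse fixture the tests use), the
two-shape mean coincides with the $\kappa = 2$ geodesic midpoint to a few
times $10^{-3}$; for random class templates the two constructions agree to
a few times $10^{-2}$, and the mean remains equidistant from both inputs
to about 1% — the defining property of a Fréchet mean.

`symmetric_transform()` handles mirror-symmetric endpoints (such as
symmetrized vessel outlines): the right halves are transformed into each
other as open curves with pinned endpoints and each intermediate half is
reflected and re-attached, so every step of the series is exactly
symmetric.

## Outline preparation

`binarize()` thresholds a greyscale image (Otsu's method by default);
`extract_contour()` runs marching squares at level 0.5 and keeps the closed
iso-contour with the greatest enclosed area — the sensible rule when every
image shows a single object. `resample_arclength()` fits a parametric
cubic spline (periodic for closed outlines, natural with pinned endpoints
for open ones) and samples it at equal arc-length spacing; "equally spaced
points" is interpreted along the fitted spline, not in the original
parameter, and the chord-length coefficient of variation of the output is
below 1%. `procrustes_align()` is a standard generalized Procrustes:
centre, scale to unit centroid size, and iterate orthogonal fits to the
running mean until it moves less than $10^{-8}$. Reflections are excluded
by default because biological left/right matters; `allow_reflection = TRUE`
restores the full similarity group. `symmetrize_vertical()` splits a closed
outline at its extremal-y vertices, keeps the side of shorter arc length
and reflects it about the vertical centroid axis.

Closed outlines are stored canonically — counter-clockwise, starting at
the vertex of maximum y (ties to minimum x) — so that file round-trips and
seed searches are reproducible.

## The synthetic data generator

Real outline datasets (vases, leaves, shells) are large image collections;
for testing, `make_families()` + `make_dataset()` emulate their statistical
structure with star-shaped Fourier templates
$r(\theta) = 1 + \sum_j a_j \cos j\theta + b_j \sin j\theta$:

* **Between-class structure**: each class is a template whose amplitudes
  are `separation` times fixed standard-normal draws, damped as $1/j$.
  A fixed seed therefore gives templates that deform continuously — and
  between-class distances that grow monotonically — as `separation`
  increases. Templates are kept star-shaped (radius bounded away from
  zero), which guarantees simple closed curves and analytic area checks.
* **Within-class variation**: a smooth radial perturbation field (six
  random harmonics scaled so the field's standard deviation equals
  `vertex_noise_sd`). Smoothness matters: independent per-vertex noise
  would be amplified by the derivative inside the SRVF and would drown the
  class signal in a way real digitized outlines do not.
* **Nuisance transforms**: rotation, scale, translation, a random cyclic
  start vertex, and a smooth monotone warp
  $\theta \mapsto \theta + \sum_{j=1}^3 e_j \sin(j\theta + \phi_j)$ with
  $\sum_j j\,e_j$ equal to `reparam_strength` (capped at 0.9), which keeps
  the warp strictly monotone by construction.

The reference study conditions — used by the tests and the acceptance
script — are `separation = 0.3`, `vertex_noise_sd = 0.03`,
`reparam_strength = 0.15`, full rotation, scale in [0.75, 1.35] and random
start vertices, with 5 classes of 30 outlines of 100 points each (seed 11).
Outline resolutions of 100–200 points bracket what digitized outline
datasets typically use. What these synthetic data do *not* emulate:
pixel-level digitization noise, jagged high-frequency structure (shells'
spines, serrated leaf margins), non-star-shaped outlines, or unbalanced
classes — so passing tests show the machinery is correct and the methods'
*relative* behaviour is reproduced, not that any particular real-world
accuracy carries over.

`rasterize_outline()` (even-odd scanline fill, no anti-aliasing) closes the
loop: it produces binary masks from which `extract_contour()` must recover
the outline to elastic distance below 0.05 at 400-pixel resolution.

## Classification protocol

`stratified_splits()` draws repeated stratified holdouts (largest-remainder
allocation of per-class training counts under a global fraction, or
explicit per-class counts). `knn_predict()` is a distance-matrix k-NN with
two deterministic tie rules the package fixes explicitly: a vote tie goes
to the tied class owning the single nearest neighbour, and distance ties at
the k-th neighbour resolve by object order. `knn_evaluate()` reports
per-replicate weighted F1 (support-weighted harmonic mean of precision and
recall), the normal-approximation 95% interval
$\bar F \pm 1.96\, s/\sqrt{R}$, and a pooled confusion matrix; `tune_k()`
scans a k grid (3–12 by default) and breaks ties toward smaller k.
`partition_f1()` scores *unlabeled* partitions — the format in which a
human expert sorts outlines into folders — by the one-to-one
group-to-class assignment maximizing weighted F1, solved exactly as a
linear assignment problem. The assignment rule is a documented choice;
per-pair contributions are $\tfrac{|c|}{n}\cdot\tfrac{2|g \cap c|}{|g|+|c|}$,
which makes the objective assignment-separable.

On the reference dataset the closed-SRVF k-NN attains mean weighted F1
above 0.9 over 20 stratified replicates and strictly outranks eigenshapes
under start-shift and reparametrization nuisance — eigenshapes presuppose
point correspondence, which a shifted start vertex destroys, while the
elastic matcher recovers it. Both numbers are computed, not asserted:
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` run the full
pipeline each time.

## Trees over class averages

`class_mean_distances()` condenses an object distance matrix to class
averages (the diagonal holds mean within-class distances, reported but
excluded from correlations and trees). `metric_correlation()` is Pearson's
r over the off-diagonal upper triangle; `neighbour_joining()` wraps the
standard NJ agglomeration (exact on additive matrices) with negative branch
estimates clamped to zero and the deficit moved to the sibling edge so path
lengths through the parent are preserved. `monophyly_check()` asks, for a
rooted tree and a tip-to-family map, whether some edge separates exactly
each family's tips. With six classes drawn from three nested template
families and landmark-consistent (shared start vertex) open-curve SRVF
distances, NJ recovers all three families as monophyletic.

## Numerical choices and edge cases

* Inner products use the trapezoidal rule (rectangle rule on the period for
  closed curves); the arccos argument is clamped to $[-1, 1]$.
* Curve resampling to the SRVF grid interpolates the vertex polygon with a
  cubic spline in its stored parameter: linear interpolation adds curvature
  kinks that register as spurious distance between differently gridded
  copies of one curve.
* `q` interpolation inside the matcher is Catmull–Rom cubic: linear
  interpolation systematically shortens a curving `q` and biases the
  matching objective downward.
* Degenerate inputs error early: outlines need 3+ distinct finite points,
  zero-derivative curves are rejected by the transform, empty foregrounds
  by `binarize()`, self-intersecting polygons by `rasterize_outline()`.
* The distance is not symmetrized by default. For near-copies the two
  directions agree to well below $10^{-3}$; for well-separated shapes the
  direction asymmetry reflects optimizer suboptimality on strongly warped
  pairs and can reach a few times $10^{-2}$. `symmetrize = TRUE` averages
  the two directions exactly.
* Identical shapes: the identity warp lies on the DP lattice and rotation
  Procrustes returns the identity, so self-distance is exactly 0 up to
  floating point.

Problem sizes used by the test and acceptance runs: invariance checks on 50
shapes at $M = 100$; the classification benchmark at $M = 60$ over the
$150 \times 150$ matrix (11,175 alignments) with `top = 6` seed
preselection and `refine = 1` (the class margins are an order of magnitude
above the alignment error, so light settings leave the F1 protocol
unchanged); tree recovery on 48 open curves at $M = 100$. These sizes make
the full suite reproducible on a single CPU in tens of minutes while
leaving the methods' behaviour unchanged at larger settings.

## Known limitations

* The reparametrization search is a discrete approximation; distances carry
  an optimization error around $5\times10^{-3}$ at $M = 100$ (against
  $\sim10^{-3}$ for the representation itself), which is negligible for
  classification but visible if you study near-identical shapes.
* Closed-curve geodesic intermediates use drift-removal projection, not
  full path straightening; for very distant shape pairs intermediates can
  drift slightly off the closed-curve manifold before re-projection.
* The generator produces star-shaped outlines only; methods accept any
  simple outline, but the test evidence is for the star-shaped family.
* No reflection search in the elastic matcher (mirror images are distinct
  shapes by design); Procrustes alignment exposes `allow_reflection`.

## A worked example

```{r example, eval = FALSE}
fams <- make_families(3, separation = 0.3, seed = 1)
ds <- make_dataset(fams, nuisance_spec(), n_per_class = 10, seed = 2)
rs <- lapply(ds$outlines, resample_arclength, n_points = 100)
D <- elastic_distances(rs, mode = "closed", grid_size = 60)
plan <- stratified_splits(ds$labels, 0.67, n_replicates = 20, seed = 3)
ev <- knn_evaluate(D, ds$labels, plan, k = tune_k(D, ds$labels, plan)$best_k)
print(ev)
summary(ev)
```
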