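---
title: "Decomposing flexible-appendage movements into kinematic primitives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing flexible-appendage movements into kinematic primitives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinprims)
```

## The model

A boneless appendage such as an octopus arm has no joints to track.  What a
tracking pipeline delivers instead is, per video frame, an ordered list of 3D
points along the arm's midline -- the *virtual backbone*.  kinprims analyzes
sequences of such backbone curves by moving to an intrinsic representation:
each frame is described by its curvature profile $\kappa(s)$ and torsion
profile $\tau(s)$ over the normalized arm index $s \in [0,1]$ (0 = base,
1 = tip), and a whole movement becomes a pair of *kinematic surfaces*
$\kappa(s,t)$ and $\tau(s,t)$ over arm index and normalized time.  Curvature
and torsion determine a space curve up to a rigid motion, so the surfaces
inherit exact invariance under rotation and translation of the animal.

Because curvature and torsion vary smoothly along the arm and in time, a
surface is well approximated by a small weighted sum of bivariate Gaussians,

$$z(s,t) \;=\; \sum_i w_i\, g[\mu_i, \Sigma_i](s,t),$$

with $g$ the bivariate normal density.  Each Gaussian is a localized episode
-- a bend (or twist) on a particular arm section during a particular time
interval -- and is the package's *kinematic unit* (motion primitive).  A
travelling bend appears as a Gaussian whose principal axis is oblique to the
arm-index axis; a stationary proximal bend is axis-aligned.  Pooling the
Gaussians of many movements, clustering them, and reading each cluster
centroid as a representative Gaussian yields a small vocabulary of units;
every movement is then a nonnegative weight vector over that shared
vocabulary, and clustering the weight vectors yields *movement prototypes*.
Finally, any combination of units can be rendered back into 3D by
integrating the Frenet–Serret equations per time slice, which closes the
loop: $n_C$ curvature units and $n_T$ torsion units span
$n_C \cdot (n_T + 1)$ distinct behaviors (torsion without curvature leaves a
straight arm unchanged).

## Geometry: estimators and numerical choices

**Resampling.** Each frame is resampled to $n$ points (default 100) at equal
arclength along the piecewise-linear input, and the arm length is normalized
to 1, so all profiles are dimensionless and comparable across frames and
animals.

**Smoothing.** Each coordinate is smoothed by a cubic smoothing spline
minimizing $p\sum_j |y_j - f(x_j)|^2 + (1-p)\int |f''|^2$.  The data site is
the *sample index* ($x_j = j$): on that scale the natural interpolation
regime sits at $p \to 1$ with a usable smoothing range around $p \approx
0.9$–$0.999$, and the default $p = 0.99$ mildly denoises tracked points
while distorting clean closed-form curves (circles, helices) by under 5%.
Had the sites been placed on the normalized arclength $[0,1]$ instead, the
same $p = 0.99$ would sit deep in the oversmoothing regime (the penalty term
scales like $h^{-3}$ with site spacing $h$) and flatten every curve; the
index convention is what makes a fixed default meaningful.  Because one
linear smoother acts on all three coordinates, smoothing commutes with rigid
motions and scalings.  The same spline machinery resamples the time axis
from $m$ frames to the $n$-row grid.

**Curvature** at an interior sample is the inverse circumradius of the
triangle through three successive points, computed as $4\Delta/(abc)$ with
$\Delta$ from a cross product.  Collinear triples return 0 (the analytic
limit for straight sections).  **Torsion** at a sample is the angle between
the osculating planes of the two adjacent sample triangles divided by the
span $d(B,D)$.  The angle is taken between *undirected* planes (absolute
value of the normals' dot product): at a curvature inflection of an exactly
planar curve the oriented normals flip sign, and the literal signed angle
would report $\pi/d$ where the true torsion is 0.  The representation is
unsigned throughout -- handedness of a twist is not encoded, and synthesis
fixes a right-handed convention.  Both estimators recover the closed forms
for circles ($\kappa = 1/r$) and circular helices
($\kappa = a/(a^2+b^2)$, $\tau = b/(a^2+b^2)$) to well under 1% at $n = 100$.

Profile endpoints where the stencils are undefined (two samples for
$\kappa$, four for $\tau$) are replicated from the nearest interior value so
surfaces stay $n \times n$.  The distal 10% of the arm (configurable) is
flat-filled from the last retained column: tracked tip values are noisy
outliers best analyzed separately.  A triangle whose height falls below
$10^{-12}$ of its side lengths is treated as degenerate (torsion 0): beyond
that the normal direction is floating-point noise.  This conditioning also
dictates a testing choice: exact ($<10^{-9}$) rigid-invariance checks use a
fixture movement whose curvature is bounded away from zero, because on
near-straight sections the torsion stencil amplifies coordinate round-off
(a large translation costs the estimator about $\varepsilon\,c/(\kappa
h^2)$ in angle).

**Bend point and elongation.** The bend point of a frame is the arm index of
its curvature maximum (most proximal maximum on ties; curves whose profile
never exceeds a $10^{-3}$ floor have no bend), and the elongation ratio of a
frame is the arclength fraction from base to bend -- the quantity that grows
as the proximal section elongates during an extension.

## Decomposition: weighted EM and BIC

A surface is a function, not a sample, so the package defines the mixture
fit as *mass-weighted* EM: each positive grid cell is an observation at its
$(s,t)$ coordinates with weight proportional to its value (weights scaled to
sum to the number of positive cells, which keeps the weighted log-likelihood
on the scale of an ordinary likelihood).  Fitted mixture proportions are
rescaled by the total surface mass $Z$ (grid sum x cell area), so
$\sum_i w_i = Z$ exactly and the rendered mixture approximates the surface
in value units.  Negative cells (possible numerical noise) are clipped to 0.

The number of components minimizes
$\mathrm{BIC} = -2L + d\log(n_\mathrm{obs})$ with $d = 6k - 1$ free
parameters ($k$ weights constrained to a fixed total, $2k$ means, $3k$
covariance entries) and $n_\mathrm{obs}$ the number of positive cells --
both choices are the package's, since "observations" of a surface admit no
canonical count.  Each candidate $k$ gets `n_starts` EM runs (default 5)
initialized by k-means++ seeding on mass-weighted resampled points; a
$10^{-6}$ eigenvalue floor keeps covariances from collapsing onto single
cells; convergence is a $10^{-8}$ relative log-likelihood change, capped at
500 iterations.  Ties in BIC break toward smaller $k$.  On the planted
4-Gaussian fixture surface, BIC selects $k=4$ in 10 of 10 seeds and recovers
centers within 0.011 normalized units.

One caveat found while validating: EM optimizes likelihood, not squared
error, so the reconstruction rmse of best-of-starts fits is not strictly
non-increasing in $k$ (it can tick up by a fraction of a percent past the
true $k$); every multi-component fit does reconstruct at least as well as
the best single Gaussian.

## Clustering: averaged per-feature distance and the gap statistic

Units are compared feature by feature: Euclidean distance between centers,
absolute differences of shape (eigenvalue ratio), size (geometric-mean
standard deviation), orientation, and weight, each divided by that feature's
standard deviation over the whole unit sample (averaging raw heterogeneous
distances would let whichever feature has the largest units dominate), and
the unit distance is the unweighted mean of the enabled components -- a
metric, verified by property test.  Two subsets are wired in: the default
`{center, shape, weight}` (the configuration behind the reported extension
clusterings) and `{center, shape, size, orientation}` as the full geometric
alternative.

The k-means variant runs a batch (Lloyd) phase followed by single-point
reassignment passes that accept any move lowering the summed
point-to-centroid distance (implemented in compiled code; emptied clusters
re-seed at the farthest point).  Cluster centroids map back to Gaussians by
element-wise parameter averaging -- a convex combination of SPD matrices, so
always a valid Gaussian -- with a medoid mode available when a
representative *observed* unit is preferred.

The number of clusters is the minimal $k$ at a local maximum of
$\mathrm{Gap}(k) = \frac{1}{B}\sum_b \log W^*_{kb} - \log W_k$, with $B$
(default 50) reference sets drawn uniformly over the per-feature bounding
box of the sample.  Two definitional choices matter here.  First, $W_k$ is
the within-cluster sum of *squared* point-to-centroid distances (the form in
the gap statistic's source literature), while the clustering itself
minimizes the summed unsquared distance; with the unsquared $W$ the gap
curve of well-separated data creeps upward monotonically and the literal
local-maximum rule (which this package implements, rather than the
one-standard-error rule) never fires.  Second, the local-maximum rule needs
clusters whose within-spread is non-negligible and roughly balanced across
features after normalization: for near-point-mass or strongly anisotropic
clusters, $\log W_k$ of the data keeps falling as fast under splits as the
uniform reference's does, the gap plateaus, and the rule overshoots.  The
planted-blob generator (`sim_unit_blobs()`) therefore separates every
feature by about 8 within-cluster standard deviations with comparable
relative spread per feature; under those conditions recovery is 20/20 seeds
for $k=3$ and 10/10 for a single blob.

## Classification and synthesis

Movement weights over the *shared* vocabulary are obtained by nonnegative
least squares of each surface on the frozen centroid densities (means and
covariances fixed), concatenated as $[\{w_i^C\}, \{w_j^T\}]$; surfaces built
exactly on the basis are recovered to $10^{-6}$.  An alternative "pool" mode
sums each movement's own fitted Gaussian weights onto their nearest
centroids -- coarser, kept for comparison.  Movement vectors are clustered
by plain-Euclidean k-means (the weights share units; no re-normalization),
with the gap statistic available for choosing the number of sub-groups;
cluster means are the prototype weight patterns and render to prototype
surface pairs through the mixture equation.  Note the plateau caveat above
applies here too: in noiseless synthetic repertoires the weight clusters are
nearly point masses and gap-based selection overshoots, so recovery
experiments cluster at the planted group count and the auto-selection path
is exercised where within-group spread is realistic.

Synthesis integrates $r' = T$, $T' = \kappa N$, $N' = -\kappa T + \tau B$,
$B' = -\tau N$ per time slice with a fourth-order Runge–Kutta step equal to
the arclength spacing and Gram–Schmidt re-orthonormalization of the frame at
every step; the base position and frame stay fixed across frames
(configurable).  Reconstructed arclength is exact to well under 0.1%, and a
synthesize-extract round trip on smooth planted surfaces agrees to about
0.05% of the peak value -- *provided torsion lives where curvature does*: a
straight arm section carries no osculating plane, so torsion planted outside
the curvature support is invisible to any extractor (the same fact that
makes a torsion unit on its own meaningless).

## The synthetic-data generator

`sim_movement()` evaluates planted units on an $m \times n$ grid, optionally
adds Gaussian surface noise (clipped at zero), and renders each time slice
into a 3D backbone curve of unit length; `sim_movement_set()` builds whole
repertoires from group weight patterns over a shared vocabulary
(`sim_default_repertoire()` provides a three-pattern extension-like
reference configuration with three curvature and three torsion units).
Noise is placed on the surfaces by default -- that is where the smoothness
assumptions live -- with point-level jitter available by smoothing noisy
tracked curves directly.  Weight patterns are reproduced exactly by default
(`weight_jitter` adds multiplicative variation when realism calls for it).
Everything is bit-reproducible given a seed.

What the generator does *not* emulate: tracking dropouts and outliers,
correlated (non-white) measurement noise, arm elongation during a movement
(generated frames all have unit length), signed torsion, and any
biomechanics (muscle activations, drag).  Passing the plant-and-recover
suite therefore shows the chain of estimators is faithful on data satisfying
the model's smoothness assumptions, not that real tracked arms satisfy them.

## Problem sizes used by the test and acceptance suites

Grids of $100 \times 100$ for decomposition and round-trip checks (with
40-frame movements), 60 units in 3 planted clusters with $B = 50$ and 20
replicates for gap recovery, 10 restarts (3 EM starts each, $k \le 6$) for
BIC selection, 30 movements (3 groups x 10) at 10%-of-peak surface noise
for end-to-end prototype recovery, and 100 random rigid motions at
$40 \times 40$/6 frames for the invariance check.  The whole suite runs in a
few minutes on one core; all sizes are set in the tests and scale up
directly.

## Known limitations

* Torsion is unsigned; mirror-image twists are identical in this
  representation, and synthesis fixes one chirality.
* Torsion is undefined (and numerically ill-conditioned) on straight
  sections; values there are floor-replicated or zeroed, and exact
  invariance guarantees apply only where curvature is bounded away from 0.
* The literal local-maximum gap rule needs genuinely dispersed clusters; on
  near-degenerate cluster structure it overshoots (see the clustering
  section for the analysis and the mitigations).
* BIC's observation count for a surface is a modeling convention; absolute
  BIC values are not comparable across grid resolutions.
* Tip behavior is excluded and flat-filled, not modeled.
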