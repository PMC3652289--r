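---
title: "Methods: fuzzy active-contour segmentation and mixture-model refinement of pulmonary nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy active-contour segmentation and mixture-model refinement of pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulecad)
```

# The problem

Pulmonary nodules in chest CT come in configurations that defeat simple
segmentation: nonsolid and part-solid ground-glass (GGO) nodules have faint
contrast, fuzzy margins and intensity inhomogeneity; juxtavascular nodules
are attached to vessels of essentially the same intensity, so the boundary
between nodule and vessel is not an intensity edge at all. `nodulecad`
implements a detection chain for these cases: a fuzzy membership field built
from the volumetric shape index, a fuzzy integrated active contour model
(FIACM) for candidate segmentation, a hybrid parametric mixture model (PMM)
that carves attached vessels off juxtavascular candidates, a 21-descriptor
feature catalogue, and a knowledge gate followed by a cost-sensitive SVM for
false-positive reduction. A synthetic phantom generator supplies ground
truth for every stage.

# Fuzzy membership from the volumetric shape index

Principal curvatures $k_1 \ge k_2$ of the iso-intensity surfaces are
computed from the Gaussian-smoothed gradient and Hessian. The sign
convention is fixed so bright convex structures carry negative curvatures;
it is the unique convention under which the shape index

$$SI(p) = \frac12 - \frac{1}{\pi}\arctan\frac{k_1(p)+k_2(p)}{k_1(p)-k_2(p)}$$

maps bright spheres to 1 and bright tubes to 0.75. Voxels with vanishing
gradient have no iso-surface and are flagged undefined (they enter later
stages with the neutral value 0.5) rather than propagating NaNs.

Per-voxel samples $(x, y, z, SI, I)$ — position, shape index, intensity —
are standardized feature-wise and clustered by fuzzy c-means (fuzzifier
$m = 2$, $c = 2$ clusters by default; centres drawn by a seeded
k-means++-style rule). The *nodule cluster* is the one whose centre has the
highest combined standardized shape index and intensity; its membership
column, rasterized over the grid, is the membership map $u \in [0,1]$.
Grayscale morphological opening (cube element, radius 1 voxel) removes
speckle in the fuzzy domain. On juxtavascular phantoms with equal nodule
and vessel intensities, the median membership over nodule voxels exceeds
0.5 while the median over vessel voxels stays below 0.5 — position and
shape index carry the separation that intensity cannot.

Which voxels are sampled is a modelling choice with consequences. Sampling
everything above a low contrast threshold (default: 25% of the intensity
range above the minimum) makes the two clusters "structure vs. faint
surround", which is the right field to drive segmentation; sampling only
structure-level voxels makes them "nodule-like vs. vessel-like", which is
the right field for vessel separation. The pipeline uses the former
globally; the refinement consumes the same global map, whose values at
structure voxels still separate sphere from tube.

# The fuzzy integrated active contour model

The level set $\phi$ (interior $\Omega_1 = \{\phi > 0\}$) evolves under an
edge term and membership-weighted region-scalable fitting terms. The local
fitting values

$$f_1(x) = \frac{B_\sigma * [H(\phi)\, I]}{B_\sigma * H(\phi)}, \qquad
  f_2(x) = \frac{B_\sigma * [(1 - H(\phi))\, I]}{B_\sigma * (1 - H(\phi))}$$

are kernel-weighted interior/exterior intensity means; where a window holds
no interior (or exterior) mass the unmasked local mean is substituted, which
avoids 0/0 far from the interface. The kernel scale is controlled by the
mean membership: $\sigma = \sigma_0 (0.5 + \bar u)$, clamped to
$[0.5, 1.5]\,\sigma_0$, so confident nodule regions use wider windows. The
smoothed Heaviside/Dirac pair is the global-support arctan form
$H_\epsilon(z) = \tfrac12(1 + \tfrac{2}{\pi}\arctan(z/\epsilon))$,
$\delta_\epsilon(z) = \epsilon / (\pi(\epsilon^2 + z^2))$ with
$\epsilon = 1.5$ grid units; $\phi$ is clipped to $[-10, 10]$ each step
instead of being reinitialized to a signed distance.

## Membership orientation in the region force

With a *fixed* membership field, weighting the interior residual by $u^m$
and the exterior by $(1-u)^m$ has a degenerate regime: wherever the two
fitted means coincide (any locally homogeneous region) the force reduces to
the sign of $(1-u)^m - u^m$, which pushes *high*-membership voxels out of
the interior and floods the interior with background. On phantoms this is
not a subtlety — the contour converges to the complement of the nodule.
This package therefore orients the weights the other way around (interior
residual damped by $(1-u)^m$, exterior amplified by $u^m$): where intensity
information is decisive the model behaves like region-scalable fitting, and
where it is ambiguous the fuzzy term alone pulls $u > 0.5$ voxels inside —
the behaviour the membership field is meant to deliver.

Two further consequences of a fixed membership field are handled
explicitly:

* The membership passed to the evolution is Gaussian-smoothed (1.5 mm).
  Hard 0/1 memberships leave no fuzzy band at class boundaries; the
  interface then erodes because the interior fit is contaminated exactly
  where the membership is most confident. A transition band with
  $u \approx 0.5$ restores the balanced, edge-seeking behaviour.
* The region force acts on a squared-intensity scale that varies by orders
  of magnitude across a scan. It is normalized by its 95th-percentile
  magnitude within the Dirac-active band and saturated to $[-1, 1]$, making
  the time step $\tau$ (default 1) the interface speed in grid units per
  iteration everywhere the force is decisive.

## Edge term and solver

The edge-stopping function is piecewise quadratic between two gradient
thresholds $a < b$: $g \equiv 1$ up to $a$ (homogeneous region),
$g \equiv 0$ beyond $b$ (definite edge), with two $C^1$-matched quadratic
branches between. The thresholds come from a posterior rule: a
two-component Gaussian mixture is fitted by EM to the Gaussian-gradient
magnitudes; $a$ and $b$ are the smallest magnitudes whose posterior edge
probability reaches `p_lo` (0.6) and `p_hi` (0.95), located on a dense grid
between the component means. The curvature/edge regularization
$\mu\,\delta_\epsilon(\phi)\,\mathrm{div}(g \nabla\phi / |\nabla\phi|)$ is
advanced semi-implicitly by additive operator splitting with lagged scalar
diffusivity $D = \mu\, g\, \delta_\epsilon(\phi)/|\nabla\phi|$ — one
tridiagonal (Thomas) solve per axis, vectorized across grid lines; the
transport corrections of the exact curvature term are dropped, as is
standard for AOS level-set solvers. The region force is advanced
explicitly. Convergence is declared when the mean fraction of sign-changed
voxels per iteration, measured over 10-iteration windows, falls below
`conv_tol` (default $10^{-4}$); steps are $O(\tau)$, so single-step flips
are too rare to measure convergence on.

The initial contour comes from adaptive local-mean thresholding (9-voxel
window, offset +40) with cavity filling: the cores of wide bright blobs sit
*below* their local mean and would otherwise start as holes, which a
fixed-membership model cannot refill. Candidates are 26-connected
components of the final interior, with components under `min_voxels`
(default 10) dropped.

# Hybrid mixture-model refinement of juxtavascular candidates

Candidates that are insufficiently sphere-like (volumetric quotient < 0.6
or central-slice compactness < 0.7) are suspected of carrying an attached
vessel. For each such candidate, observation vectors $v = (I, u, o)$ are
built at the voxels of its mask: intensity, membership, and the regularized
structure-tensor flow vector $o$. The structure tensor is the componentwise
Gaussian-smoothed outer product of per-voxel gradients; the flow vector is
$l_1 = \lambda_3 e_1$ with $e_1$ the eigenvector of least variation, so a
tube carries long, axis-aligned vectors while a sphere's shell carries
scattered ones. Signs are made consistent by flipping vectors with negative
inner product against a reference — the dominant eigenvector of the
vectors' second-moment matrix, since any consistent half-space reference
serves the purpose.

The observations follow a mixture of $M - 1 = 2$ multivariate Gaussians
plus a uniform outlier component of fixed density,

$$f(v \mid \theta) = \sum_{i=1}^{M-1} \alpha_i\, \phi(v \mid \mu_i, \Sigma_i)
  + \alpha_M\, p_M(v),$$

fitted by EM with closed-form weighted updates, a $10^{-4}$ weight floor
and a $10^{-6}\,\mathrm{tr}(\Sigma)/d$ ridge on collapsing covariances. The
intensity and flow columns are standardized; the membership column keeps
its $[0,1]$ scale so component means remain interpretable. The uniform
density defaults to the reciprocal volume of the observation bounding box —
in the 5-D standardized space a constant like $1/\pi$ is far above typical
Gaussian densities and absorbs entire structures instead of outliers.

Assignment and removal follow a conservative rule: the Gaussian with the
highest mean membership is the nodule component; Gaussians with mean
membership below 0.5 are vessel components; a voxel is removed only when
its best *structure* component is a vessel component **and** its own
membership is below 0.5, so high-membership nodule-shell voxels are never
sacrificed. The fit-and-remove step runs twice — the refit on the remainder
catches the attachment collar whose flow statistics were masked by the full
vessel limb. The refined mask is the largest connected component of what
remains, always a subset of the original (refinement never grows a
candidate, and voxels outside the candidate's bounding box are untouched);
if removal would empty the mask the original is kept and the candidate
flagged `refinement_failed`. When no vessel-like component arises — an
isolated sphere forced through refinement — nothing is removed.

# Features, gate and cost-sensitive SVM

Each candidate is described by exactly 21 descriptors: 4 intensity
(mean/SD in the largest-area axial slice and in 3-D), 1 position (distance
of the 3-D centroid from the volume centre — a single scalar so the
catalogue totals 21), 12 shape and 4 texture. The 2-D shape set runs on
the largest in-slice component: area, chain-code perimeter
($L = n_e + \sqrt2\,n_o$), moment-based diameter and ellipticity,
inscribed/circumscribed circularity, slenderness, rectangle degree,
compactness and convex-hull concavity ratio. Compactness uses the pixel
*region* contour — the chain-code path plus the $\pi h$ half-pixel offset
of a closed convex boundary — because the raw centre path makes digital
discs score well above 1. In 3-D: volume, the long axis (maximal boundary
extent plus half a voxel) and the volumetric quotient — volume over the
circumsphere volume — which is near 1 for spheres and far below for tubes.
Texture is a 32-level gray-level co-occurrence matrix, symmetrized,
normalized per offset and averaged over the four distance-1 directions:
energy, contrast, entropy (natural log) and inverse difference moment.

False-positive reduction is two-staged. A knowledge gate of half-space
tests on (volume, volumetric quotient, 3-D mean, 3-D SD) removes easily
dismissible objects; the defaults accept volumes between 3 and 30 mm
sphere equivalents with quotient at least 0.25. Survivors go to a
soft-margin SVM with RBF kernel and class-dependent penalties
$C_+ = C_- \cdot n_-/n_+$ (the imbalance convention; only $C_-$ is
searched). Features are min-max normalized to $[0,1]$ on the training set.
$(C_-, \gamma)$ are chosen by stratified k-fold cross-validation on the
rank-statistic AUC of pooled out-of-fold decision values, ties broken by
the smallest $C_-$ then the smallest $\gamma$; grids default to powers of
two ($C_- \in 2^{-1..3}$, $\gamma \in 2^{-3..3}$).

# The phantom generator

Phantoms are the study conditions, not a tuning dial. A scan is a
$44 \times 44 \times 36$ grid at 1 mm spacing containing one nodule —
solid, part-solid (solid core of half the radius plus faint halo), nonsolid
(GGO), or juxtavascular (solid nodule sharing its intensity with a tangent
vessel) — plus a background vessel, with additive Gaussian noise
($\sigma = 25$ intensity units) and a multiplicative bias field (three
random low-frequency cosine modes, amplitude 5%, mean 1). Contrast levels:
background $-900$, solid structures and vessels $+400$, nonsolid $+120$ —
GGO nodules are faint against parenchyma while solid structures are not.
Nodule radii are drawn from 4–7 mm (5–8 mm for nonsolid), vessel radii from
1.5–2.5 mm. Noise at $\sigma = 25$ against contrasts of 1000–1300 units
matches the comfortable end of thin-slice CT; the 5% bias field produces
the slow intensity drift the region-scalable fitting exists to tolerate.

Intensity composes by maximum over structure contributions, so an
attachment region keeps the shared nodule/vessel intensity instead of
doubling. Labels (0 background, 1 nodule, 2 vessel, 3 attachment zone) are
assigned by partial occupancy under $2\times$ supersampling, nodules
winning ties; the ground-truth extent of a soft-edged structure is its
full-width-at-half-maximum support (radius plus $\sqrt{2\ln 2}$ times the
edge softness), i.e. the half-contrast boundary a segmentation of a fuzzy
object should recover. Everything is deterministic given the seed.

What the phantoms do *not* emulate: lung anatomy (airways, fissures,
pleura), juxtapleural nodules, branching vessel trees, CT reconstruction
noise texture (noise is white Gaussian, not correlated), and scanner
calibration. Passing phantom suites therefore demonstrates that the
algorithms do what their models claim under controlled conditions — not
clinical performance.

# Desk-scale study sizes and numerical choices

The bundled evaluation runs 10 phantom scans (cycling solid, juxtavascular,
nonsolid, part-solid) against a classifier trained on 30 positive and 100
negative phantom candidates; negatives are vessel fragments and noise blobs
segmented by the same adaptive threshold as the positives so their masks
carry realistic segmentation noise. These sizes keep a full run in a few
minutes on one CPU while leaving each stochastic criterion enough trials to
be meaningful. Further numerics: FIACM runs at most 150 iterations in the
pipeline (300 in isolation tests); the EM tolerance is $10^{-6}$ relative
log-likelihood; fuzzy c-means uses tolerance $10^{-6}$ and at most 200
iterations; assignment ties break to the lowest component index; the
detection match requires a candidate to cover 25% of a truth nodule and is
greedy one-to-one by overlap.

# Known limitations

* The membership-weight orientation in the evolution is this package's
  reading; with a fixed membership field the literal orientation printed in
  the source model is unstable (see above), and no reading reproduces both.
* DICOM series input is not supported (no DICOM reader is available to the
  package); NIfTI and MetaImage are.
* The refinement assumes one dominant vessel attachment; a nodule threaded
  by several vessels of distinct directions would need more structure
  components than the fixed $M = 3$.
* Juxtapleural nodules and benign/malignant differentiation are out of
  scope.
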