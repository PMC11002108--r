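---
title: "Left atrial motion tracking and strain: models, parameters and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left atrial motion tracking and strain: models, parameters and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lastrain` estimates three-dimensional left atrial (LA) endocardial motion
from retrospectively gated cardiac CT (RGCT) and derives global and regional
area and fibre reservoir strains.  This vignette is the package's own account
of the underlying models, the parameters that matter, the numerical choices
made where the design was genuinely open, and what the synthetic verification
machinery does and does not demonstrate.

## The motion model

LA motion over one cardiac cycle is represented as a cyclic spatiotemporal
free-form deformation: a dense displacement field

$$u(x, t) \;=\; \sum_{\ell} \sum_{i} \sum_{k}
  c^{(\ell)}_{ik}\, B_i^{(\ell)}(x)\, \tilde B_k(t),$$

where $B_i^{(\ell)}$ are tensor-product cubic B-splines on a regular spatial
control-point grid at resolution level $\ell$, and $\tilde B_k$ are cubic
B-splines on a *periodic* temporal knot sequence, so that $u$ is cyclic with
the cardiac period by construction.  The evaluation at $t = 0$ (the
end-diastolic reference frame, coinciding with the R-wave) is subtracted,
enforcing $u(x, 0) = 0$ exactly.  Two levels are used by default, with
control-point spacings of 1/4 and 1/8 of the image extent and four temporal
control points; all of this is configurable through `registration_config()`
and `bspline_lattice()`.

All later frames are registered to the ED frame *simultaneously*, by
minimising

$$E(c) \;=\; \sum_{t=1}^{F-1} \big[-\mathrm{NMI}\!\big(I_0(x - u(x,t)),\,
I_t\big)\big] \;+\; \lambda_{BE}\,\mathcal{B}(c) \;+\;
\lambda_{SW}\,\mathcal{S}(c),$$

with NMI the normalised mutual information $(H_A + H_B)/H_{AB}$,
$\mathcal{B}$ a bending-energy penalty (squared second spatial differences of
the control-point grids, per temporal control point), and $\mathcal{S}$ a
smoothed L1 norm $\sum_j \sqrt{c_j^2 + \varepsilon^2} - \varepsilon$
(with $\varepsilon = 0.01$ mm) that encourages sparsely activated control
points.  Optimisation is quasi-Newton (L-BFGS) with the analytic gradient,
coarse-to-fine over levels.

**Warping direction.**  The ED frame is resampled through $x - u(x, t)$ and
compared with frame $t$.  With this convention $u$ is the forward material
displacement: `propagate_mesh()` moves each ED vertex to $x + u(x, t)$, and a
rigid translation of the chamber is recovered exactly.  (With the opposite
convention the recovered field has the opposite sign to the material motion
and cannot propagate the mesh directly.)  For non-rigid fields the two
conventions agree to first order in $\|\nabla u\|$; at the strain magnitudes
of interest here the difference is far below the verification tolerances.

**Similarity details.**  The registration's internal NMI uses a joint
histogram with hard binning of the fixed frame and a cubic-kernel Parzen
window along the moving axis (32 bins by default over each image's own
intensity range), which makes the objective differentiable in the
coefficients.  The standalone `nmi()` function uses plain equal-width
binning on both axes, satisfying the textbook identities
$\mathrm{NMI}(A, A) = 2$ and symmetry.

**Hyperparameters.**  The sparsity weight (SW, default $10^{-4}$) and
bending-energy weight (BE, default $10^{-3}$) are the two weights a user
should consider tuning; `hyperparameter_search()` implements the grid search
used for that purpose: every (SW, BE) combination is scored per case by
Dice, average surface distance and directed Hausdorff distance at the
end-systolic frame, each metric min-max normalised across the grid (Dice
inverted to an error) and combined with equal weights; a seeded five-fold
cross-validation selects the optimum on training cases and reports held-out
error.  The default grid offers 9 SW values (including SW = 0, to assess the
sparsity constraint in isolation) times 7 BE values = 63 combinations.

**A known artifact.**  When all frames are identical, the exact optimum is
$u \equiv 0$, but trilinear interpolation slightly sharpens the moving
histogram away from grid-aligned sampling, so Parzen-NMI can improve
marginally for small non-zero displacements.  At the default regularisation
this produces a drift of roughly a fifth of a voxel (~0.25--0.35 mm at
1.5 mm spacing).  Raising SW to $10^{-3}$ suppresses the drift below 0.1 mm
but biases real displacement amplitudes low enough to triple the
verification RMSE, so the default stays at $10^{-4}$; treat sub-voxel
displacements on (near-)static series with caution.

## Strain

Strains are computed per surface element against the ED mesh.  For a
triangle with reference and deformed vertex positions, both are expressed in
local orthonormal in-plane frames; the 2x2 matrix $F$ mapping reference edge
vectors to deformed edge vectors is the in-plane deformation gradient.  Then

* **area strain** $= 100\,(A_{def} - A_{ref})/A_{ref}$, and
* **fibre strain** $= 100\,(\lVert F \hat f\rVert - 1)$ with $\hat f$ the
  unit fibre direction in the reference frame,

both in percent.  Under a uniform in-plane scale $s$ these reduce to
$100(s^2 - 1)$ and $100(s - 1)$ for any fibre direction — the closed forms
the test suite checks to $10^{-9}$.

Global and regional transients are unweighted means of the per-element
strains over the LA body (an area-weighted option exists but is off by
default, following the convention of averaging elemental strain).  Orifice
rim elements never enter the averages.  The **reservoir strain** is the
maximum minus minimum of a transient over the cycle, which is insensitive to
a mis-triggered reference frame.  **Normalised regional strain** is
$(r - g)/g$ for regional reservoir $r$ and global reservoir $g$, so negative
values mark regions straining less than the chamber average — the ratio
form (rather than the difference $r - g$) is used because it gives the sign
semantics just stated and is dimensionless across patients with different
global strain.  **Dyssynchrony** $\Delta T$ is the range, in frames, of the
regional transient argmax times (ties resolve to the earliest frame).
Chamber volumes close the orifices with centroid fans and integrate the
divergence theorem; LAEF is $100\,(V_{max} - V_{min})/V_{max}$.

## Atrial coordinates, regions and fibres

Regional analysis needs an intrinsic 2D parameterisation of the atrial body.
The package computes two harmonic coordinates with a cotangent-weight
Laplacian and Dirichlet anchors (a simplified construction in the spirit of
universal atrial coordinates, not a reimplementation of any published
atlas pipeline):

* $\alpha$ (lateral 0 to septal 1): anchored at two landmark-seeded geodesic
  paths running from the appendage rim and the right-inferior-vein rim down
  to the mitral rim on the lateral and septal sides respectively;
* $\beta$ (mitral 0 to roof 1): anchored at the mitral boundary loop and at
  a roof geodesic joining the two superior vein rims through the posterior
  roof point.

Both are clamped to $[0, 1]$; a direct sparse solve makes the discrete
harmonic interpolation exact to solver precision, and the discrete maximum
principle holds on the near-equilateral meshes produced by the generator.
Elements are labelled with the five wall regions (posterior, septum,
lateral, anterior, inferior) by their $(\alpha, \beta)$ centroid falling in
axis-aligned rectangles of the unit square.  The rectangle placement is a
declared package default stored in `inst/extdata/regions_default.json`
(inferior near the mitral rim, septal/lateral bands at the $\alpha$
extremes, a posterior band above an anterior band); no claim is made that it
matches any particular published partition, and it is fully user-overridable.
With two-path boundary conditions $\alpha$ spans its full range on both the
anterior and posterior walls, so the $\beta$ split carries the
anterior/posterior distinction; on strongly non-ellipsoidal anatomies the
user should inspect and adjust the rectangles.

Fibre directions come from an atlas $\theta(\alpha, \beta)$ sampled on a
grid over the unit square and bilinearly interpolated at each element's
coordinate centroid.  The angle is realised in an orthonormalised tangent
frame: the first axis is the normalised in-plane gradient of $\alpha$, the
second its in-plane orthogonal complement oriented towards the $\beta$
gradient (Gram-Schmidt; $\hat e_\alpha$ and $\hat e_\beta$ are not generally
orthogonal, so the raw pair would not define the angle consistently).  The
bundled atlas (`inst/extdata/atlas_synthetic.json`) is a smooth *synthetic*
angle field, not measured human fibre data; real atlases are ingested
through the same JSON grid format.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against
exactly known ground truth:

* **Anatomy** — a subdivided icosahedron scaled to an ellipsoid (default
  semi-axes 32 x 27 x 24 mm, chosen as a typical adult LA body), perturbed
  by six smooth seeded radial bumps of 3% relative amplitude, with six
  circular orifices cut (mitral 38 degrees angular radius, four pulmonary
  veins 14-15 degrees, appendage 16 degrees) and rim elements labelled.
* **Motion** — radial scaling about the chamber centroid with a raised-cosine
  temporal bump: $s(t) = 1 + (s_{peak}-1)\,w(t)$, $w(0)=w(F)=0$,
  $w(t_{peak})=1$, $C^1$ and periodic.  The default $s_{peak} = 1.08$ at
  frame 4 of 10 gives a peak area strain of ~16.6% and fibre strain of 8%,
  in the range reported for diseased atria; an analytic family was chosen so
  ground-truth strain is available in closed form.
* **Images** — parity-fill rasterisation of the (capped) surface at
  64^3 voxels and 1.5 mm spacing by default (coarser than clinical CT to
  keep desk-scale runtimes; configurable), blood pool 300 and background 50
  intensity units, one-voxel Gaussian boundary smoothing and additive
  Gaussian noise (sd 5).  The whole volume is warped in the verification
  loop, including structures outside the chamber.

What the generator does *not* emulate: patient-derived shape statistics,
wall thickness (the workflow is endocardial-surface only), CT noise texture
and beam-hardening, ECG mis-triggering artefacts, and neighbouring
structures with tissue-like contrast.  Passing the verification loop
therefore demonstrates correct mechanics of the tracking-and-strain chain at
realistic motion amplitudes and CT-like contrast — not clinical accuracy on
patient images.

## The verification loop

`run_verification()` mirrors the synthetic-image verification idea: the
analytic motion is first projected onto a control-point lattice by least
squares (`fit_motion_field()`), so the truth lies in the representation
space the registration searches; synthetic frames are made by warping the
noisy ED image through that field; the series is re-registered from scratch;
and the ED mesh is propagated through both fields.  Reported quantities are
the median body-vertex position error per frame and the absolute global
reservoir-strain errors for both metrics.  At the defaults (seed 1) this
yields a median peak-frame RMSE of ~0.14 mm and reservoir errors below one
percentage point — comfortably inside the 0.8 mm and 3 point bounds the
acceptance suite asserts; `scripts/acceptance.R` recomputes exactly these
two numbers.

## Planar two- and four-chamber strain

The 2D comparator resamples each frame into a view plane defined from
landmarks (two-chamber: mitral centre, appendage ostium, chamber centroid;
four-chamber: mitral centre and the two inferior vein ostia — the exact
landmark choice is configurable), intersects the ED mesh with the plane for
the reference contour, marks rim-derived segments excluded, and tracks the
contour with the same registration engine in 2D mode (a flat lattice axis;
2D and 3D share one code path).  Strain is the percentage change of
non-excluded contour length; 2D GLS is the mean of the two views' reservoir
strains.  Because the planes are static while the chamber moves through
them, apparent in-plane motion differs from projected material motion; on
the synthetic radial-scaling case the recovered GLS is within a few points
of the 10% linear stretch but systematically less exact than the 3D
pipeline — which is precisely the limitation of planar strain the 3D method
addresses.

## Biomarker classification

`roc_cv()` evaluates scalar biomarkers (reservoir strains, LA EDV, LAEF,
GLS) for binary AF classification with seeded stratified five-fold
cross-validation: AUC per fold by the Wilcoxon rank statistic, marker
orientation fixed on training data only, and a vertically averaged mean ROC
curve on a fixed false-positive-rate grid.  `combine_biomarkers()`
normalises each marker by z-scoring with training-fold statistics, orients
it so larger means more AF-like, and sums — an unweighted combination was
chosen over a fitted logistic model to keep the combined score a transparent
"volume + function" index and to avoid fitting two coefficients to a
handful of training cases per fold.  Vertical averaging of fold curves was
chosen over threshold averaging as the common convention for mean ROC
display.

## Numerical choices and degenerate inputs

* Lattice support: points outside a level's support get zero displacement
  from that level and a warning flag (`propagate_mesh` contract).
* Histogram edges: the moving-axis Parzen coordinate is clamped one bin
  inside the histogram; a constant image makes NMI degenerate and is
  defined as 1.
* Harmonic solve: disconnected interior components without Dirichlet
  vertices raise an error; boundary paths sharing vertices (degenerate
  $\alpha$ anchors) raise an error.
* Fibre mapping: elements with vanishing $\|\nabla\alpha\|$ fall back to
  the neighbour-average fibre and are flagged.
* Argmax ties in $\Delta T$ resolve to the earliest frame; grid-search ties
  resolve to the lowest SW, then BE, and are reported.
* Rasterisation handles tangential ray hits by dropping unmatched
  crossings; voxel centres are jittered by $10^{-7}$ voxel to dodge exact
  edge intersections.
* All lengths are mm, volumes ml, strains percent, times frame indices;
  frame 0 = ED = R-wave.

## Problem sizes

The shipped tests and the acceptance script run the full loop on one
64^3-voxel, 10-frame case (two lattice levels, ~5.4k and ~20k coefficients)
and keep unit-test registrations at 32-48^3 voxels with 2-3 frames; these
sizes were chosen so the whole suite completes on a laptop-class single
core while still exercising every code path at realistic motion amplitudes.

## Known limitations

* The harmonic-coordinate construction is a deliberate simplification; its
  region boundaries are package defaults, not a validated atlas.
* The bundled fibre atlas is synthetic; fibre-strain *values* on real
  anatomies are only as meaningful as the atlas supplied.
* Strain is endocardial-surface strain; no transmural or thickness
  information.
* The registration offers no diffeomorphic guarantee; strong motions with
  folding are out of scope.
* Cohort-level clinical findings require patient data and are out of scope;
  the classification module is exercised on simulated marker tables.
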