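# lastrain

Three-dimensional left atrial (LA) motion tracking and strain analysis for
retrospectively gated cardiac CT (RGCT), in R.

## The problem

Atrial fibrillation and heart failure remodel the left atrium; its
**reservoir strain** — how much the chamber stretches while it fills during
ventricular systole — is a sensitive functional marker, but clinical practice
mostly measures it on 2D echo or CT views, which see only a slice of a
genuinely three-dimensional motion.  `lastrain` implements a full 3D
workflow for researchers working with gated CT: it tracks the LA endocardium
across the cardiac cycle by deformable image registration, maps an atrial
coordinate system and fibre directions onto the surface, and reports global
and regional area and fibre strains together with the derived clinical
markers (reservoir strain, normalised regional strain, dyssynchrony
interval, chamber volumes, emptying fraction, planar 2D GLS) and a
cross-validated ROC analysis for biomarker evaluation.

## The method in brief

Motion is a cyclic spatiotemporal free-form deformation: multi-level cubic
B-splines in space and a periodic cubic B-spline in time parameterise a
displacement field $u(x,t)$ with $u(x,0)=0$, fitted by simultaneously
registering every later frame to the end-diastolic (ED) frame:

$$\min_c\; \sum_{t=1}^{F-1} -\mathrm{NMI}\big(I_0(x - u(x,t)),\, I_t\big)
\;+\; \lambda_{BE}\,\mathcal{B}(c) \;+\; \lambda_{SW}\,\|c\|_{1,\varepsilon}$$

with normalised mutual information similarity, a bending-energy smoothness
penalty $\mathcal{B}$, and a smoothed L1 penalty encouraging sparsely
activated control points (L-BFGS with analytic gradients, coarse-to-fine).
The ED surface mesh is propagated through the field; per-element
**area strain** $100(A_{def}-A_{ref})/A_{ref}$ and **fibre strain**
$100(\lVert F\hat f\rVert-1)$ (in-plane deformation gradient $F$, fibre
direction $\hat f$ from an atlas mapped through harmonic atrial coordinates)
are averaged globally and in five wall regions; reservoir strain is the
max − min of each transient.

A synthetic-data module generates LA-like anatomies with exactly known
cyclic motion and CT-like image appearance, so the whole chain is verifiable
against closed-form ground truth without patient data.

## Worked example

```r
library(lastrain)

# a synthetic LA: ellipsoid-with-orifices anatomy, 8% peak radial expansion,
# 10 frames, 64^3 voxels at 1.5 mm
case <- synth_la_case(seed = 1)
series <- synth_image_series(case$anatomy, case$motion, noise_sd = 5, seed = 1)

report <- run_pipeline(pipeline_config(
  images    = series$images,
  mesh      = case$anatomy$mesh,
  landmarks = case$anatomy$landmarks,
  seed      = 1))
report
#> <strain_report>
#>   global reservoir area strain: 13.81 %
#>   global reservoir fibre strain: 6.80 %
#>   delta-T (area): 0 frames
#>   delta-T (fibre): 0 frames
#>   LA EDV: 85.7 ml, LAEF: 17.7 %
```

The generating motion peaks at an 8% radial scale, whose analytic peak area
strain is $100(1.08^2-1) = 16.6\%$ and fibre strain $8\%$; the values above
are recovered through the full rasterise-register-track chain, within a
couple of percentage points after the pull-back warping convention is
accounted for.  Zero dyssynchrony (delta-T) is correct for spatially uniform
motion.
`tidy(report)` returns the per-region reservoir and normalised strains as a
tibble, `glance(report)` the one-row scalar summary, and
`autoplot(report$transients)` the strain curves.

The verification loop — warp the ED image with a known motion field,
re-register, compare — is one call:

```r
res <- run_verification(seed = 1)
res$median_rmse_peak_mm      # 0.138 mm
res$reservoir_error_pct      # area 0.86, fibre 0.46 percentage points
```

A thin CLI over the same functions lives in `inst/cli/lastrain.R`
(`synth`, `register`, `run`, `verify`, `classify` subcommands).

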