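---
title: "Measuring muscle architecture from fascicle-band distortion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring muscle architecture from fascicle-band distortion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

In B-mode ultrasound of a pennate muscle, the two aponeuroses appear as
bright, quasi-horizontal bands, and the fascicles between them as oblique
striations. Two architecture parameters summarise the geometry per frame:

* **fascicle length (FL)** — the Euclidean distance between the points where
  a fascicle inserts into the superficial and deep aponeuroses, in mm;
* **pennation angle (PA)** — the acute angle between the fascicle direction
  and the deep aponeurosis, in degrees.

Classic automated approaches either track one user-chosen fascicle
(fragile when that fascicle leaves the imaging plane) or detect a dominant
stripe orientation in every frame (fragile under noise and vessels).
`fasctrack` instead measures the *distortion of the whole fascicle band*:
every trackable point between the aponeuroses contributes, and no single
fascicle or intensity pattern needs to survive the recording.

## Pipeline

The measurement of a video proceeds in four stages, given a one-time manual
initialization on frame 0 (two aponeurosis boxes plus one fascicle-direction
line EF):

1. **Aponeurosis tracking.** Each user box is followed through the video by
   a particle filter. The state of a box is a six-parameter affine warp
   $[x, y, \theta, s, a, \psi]$ (translation, rotation, scale, aspect,
   skew) mapping a canonical template grid to the image. The transition
   model perturbs each parameter independently with Gaussian noise; the
   observation likelihood of a particle is derived from the error of its
   warped image patch under a sparse representation over ten target
   templates (the frame-0 box content and nine ±2 px jitters of it) plus
   positive/negative single-pixel "trivial" templates. The sparse code is
   obtained by a fixed, small number of accelerated proximal-gradient
   (FISTA) iterations. The emitted per-frame state is the posterior
   weighted mean — the conditional expectation that the Bayesian
   formulation identifies as the optimal estimator — and particles are then
   resampled systematically.
2. **Aponeurosis delineation.** In every frame the propagated box seeds a
   two-phase Chan–Vese segmentation restricted to a window around the box.
   The band-facing edge of the largest segmented component is extracted
   (per column: bottom-most pixel for the superficial aponeurosis, top-most
   for the deep one), refined to subpixel precision at the region-mean
   intensity threshold, and fitted with a straight line by ordinary least
   squares. These two lines are the per-frame fascicle-band boundaries.
3. **Distortion tracking.** For each consecutive frame pair the rectangle
   spanned by the current insertion points defines a region of interest.
   Interest points are detected there in a nonlinear (edge-preserving)
   diffusion scale space, tracked into the next frame by pyramidal
   Lucas–Kanade optical flow with a forward–backward validity check, and
   summarised into a 2-D affine transform by M-estimator sample consensus
   (MSAC). The fascicle line EF is mapped through that transform, and the
   tracked frame becomes the new reference.
4. **Geometry.** The insertion points A and B are the intersections of the
   propagated EF with the two fitted boundary lines; FL is their calibrated
   distance and PA the acute angle between EF and the deep boundary line.
   Insertions may leave the image during strong contractions; the lines are
   extrapolated and the frame flagged.

## Model details and numerical choices

### Chan–Vese evolution

The segmentation minimises the two-phase piecewise-constant energy

$$E(u) = \rho\,\mathrm{TV}(u) + \beta_1 \sum u\,(I - c_1)^2
       + \beta_2 \sum (1 - u)\,(I - c_2)^2 + \gamma \sum u$$

over a relaxed interior indicator $u \in [0,1]$, with the region means
$c_1, c_2$ recomputed every iteration. We use the *unconstrained* (efficient)
formulation: no signed-distance function is maintained during evolution, the
data term drives every pixel, and each step is a projected gradient step
whose length follows the Barzilai–Borwein secant rule, seeded by the step
size `dt` and clipped to $[0.01\,dt,\ 100\,dt]$ because BB steps are
non-monotone. Iteration stops when the mean absolute per-pixel change falls
below $\zeta = 0.18^2\,dt$, or at `max_iter`. Two further choices matter in
practice:

* intensities are normalised to $[0,1]$ inside the solver, which makes the
  segmentation exactly invariant to affine intensity rescaling (scanner gain);
* the interface exposes a level set $\varphi$ with interior
  $\{\varphi > 0\}$; internally $u = H_\varepsilon(\varphi)$ with a smoothed
  Heaviside of width 1.5 px, and the returned $\varphi$ is $u - 1/2$.

Defaults: $\rho = 9\times10^{-4}$, $\beta_1 = \beta_2 = 1$, $\gamma = 0$,
`dt = 0.51`, `max_iter = 5000`. The sentence fixing $\beta_1, \beta_2,
\gamma$ in the method's published description is grammatically ambiguous
(three symbols, two values); we default to $\beta_1 = \beta_2 = 1,
\gamma = 0$ and expose all three.

The binary mask quantises the band edge to whole pixels, which makes the
fitted line jump by up to one pixel between frames. The boundary is
therefore refined per column to the subpixel crossing of the region-mean
threshold $(c_1 + c_2)/2$ within a few rows of the mask edge before the
least-squares fit; per-column noise in this refinement averages out over the
few hundred fitted columns.

### Particle filter

Defaults follow the published configuration: 800 particles, 39×39 template
grid, ten templates, target/trivial L1 penalties 0.2 / 0.001, Lipschitz
constant 8, five proximal-gradient iterations, occlusion re-weighting 10.
Three details are this package's own:

* **Variance mapping.** The published transition variances
  `[0.03, 0.0005, 0.0005, 0.03, 1, 1]` are listed against the state order
  $[x, y, \theta, s, a, \psi]$, but read positionally they would give the
  translations a standard deviation of 0.02–0.17 px — too small to follow
  any visible motion. The magnitudes match the affine-matrix-entry
  convention of the $\ell_1$-tracker family (diagonal 0.03, off-diagonal
  5e-4, translation 1), so the defaults map them as
  $s, a \leftarrow 0.03$, $\theta, \psi \leftarrow 5\times10^{-4}$,
  $x, y \leftarrow 1$; the scale-like parameters $s$ and $a$ receive their
  noise multiplicatively (relative), since additive noise of that size flips
  the sign of the aspect of a thin aponeurosis box. The mapping is a named
  vector in `pf_params()` and fully overridable.
* **Likelihood sharpness and observation blur.** Weights are
  $\exp(-\lambda\,e)$ with $e$ the target-template projection error of the
  L2-normalised patch. On normalised 39×39 patches, a 1–2 px box
  displacement changes $e$ by only ~0.01–0.03, so the default sharpness is
  $\lambda = 60$; much smaller values flatten the posterior and the tracker
  lags fast motion. Each frame is pre-blurred with a 1.5 px Gaussian before
  patch extraction: resampling a box several hundred pixels wide onto 39
  columns otherwise undersamples the image (stride ≈ 8 px), and the
  aliasing noise swamps the displacement signal.
* **Estimator.** The posterior mean is emitted instead of the single
  highest-weight particle: with hundreds of nearly equally weighted
  particles the argmax follows observation noise (several px of jitter on a
  static scene), while the conditional expectation is stable to a fraction
  of a pixel. The best particle's projection error is kept as a per-frame
  diagnostic.

One property of the published penalties is worth knowing: because the
trivial-template penalty (0.001) is 200× cheaper than the target penalty
(0.2), the *converged* lasso solution routes the entire patch through the
trivial templates. The five-iteration operational budget is therefore not
merely a speed choice — it is what keeps the target templates in play. The
package's tests verify both regimes: atom identification at the operational
budget, and agreement of the reconstruction error with an independent
coordinate-descent solver at an extended budget.

### Distortion step

Interest points are detected as scale-normalised determinant-of-Hessian
maxima in a nonlinear diffusion scale space (Weickert "edge" conductivity,
contrast parameter at the 70th gradient percentile, explicit time stepping,
octaves × sublevels = 9 × 5 capped by the ROI size). Because edge-preserving
diffusion never blurs strong edges away, the usual $\sigma^4$ normalisation
diverges with scale; derivatives are instead computed with a stencil spacing
proportional to $\sigma$, which keeps responses comparable across levels.
Detection is deterministic; no descriptors are computed — correspondence
comes from optical flow, as in the published design.

The Lucas–Kanade tracker converts its physical parameters through the
calibration (block 5 mm → px rounded to the nearest odd integer ≥ 3;
bidirectional error 3 mm → px) and caps the pyramid depth so the block still
fits at the coarsest level. A point is valid if the forward track converged
in bounds and the backward track returns within the bidirectional tolerance.

MSAC samples three correspondences, fits the exact affine, scores all pairs
with the truncated cost $\min(d^2, d_{\max}^2)$ ($d_{\max} = 30$ px), keeps
the lowest-cost model and refits by least squares on its inliers. The
printed trial budget of $10^6$ is capped by the standard adaptive rule
(99.99 % confidence of one outlier-free sample) — on ordinary frames a few
dozen trials suffice. If fewer than three valid points survive, the previous
frame's transform is carried forward and the frame flagged.

Per the reference-update cadence, every consecutive frame pair forms
(reference, tracked); after measurement the tracked frame becomes the new
reference and interest points are re-detected in the updated ROI.

## The phantom generator

`phantom_spec()` renders calibrated videos that emulate the B-mode
appearance this method relies on: two bright bands (default intensity 0.85
on background 0.12, thickness 14 px), a fascicle band textured with
oblique *dashed* striations with exponential ("Poisson") spacing jitter,
per-dash brightness and lateral jitter (dash endpoints give interest-point
detectors genuine 2-D structure — continuous parallel lines would make all
motion along the stripes unobservable), and multiplicative speckle
`I(1 + sigma * eta)`. The speckle field `eta` is generated once in frame-0
coordinates and warped with the scheduled motion: B-mode speckle is
scatterer-generated and moves with the tissue (this is what makes speckle
tracking possible at all). Per-frame *independent* noise would model
electronic noise instead, and acts as a static zero-motion texture that
biases any flow estimator toward zero.

The superficial band position is derived from `fl0` and `pa0` so that
`fl0 * sin(pa0)` equals the perpendicular band gap times the calibration.
Motion schedules: `static`, whole-scene `translate`, a parametric
`contraction` (linear PA and FL schedules with the deep aponeurosis held
fixed — the frame-t geometry is an exact global affine of frame 0), or
explicit per-frame affines. Ground truth FL/PA comes from mapping the
frame-0 fascicle segment and band edges through those affines (affine maps
preserve incidence, so insertion points transform directly).

What the phantom does **not** emulate: attenuation and depth-dependent gain,
curved aponeuroses, out-of-plane motion, partial speckle decorrelation,
vessels and fat layers. Passing the phantom studies therefore demonstrates
the pipeline's internal consistency and robustness to in-plane affine
motion plus stationary multiplicative noise — not performance on clinical
recordings, for which the published external videos remain the benchmark.

Default study sizes (chosen once as desk-scale representatives of the
published recordings): 224 × 320 px at 0.2 mm/px, FL₀ = 50 mm, PA₀ = 20°,
10-frame static and 30-frame contraction (PA 20°→30°, FL 50→40 mm,
speckle σ = 0.15) sequences. The tests and the acceptance script use these
sizes; a full analysis of the public gastrocnemius videos runs the same
pipeline on larger frames.

## Sensitivity harness and metrics

`run_sensitivity()` re-runs the pipeline with the same seed under perturbed
initializations of the fascicle line: parallel shifts along the deep
boundary (default ±10, ±20 px, the published scenario set), rotations
produced by moving E and F by ±d px in opposite directions along the line
normal (default d = 10), and box-thickness changes. Two exact geometric
facts anchor the harness: a parallel shift leaves the frame-0 PA unchanged,
and a rotation changes the frame-0 PA by exactly the imposed line rotation
(both runs measure against the same fitted deep boundary).

Agreement metrics are RMSE and the pairwise within-subject coefficient of
variation, $\mathrm{CoV} = \mathrm{mean}_i\!\left[\frac{|a_i - b_i|/\sqrt2}
{(a_i + b_i)/2}\right]\times 100\%$ — the definition standard in the
measurement-reliability literature behind the common ≤10 % acceptability
threshold. Other CoV definitions give different numbers; comparisons across
software should check the formula.

## Known limitations

* Straight-line aponeurosis fits only; curved aponeuroses would need
  polynomial boundary fitting.
* Errors of the frame-to-frame distortion step compound along the video;
  on the 30-frame contraction phantom the accumulated drift stays below
  2 % FL / 0.6° PA, but longer videos drift more.
* The method inherits the initialization sensitivity of its fascicle
  direction line: a rotated initialization shifts all subsequent PA values.
* Measurements assume in-plane motion; out-of-plane probe motion violates
  the affine-distortion model.
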