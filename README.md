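# fasctrack

Automated frame-wise measurement of **muscle fascicle length (FL)** and
**pennation angle (PA)** in B-mode ultrasound videos of pennate muscle,
based on the distortion pattern of the fascicle band rather than on any
single fascicle or intensity pattern.

In a longitudinal B-mode scan of a pennate muscle the two aponeuroses
appear as bright bands and the fascicles as oblique striations between
them. Given a one-time initialization on the first frame — a box around
each aponeurosis and one line EF parallel to the fascicle direction — the
pipeline measures every frame in four stages:

1. **Aponeurosis tracking** — each box is followed by a particle filter
   over a six-parameter affine state ϑ = [x, y, θ, s, a, ψ], with an
   observation likelihood exp(−λ‖patch − T a‖²) from a sparse
   representation of the warped box patch over target + trivial templates,
   solved by accelerated proximal-gradient iterations.
2. **Delineation** — a two-phase Chan–Vese segmentation
   (E = ρ·Length + β₁∫ᵢₙ(I−c₁)² + β₂∫ₒᵤₜ(I−c₂)² + γ·Area), driven by
   Barzilai–Borwein gradient steps, delineates each aponeurosis inside the
   propagated box; the band-facing edge is line-fitted by least squares.
3. **Distortion tracking** — interest points detected in a nonlinear
   diffusion scale space inside the ROI spanned by the insertion points are
   tracked with pyramidal Lucas–Kanade flow (forward–backward validated)
   and condensed into a per-frame-pair affine by MSAC; EF is propagated
   through that affine.
4. **Geometry** — A = EF ∩ superficial boundary, B = EF ∩ deep boundary;
   FL = ‖A − B‖ · mm/px, PA = acute angle between EF and the deep
   boundary line.

The package also ships a calibrated synthetic phantom generator with
analytic ground truth (bands + dashed striations + tissue-locked speckle +
global affine motion), an initialization-sensitivity harness, and RMSE /
coefficient-of-variation agreement metrics.

## Worked example

Generate a 30-frame contraction phantom (PA 20°→30°, FL 50→40 mm, speckle
σ = 0.15), run the pipeline, and compare with the analytic ground truth:

```r
library(fasctrack)

spec <- phantom_spec(
  n_frames = 30, speckle_sigma = 0.15,
  motion = list(type = "contraction", pa1 = 30, fl1 = 40), seed = 5
)
video <- phantom_video(spec)
init  <- make_init(spec)         # the simulated manual initialization
gt    <- ground_truth(spec)

res <- run_pipeline(video, init, seed = 1)
head(res, 3)
#> # A tibble: 3 x 9
#>   frame fl_mm pa_deg    ax    ay    bx    by n_inliers flags
#>   <int> <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl>     <int> <chr>
#> 1     0  50.0   20.0  277.  84.5  42.8  170.        NA ""
#> 2     1  49.7   20.3  273.  84.9  44.3  170.       200 ""
#> 3     2  49.3   20.7  269.  85.4  45.4  170.       200 ""

agreement_report(res, gt)
#> # A tibble: 1 x 5
#>   rmse_fl rmse_pa cov_fl cov_pa n_pairs
#>     <dbl>   <dbl>  <dbl>  <dbl>   <int>
#> 1   0.339   0.253  0.445  0.490      30

plot_measurements(res, reference = gt)
```

`fl_mm`/`pa_deg` are the per-frame measurements, `ax..by` the insertion
points A (superficial) and B (deep) in pixels, `n_inliers` the MSAC inlier
count of the distortion step, and `flags` frame-level diagnostics
(`mcv_failed`, `distortion_carried`, `extrapolated`). On this phantom the
pipeline stays within 1.7 % of the true FL and 0.6° of the true PA over the
whole contraction.

A thin command-line interface wraps the same functions
(`exec/fasctrack`): `track`, `synth`, `sensitivity`, and `eval` verbs, e.g.

```sh
fasctrack synth --out phantom/ --seed 5 --n-frames 30 --pa1 30 --fl1 40
fasctrack track --video phantom/ --init phantom/init.yaml \
                --mm-per-pixel 0.2 --out measured.csv --seed 1
fasctrack eval  --auto measured.csv --truth phantom/ground_truth.csv --out report.json
```

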