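# anthroscan

Hip and waist circumference from 3D body point clouds, with the evaluation
machinery around it: segmentation-mask scoring for video-frame background
removal, PLY/OBJ/XYZ geometry I/O, PCA + ICP registration of a point cloud
to a reference mesh with cloud-to-mesh error statistics, and a synthetic
body-scan generator with exactly known ground truth.

The package targets the workflow where a subject is filmed with a handheld
device, the frames are background-masked, a structure-from-motion (SfM)
point cloud is reconstructed, and body measurements are read off the cloud.
It is written for researchers in digital anthropometry and body-shape
analysis who need the *measurement and evaluation* side of that pipeline —
mask prediction and photogrammetric reconstruction themselves are out of
scope (masks and clouds are inputs).

## The estimator

Given a cloud aligned with Y vertical and the subject's measured height
`H`:

1. scale uniformly so the vertical extent equals `H` (the metric anchor —
   SfM clouds carry no units);
2. cut horizontal slices of 1 cm thickness at 1 cm steps;
3. fit each slice's (x, z) points to an ellipse by direct least squares
   under the ellipse-specific constraint `4AC − B² = 1` (the fit cannot
   degenerate into a hyperbola or parabola);
4. evaluate each slice's circumference with the Ramanujan approximation
   `P ≈ π[3(a+b) − √((3a+b)(a+3b))]`, accurate to 1e−4 relative for
   body-like aspect ratios;
5. **hip** = maximum-perimeter slice in the band `[0.35 H, 0.50 H]`
   (largest circumference slightly below mid-height, as anthropometrists
   define it); **waist** = the slice in `(0.50 H, 0.65 H]` closest to the
   anthropometrist's tape value when one exists, else the band's
   minimum-perimeter slice.

Registration quality against a reference mesh (e.g. a structured-light
scan) is summarised by RMSE, mean distance and population SD of the
point-to-nearest-triangle distances, so `RMSE² = MD² + SD²` holds exactly.

## Worked example

Every stage can be exercised on a synthetic subject with known ground
truth:

```r
library(anthroscan)

spec  <- default_body_spec(170, hip_circ_cm = 100, waist_circ_cm = 85, seed = 1)
truth <- synthetic_ground_truth(spec)        # hip 100.000 cm @ y 81.6, waist 85.000 cm @ y 98.6
cloud <- sample_cloud(spec, n_points = 40000, noise_sigma_cm = 0.5, seed = 2)

measure_body(cloud, 170, reference_waist_cm = truth$waist_perimeter)
#> Body measurement (waist rule: reference)
#>   hip:   98.52 cm at y = 80.5 cm
#>   waist: 84.80 cm at y = 101.5 cm
#>   scale factor: 0.9833
```

The hip comes back 1.5% low: with 0.5 cm of isotropic noise the extreme
points that define the vertical extent inflate the height anchor by ~2.5 cm,
shrinking every circumference slightly — the intrinsic cost of scaling by
height. The waist matches to 0.2 cm. Registering the same cloud against the
generator's mesh:

```r
mesh <- mesh_from_spec(spec, 60, 48)
icp(cloud, mesh, max_iter = 20)
#> ICP registration: 40000 points, 6 iterations (converged)
#>   RMSE 0.5044 cm | mean distance 0.4024 cm | SD 0.3041 cm
```

— the error statistics of an on-surface cloud with σ = 0.5 cm noise, as
expected. Contaminating the cloud with `add_spurious()` (uniform background
debris in a room-shaped box around the subject) drives all of these numbers
up by one to two orders of magnitude, which is the package's model of
measuring an *unmasked* SfM reconstruction.

Results follow broom conventions (`tidy()` for per-slice / per-iteration /
per-frame tables, `glance()` for one-row summaries) and each result type
has an `autoplot()` method.

A command-line front-end with `simulate`, `mask-eval`, `chroma`,
`register`, `measure` and `report` subcommands is installed at
`inst/scripts/anthroscan`; `run_pipeline()` drives the whole synthetic
study from a plain-text config and writes bit-reproducible CSV/JSON
reports.

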