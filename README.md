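# vesselcam

Camera-based liquid level and consumed-volume estimation in a conically
shaped drinking glass, for fluid-intake monitoring of fluid-restricted
patients (e.g. hemodialysis patients limited to ~1 L/day, for whom
self-reporting is notoriously unreliable).

A low-resolution camera clipped to the rim images the inside of the glass.
The contact line of the liquid with the wall appears as an arc of an
ellipse. vesselcam implements the full measurement chain:

1. **Segmentation** — disk pre-blur, then a Sobel binary gradient mask
   (normalized kernels, threshold 0.005) or a Frangi-style **vesselness**
   ridge filter, followed by morphological refinement (dilate with line
   elements, fill holes, erode).
2. **Level detection** — scan the mask with quadratic curves
   `row = a·col² + b·col + c` (a = 0.003, b ∈ [−0.58, −0.14], 4 steps,
   every row intercept); the connected component with the largest
   single-curve overlap is the level arc, which is then pruned, bridged
   and smoothed into a per-column trace.
3. **Ellipse reconstruction** — the visible arc plus a point-reflected
   copy (placed 50 px above the bottom edge) is fit as a general conic
   `A x² + B xy + C y² + D x + E y + F = 0` by least squares (`ls_conic`,
   `direct`, or `taubin`); level in px is the row of the top tangent
   measured from the bottom edge, area in px² is `π·a·b`.
4. **Calibration** — level: `mm = p1·px² + p2·px + p3` (OLS); area:
   `mm² = a·exp(b·x) + c·exp(d·x)` (Levenberg–Marquardt with deterministic
   multistart); iterated robust (MAD-standardized, k = 2.5) outlier
   flagging.
5. **Volume** — conical frustum `V = (π/3)·h·(r1² + r2² + r1·r2)`, with
   radii from calibrated areas (`r = sqrt(area/π)`).
6. **Agreement** — Bland–Altman bias, limits of agreement, and the
   coefficient of variation of inferred vs reference volumes.

A synthetic scene generator (`render_scene`, `add_noise`) renders frames
with exact ground truth — pinhole projection of the contact circle, radial
illumination, specular clutter, Gaussian + salt-and-pepper degradation —
so every stage is testable end to end without camera hardware. A measured
calibration table for the default glass ships in
`inst/extdata/table2.csv`.

## Worked example

Calibrate from the bundled table, then convert two frame measurements to
consumed volume:

```r
library(vesselcam)

tab <- read_calibration_table()
use <- !tab$outlier & is.finite(tab$level_px)
lv <- fit_level_model(tab$level_px[use], tab$level_mm[use])
ar <- fit_area_model(tab$area_px2[use], pi * (tab$diameter_mm[use] / 2)^2)
print(lv)
#> Quadratic level calibration: mm = 0.00167 * px^2 + 0.0481 * px + 15.4
#>   R^2 = 0.9913, std. error = 1.4248 mm (n = 14, dof = 11)
print(ar)
#> Two-term exponential area calibration: mm^2 = 3670 * exp( 2.51e-06 * x ) + -3660 * exp( -0.000243 * x )
#>   R^2 = 0.9774, std. error = 51.2216 mm^2 (n = 14, dof = 10)

m_full  <- list(level_px = 146, area_px2 = 8215)   # full glass (60 mm)
m_later <- list(level_px = 109, area_px2 = 13895)  # after drinking (40 mm)
volume_difference(m_full, m_later, lv, ar)
#> 60.7  (mL consumed between the two frames)

ba <- bland_altman(tab$calc_vol_ml[use], tab$derived_vol_ml[use])
print(ba)
#> Bland-Altman agreement (n = 14)
#>   mean difference     : 2.14 mL
#>   SD of differences   : 3.98 mL
#>   limits of agreement : [-5.65, 9.94] mL
#>   SE of mean difference: 1.06 mL
#>   CV                  : 3 %
```

The calibration explains the level to 1.4 mm and the section to ~51 mm²
over the glass's working range; volume agreement has a 2 mL bias and a CV
of 3% — about 30 mL/day against a 1 L restriction.

Single frames (files or matrices) are measured with
`measure_image(image, vessel_config())`; `run_end_to_end()` performs a
fully synthetic simulate → measure → calibrate → evaluate experiment. A
thin CLI over these functions is installed at `inst/cli/vesselcam.R`
(subcommands `simulate`, `measure`, `calibrate`, `evaluate`, `run-all`).

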