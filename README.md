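# guvpore

Automated pore tracking and edge-tension estimation for electroporated
giant unilamellar vesicles (GUVs).

## The problem

When a GUV is porated by a strong DC pulse, a micrometer-scale macropore
opens and then closes in four stages: rapid growth, stabilization at a
maximum radius, a long *slow leak-out* stage, and fast final closure.
During the slow stage the membrane's pore edge tension γ — the energy cost
per unit length of the open pore rim, in piconewtons — drives closure
according to

```
R² ln r(t) = −(2γ / 3πη) · t + C
```

where `R` is the vesicle radius after pore closure, `r(t)` the pore
radius, `η` the viscosity of the aqueous medium and `C` an
experiment-dependent constant. Recording a vesicle with a fast camera
under phase contrast, resolving `r(t)`, and regressing `R² ln r` against
time in the linear stage therefore yields γ from the slope:
`γ = (3π/2) · η · |slope|` (with η in mPa·s and the slope in µm²/ms, the
product is directly in pN).

Measuring hundreds of per-frame pore diameters by hand is slow and
user-dependent; `guvpore` automates the whole chain for anyone doing
membrane biophysics with GUV electroporation: phase-contrast image
sequences in, γ with fit diagnostics out.

## What the package does

- **TIFF I/O and pre-processing** — multi-page grayscale stacks (8/16-bit),
  optional rolling-ball background subtraction, automatic crop suggestion,
  90° rotation, time slicing (`read_stack()`, `subtract_background()`,
  `suggest_crop()`, `rotate90()`, `slice_time()`).
- **Per-frame segmentation** — Sobel gradient, isodata thresholding,
  bottom-half restriction, membrane-area-relative speck removal,
  directional labeling from the top center, and pore width as the
  Euclidean distance between the membrane elements flanking the gap
  (`segment_frame()` and friends).
- **Vesicle geometry** — area-equivalent GUV diameter from the first and
  last (closed) frames and the 5% radius-constancy gate that the model
  assumption requires (`measure_diameter()`, `radius_gate()`).
- **Pore dynamics** — the `R² ln r` trace, moving-average smoothing for
  display/detection, automatic linear-region detection (with manual
  override), the regression and unit conversion to γ, and four-stage
  annotation (`build_trace()`, `detect_linear_region()`,
  `fit_edge_tension()`, `classify_stages()`).
- **Synthetic ground truth** — a phase-contrast-like GUV video generator
  with exact four-stage pore dynamics, so every step is testable without a
  microscope (`synthetic_spec()`, `generate_trace()`, `render_stack()`).
- **One-call pipeline** — `pore_analyze()` orchestrates everything, never
  crashes on a degenerate frame, writes the pore-size-vs-time text file,
  the dynamics plot, and a machine-readable result JSON; `"complete"` mode
  additionally saves the processed mask stack. `tidy()`, `glance()` and
  `autoplot()` methods give tibble summaries and ggplot figures.

A thin command-line front end lives in `inst/scripts/guvpore.R`
(`analyze` and `synth` subcommands).

## Worked example

Generate a synthetic vesicle (radius 12 µm, true γ = 40 pN, 360 fps,
0.25 µm/px) and analyse it:

```r
library(guvpore)

spec   <- synthetic_spec(R_true = 12, gamma_true = 40, r_max = 3.6, seed = 3)
truth  <- generate_trace(spec)
stack  <- render_stack(truth, spec)
result <- pore_analyze(stack)
result
#> <guv_edge_tension>
#>   gamma     = 40.7 pN
#>   slope     = -8.646 um^2/ms  (C = 477.2 um^2)
#>   R^2       = 0.9949 over 13 points (automatic region 9..21)
#> <guv_geometry> R before 11.6 um, after 11.6 um, deviation 0.01%
```

The recovered γ (40.7 pN) sits within 2% of the generating value; the
slope is the fitted coefficient of `R² ln r` vs time in µm²/ms over the
automatically detected slow-closure window (open-pore points 9–21), and
the vesicle radius was measured at 11.6 µm before and after the pore
(deviation far below the 5% gate). Broom-style accessors give the same
numbers as tibbles:

```r
glance(result)
#> # A tibble: 1 × 12
#>   gamma_pN slope intercept r.squared n_points region_start region_end ...
#> 1     40.7 -8.65      477.     0.995       13            9         21

tidy(result)
#> # A tibble: 2 × 5
#>   term      estimate std.error statistic  p.value
#> 1 intercept   477.      10.1        47.3 4.60e-14
#> 2 slope        -8.65     0.187     -46.1 6.09e-14
```

`autoplot(result)` draws the dynamics graph: raw `R² ln r` points, the
smoothed series, the shaded linear region, and the fitted line.

For a real video the call is the same with a file path and the
acquisition metadata:

```r
pore_analyze("vesicle.tif", frame_rate = 360, pixel_size = 0.25,
             viscosity = 1.06, out_dir = "results/")
```

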