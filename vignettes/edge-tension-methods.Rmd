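---
title: "Measuring pore edge tension from GUV videos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pore edge tension from GUV videos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering choices inside
`guvpore`: the model the edge-tension estimate rests on, every tunable
parameter with its default and rationale, what the synthetic video
generator does and does not emulate, and the numerical conventions used
throughout.

## The model

A giant unilamellar vesicle (GUV) porated by a DC pulse develops a single
macropore whose life has four stages: (i) growth, (ii) stabilization at a
maximum radius, (iii) slow closure, (iv) fast terminal closure. In stage
(iii) — the slow leak-out regime, which dominates the pore lifetime — the
pore radius $r(t)$ obeys

$$ R^2 \ln r(t) = -\frac{2\gamma}{3\pi\eta}\, t + C , $$

where $R$ is the vesicle radius (taken after pore closure), $\eta$ the
viscosity of the aqueous medium and $C$ an experiment-dependent constant.
The relation assumes an incompressible membrane, uniform membrane tension
and a vesicle radius that stays essentially constant during closure; the
last assumption is what the 5% radius gate (below) screens for. Fitting a
line to $y(t) = R^2\ln r$ on stage (iii) gives the edge tension from the
slope $s$:

$$ \gamma = \tfrac{3\pi}{2}\,\eta\,|s| . $$

Units are bookkept so no conversion constants appear downstream: radii in
µm, time in ms, $\eta$ in mPa·s. Then $1\ \mathrm{mPa\,s} \cdot 1\
\mu\mathrm{m^2/ms} = 10^{-12}\ \mathrm{N}$, i.e. the product is directly
in pN. The $\ln r$ uses $r$ in µm; the dimensional offset inside the
logarithm is absorbed by $C$ and never affects the slope.

Only stage (iii) is modelled quantitatively. Growth, stabilization and
fast closure are annotated (`classify_stages()`) for reporting, not used
for $\gamma$.

## The measurement chain

Each frame passes through:

1. **Sobel gradient** (3×3 kernels, replicated borders). The sharp
   dark→bright transition at the membrane and the bright phase-contrast
   halo outside it produce a closed high-gradient ring.
2. **Isodata threshold**: the intermeans iteration started at the midpoint
   of the intensity range, converging to the fixed point
   $T = \tfrac12(\overline{x\le T} + \overline{x> T})$ (relative
   tolerance $10^{-6}$ of the range, ≤200 iterations; a constant image is
   an error). Pixels strictly above $T$ are foreground.
3. **Bottom half**: the analysed pore must face the image bottom, so pore
   analysis keeps rows $\lfloor h/2\rfloor+1..h$. Odd heights leave the
   extra row in the bottom half, erring toward a larger analysis region.
   After this crop the top row passes through the vesicle center, which
   is what makes the next step find the inner contour first.
4. **Speck removal**: connected components with area strictly below
   $f(\text{sensitivity})\cdot A_{\text{ref}}$ are dropped.
   $A_{\text{ref}}$ is the largest component of the *first* frame's
   bottom-half mask (the membrane itself), so the filter scales with
   image resolution. The user-facing sensitivity (0–100, default 50)
   maps linearly and inversely onto a 15%→0% area fraction: higher
   sensitivity keeps more elements, 100 keeps everything. The 15% cap
   protects the membrane from being erased.
5. **Directional labeling**: components are labeled with 8-connectivity
   (a one-pixel diagonal contour must stay connected; `igraph` finds the
   components of the 8-neighbour pixel graph). From the top-center pixel
   the scan advances column-by-column outward then row-by-row downward;
   the first foreground pixel on each side selects the left/right
   membrane element. Same element on both sides ⇒ pore closed; different
   elements ⇒ open pore; nothing found on either side ⇒ the membrane was
   lost in that frame (the frame is excluded).
6. **Pore width**: the pore size ($2r$) is the Euclidean distance between
   the *globally nearest pixel pair* across the two elements. For an
   equatorial pore this is the gap chord. The nearest-pair rule is the
   parameter-free reading of "distance between the pore edges"; its known
   cost is a slight inward bias (the nearest pixels sit at the inner
   corners of the membrane band). If only one side was found, the pore
   runs off-frame: the frame is flagged open but its width is recorded as
   invalid rather than measured against the image border.

**Vesicle diameter** (first and last frames, full frame, pore closed):
after the same speck removal, the inner membrane element is selected by
directional scanning outward *from the image center* — on a full frame a
scan from the top edge would reach the outer halo ring first, while the
image center is guaranteed to lie inside the vesicle — its holes are
filled, and the diameter is that of the circle with the filled region's
area: $2p\sqrt{A/\pi}$ at $p$ µm/px. Closedness is verified by a
disk-likeness check: the filled area must reach at least half of
$\tfrac{\pi}{4}$ of its bounding box (a broken arc encloses nothing and
fails). When the last-frame measurement fails the user may supply the
diameter (`final_diameter`).

**Radius gate**: the relative deviation
$|R_\text{before}-R_\text{after}|/R_\text{before}$ above 5% flags the
vesicle (warning, never a stop): the constant-$R$ assumption behind the
slope→γ conversion is then questionable. The denominator is the pre-pulse
radius; the choice is ours, the comparison itself is standard practice.

## Trace, region detection and fit

$y = R^2\ln r$ is computed per open frame ($R$ = post-closure radius;
closed and invalid frames are excluded rather than clamped, $\ln 0$ being
undefined). A centered moving average (default window 5 frames, shrinking
symmetrically at the ends of the open segment) smooths the radii — for
display and region detection only.

The automatic slow-closure detector scans every contiguous window of at
least 5 points of the *smoothed* series and keeps the longest one with
determination coefficient $R^2_{\text{fit}} \ge 0.995$ and negative
slope; among equally long windows the latest-starting wins, since stage
(iii) immediately precedes fast closure. The 0.995 threshold is
deliberately strict: at looser thresholds (e.g. 0.98) a long window that
swallows the stabilization plateau can outscore the true linear stage
simply by being longer. If nothing qualifies the best-determination
window is proposed with a warning; the user can always fix the region in
physical units (`region_ms`, the analogue of picking two points on the
graph).

The regression itself is ordinary least squares on the **raw** $y$ values
inside the region: fitting smoothed values would feed autocorrelated
noise into the slope's standard error. A non-negative slope is an error
("pore not closing"); a fit with $R^2_{\text{fit}} < 0.9$ only warns.
Time is centered before the windowed scans for numerical stability; on an
exactly linear series the fit reproduces slope and intercept to machine
precision, and γ is invariant under shifts of the time origin.

## The synthetic generator

`synthetic_spec()` + `generate_trace()` + `render_stack()` produce videos
with exact ground truth, so the whole pipeline can be validated without a
microscope. Defaults describe a typical fast-camera recording:

| parameter | default | rationale |
|---|---|---|
| `frame_rate` | 360 fps | fast-camera pore recordings |
| `pixel_size` | 0.25 µm/px | mid-magnification phase objective |
| `R_true` | 20 µm | mid-sized GUV |
| `gamma_true` | 40 pN | typical PC-membrane edge tension |
| `viscosity` | 1 mPa·s | water-like medium |
| `r_max` | 0.3·R | macropore, a few µm |
| `t_growth`, `t_stable` | 10, 15 ms | short early stages |
| `r_cutoff` | 0.5 µm | slow→fast hand-over |
| `halo_width` | 6 px | phase-contrast halo |
| `membrane_width` | 1 px | dark→bright transition ramp (bilayer unresolvable) |
| `blur_sigma` | 0.8 px | Gaussian PSF, σ ≈ 0.21λ/NA at λ = 550 nm, NA 0.6 |
| `halo_inset` | 3 px | halo encroachment over the boundary (below) |
| `noise_sigma` | 0.01 | ~2.5 gray levels of camera noise at 8 bit |

The trace is exact: growth is a smooth cubic ramp, stage (iii) inverts
the leak-out relation so its $y(t)$ is a perfect line with slope
$-2\gamma/3\pi\eta$, fast closure collapses to zero over 3 frames, and
closed frames bracket the sequence. The render draws a dark interior, a
ramped dark→bright transition, a bright halo annulus and a mid-gray
background; an open pore removes the rim structure over the angular
sector whose chord equals $2r$, blending to background with a radial
profile local to the rim (the mixed solution sits at the pore mouth, not
deep in the interior) and a PSF-scale angular feather centered on the
true pore edge (lateral mixing has no sharp boundary; a hard cutoff
would leave detectable radial flank edges that drag the measured chord
inward).

`halo_inset` encodes a real property of phase-contrast imaging: the halo
bleeds inward over the object edge, so dark objects appear slightly
shrunken. Rendering the transition at $R - 3\,\mathrm{px}$ makes the
automated measurements *underestimate* radii mildly — vesicle radius by
~1–2%, pore radius by ~9% on average across the validation grid — which
is the behaviour automated measurement on real phase-contrast imagery
shows, with the pore bias larger than the vesicle bias because the
nearest-pair endpoints sit at the inner corner of the displaced band.
Detection misses are a separate phenomenon: pores whose rendered chord
falls below ~2 px (the tail of fast closure, the first growth frame)
segment as closed and are reported as radius 0, not as a measured width.

What the generator does **not** emulate: pulse-time deformation of the
vesicle, multiple or merging pores, intensity flicker, out-of-focus
drift, vesicle-internal structures, or a quantitatively realistic
phase-contrast transfer function (the halo is an idealized annulus).
Passing the validation grid therefore shows the *algorithmic* chain is
correct and its discretization biases are bounded; it does not certify
performance on adversarial real-world videos, where the sensitivity
parameter, background subtraction and manual region selection exist
precisely to let the user intervene.

## Validation problem sizes

The test suite and the acceptance script work at desk scale: recovery of
γ across γ ∈ {10, 25, 40, 60} pN × R ∈ {15, 30} µm at 360 fps (eight
videos, 35–460 frames each, within 15% of truth with median error below
8%), and the bias grid R ∈ {15, 30} µm × noise ∈ {0, 0.01} at γ = 40 pN.
Unit oracles are brute force: hand-convolved Sobel patches, exhaustive
isodata scans, pairwise-distance pore widths, counted-pixel disk areas,
and a direct min/max-filter envelope for the rolling-ball background.

## Other conventions and degenerate inputs

- Frames are numeric arrays on the raw integer scale of their bit depth;
  analysis never normalizes for display. TIFF round-trips are lossless.
- Background subtraction (optional, off by default; `ball_radius` 50 px)
  is the grayscale opening with a disc: flat backgrounds vanish exactly,
  structures smaller than the ball survive, and the operation is
  idempotent to within a gray level.
- The suggested crop expands the largest component's bounding box in the
  thresholded maximum-intensity projection by 20%, split 10% per side
  (the split is our choice), clamped to the frame.
- At least 3 frames are required, and the first/last frames should show a
  closed vesicle; slicing away the closed bracket only warns, since the
  user may supply the final diameter manually.
- A frame whose segmentation fails (membrane lost, everything despeckled)
  is marked invalid and excluded; the pipeline never aborts on single
  frames. Traces shorter than 8 open points refuse automatic region
  detection and ask for a manual region. Flat traces classify as all
  stable and fit nothing.
- Component labels are assigned in column-major order of first pixels, so
  all labeling is deterministic; with a fixed seed the entire pipeline,
  in either analysis mode, is bit-reproducible.

## Known limitations

- **One pore at a time.** Two pores merging are measured as one wide gap
  from the start; the growth stage is then wrong, though the stage-(iii)
  slope — and hence γ — is typically unaffected.
- Pores must face the image bottom; top/side pores are handled by the 90°
  rotation edit, not tracked automatically.
- Pore widths below ~2 px are unresolvable by design of the 8-connected
  gap test; sub-resolution pores read as closed.
- The rolling-ball radius is not auto-tuned; heavily vignetted videos may
  need a different `ball_radius`.
- $R(t)$ is not tracked during closure; the model assumes it constant and
  the 5% gate only screens violations after the fact.
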