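---
title: "Many-channel volume rendering and freehand segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Many-channel volume rendering and freehand segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluovol)
```

`fluovol` is a CPU reference implementation of a many-channel fluorescence
volume pipeline.  Its guiding idea is that every structure — a spectral
channel, a co-registered scan, a segmented subvolume — is kept as an
independent grayscale *channel* with its own render settings, and that
rendering, selection and quantification all operate on the same original
intensity values.  Nothing is ever baked into RGB or converted to an
isosurface: grayscale values in, grayscale values analyzed.

This vignette records the models the package implements, the tunable
parameters and their defaults, the numerical conventions, the design choices
made where the design was genuinely open, and what the synthetic fixtures do
and do not demonstrate.

## Data model and conventions

A channel holds a 3D array `(nx, ny, nz)` of intensities normalized to
`[0, 1]` by its declared bit depth (8, 12 or 16; 12-bit data in 16-bit
containers must be declared, never guessed from the data maximum, because a
dim scan and a 12-bit scan are indistinguishable by their maxima).  Voxel
`(i, j, k)` (zero-based) has its center at `((i,j,k) + 0.5) * spacing`
micrometers; brick index ranges are half-open.  These two conventions remove
every off-by-one ambiguity in projection and tiling, and the round trip
`raw -> normalize -> denormalize` is exact by construction.

The streaming hierarchy is channel → brick → slice.  Bricks
(`make_bricks()`, default maximum extent 128 voxels — ample for the
desk-scale volumes this implementation targets) tile a channel exactly;
slices are view-perpendicular planes spaced uniformly along the view
direction, so a slice-based render and a ray marcher visit the same sample
positions.  Slicing depends only on geometry; content never changes the
schedule.

The camera is orthographic (the natural choice for co-registered microscopy
stacks; the projection matrix/homogeneous-divide path in `project_voxel()`
accepts any 4x4 matrix, so a perspective matrix projects correctly for
selection, but the renderer itself assumes parallel rays).

## Per-channel transfer and shading

The named per-channel controls need concrete formulas; we chose the standard
DVR forms:

* window then gamma: `t = clamp((I - low) / (high - low), 0, 1)`,
  `v = t^(1/gamma)` — "contrast" is the window width;
* opacity `alpha = alpha_scale * v`, premultiplied color
  `C = alpha * (v * color)` or `alpha * colormap(v)` (a built-in
  blue-to-red rainbow when the colormap is enabled);
* depth attenuation multiplies color by `1 - coefficient * depth_fraction`;
* shading multiplies color by `ambient + (1 - ambient) * max(0, N.L)` with
  `N` the normalized central-difference gradient (pointing out of bright
  structures).  Shadows are implemented only as the simplified one-ray term
  `1 - shadow_strength * A`, `A` being the opacity accumulated toward the
  light; a full shadow pipeline is out of scope.
* MIP channels track the per-ray maximum of `v` and are colored after the
  maximum is known, so a MIP channel can be intermixed like any other
  channel image.

Interpolation is trilinear (nearest-neighbor available as an option); the
accuracy tests are all stated against a trilinear ray-marching oracle.

Because slices may be spaced differently from the voxel grid, sample opacity
is corrected as `alpha' = 1 - (1 - alpha)^(spacing / reference)` with the
channel's smallest voxel spacing as reference.  Without this correction a
finer slicing would darken or brighten the image; with it, renders at
spacing 1 and 0.5 agree with the correspondingly-sampled ray marcher to
`1e-3`.

## Compositing, intermixing and streaming

Five operators cover every combination step, always on premultiplied RGBA:
front-to-back (DVR slice accumulation), back-to-front (layered
intermixing), addition (composite intermixing, and cross-channel combination
within a slice in depth mode), maximum (MIP), multiplication (shading
modulation).  The color equations fix only the RGB behavior; for the two
blending operators we adopted the standard premultiplied alpha updates
(`a_out = (1 - a_dest) a_source + a_dest` and
`a_out = a_source + (1 - a_source) a_dest`) so that occlusion is well
defined.

The three intermixing modes map onto two streaming orders:

* **composite** and **layered** stream channel-major: each channel renders
  completely (brick by brick, slice by slice), then its image joins the
  accumulated result — by addition, or by placing the already-accumulated
  front layers over the new channel.  In the layered mode the first-listed
  item therefore ends up in front, matching the reading order of a layer
  list.
* **depth** streams brick-major: bricks sorted front to back, and within
  each slice all channels are sampled and summed before the slice is
  composited front to back.  This is what gives true cross-channel
  occlusion, and it requires co-registered channels (identical dimensions,
  spacing and brick grids).  We read the cross-channel combination within a
  slice as addition; for the slice spacings used here the alternative
  readings coincide on every test we run.  Depth mode supports DVR channels
  only — a per-ray maximum cannot be interleaved slice-by-slice with
  alpha blending — and, at the scene level, channels rather than groups,
  since a group buffer has no single depth per pixel.

The executor maintains the three-buffer protocol: a *channel* buffer for the
in-progress channel, an *intermediate* buffer holding completed channels,
and an *output* buffer shown at each render-loop boundary (intermediate
composited with the partially rendered channel).  The separation exists
because intra-channel compositing (front-to-back) and inter-channel
compositing (e.g. addition) use different equations; mixing partial results
in fewer buffers produces wrong intermediates.  A render loop's *budget* is
defined in work units (slices sampled), not milliseconds: a CPU reference
implementation cannot promise wall-clock budgets, but the contract that
matters — interruption only at legal points, and a final image bit-equal
regardless of budget — is preserved and tested at budgets 1, 7 and
unlimited.  Groups render recursively to their own HDR buffers, then
combine with the scene mode in list order.

## HDR accumulation and tone mapping

Frame buffers are unclamped premultiplied float RGBA; the composite mode
deliberately drives values above 1 where channels colocalize.  `tone_map()`
converts to display in a fixed order: luminance scale, equalization, gamma,
clamp.  The curve operates on un-premultiplied color and the result is
re-premultiplied with the full (unclamped) alpha, so accumulation still
brightens — and, at identity parameters, clips — before the final clamp.

The equalization control needed a concrete curve.  Requirements: identity
at `e = 0`; strictly monotone (pixel brightness ordering must survive);
strong-enough compression that moderately over-range values (up to ~3 at
`e = 0.5`) fall below the display ceiling instead of clipping.  We use

\[ v' = \frac{v}{(1 + e)(1 + e\,v)} , \]

a Reinhard-style rational curve with both a slope and an asymptote
reduction.  At `e = 0.5` it maps HDR values up to ≈ 6 into `[0, 1)`, so the
four test levels {1.0, 1.5, 2.0, 3.0} — one clipped level at identity —
become four distinct 8-bit levels.  The display gamma here is independent of
any per-channel gamma: one shapes a channel's transfer, the other the final
image.  Quantization is round-half-up to 8 bits (PNG) or 10 bits stored in
16-bit TIFF containers.

## Freehand segmentation

Selection is driven by 2D strokes painted on the rendered image.  Each
stroke carries two rasters: a seed region and a (larger) diffusion region.
Membership is decided by *forward* projection — every voxel center is
projected with the camera matrix and tested against the stroke raster —
because inverting a projection maps one pixel to an entire ray.  Each voxel
is tested independently, which keeps the contract trivially parallel.

**Automatic threshold.**  A 256-bin histogram of the seed-region voxels is
fit by a single Gaussian via the sample mean and standard deviation, and
the threshold is placed two standard deviations below the mean,
`t = max(mean - 2*sd, 0.01)`; the floor excludes low-intensity noise, and
with zero spread the degenerate value `mean - 0.01` is used.  The moment
fit is deliberately simple and is accurate exactly when the painted voxels
are dominated by one unimodal intensity population.  When the stroke's
projection columns run through deep empty background (the usual situation
for a thin structure viewed through a 64-voxel-deep stack), the histogram
is background-dominated and bimodal, the standard deviation explodes, and
the rule collapses to its floor — which is why the brush also accepts a
manual threshold, and why the packaged tube walkthrough uses one (below).

**Occlusion.**  Candidate seeds are validated by casting a ray *back to the
viewer*, accumulating opacity under the channel's own transfer function —
what you see is what you can pick.  A seed survives if the accumulated
opacity stays below `opacity_cutoff` (default 0.7).  Only seeds are tested
(the diffusion region is typically much larger); the tests verify this
equals testing all voxels and intersecting.

**Morphological diffusion.**  Validated seeds grow by iterating

\[ u_{i+1}(x) = g(x)\,\delta_i(x) + (1 - g(x))\,u_i(x), \qquad
   \delta_i(x) = \max_{b \in B} u_i(x + b), \]

with `B` a 3×3×3 box (26-connectivity, default) or the 6-neighborhood, both
including the center.  Since the dilation dominates (`delta >= u`) and `g`
lies in `[0, 1]`, the update is pointwise non-decreasing and the field's
energy grows monotonically — the scheme cannot oscillate and, for binary
`g`, reaches the flood fill of `{g = 1}` in at most diameter-many
iterations.  Both properties are tested against a queue-based BFS oracle.

The stop function needed a concrete form; we use the product of a smooth
threshold term and a Perona–Malik edge term:

\[ g(x) = \operatorname{clamp}\!\Big(\frac{I(x) - (t - w)}{w}, 0, 1\Big)
          \cdot \exp\!\big(-(|\nabla I(x)| / \kappa)^2\big), \]

with defaults `w = 0.1` (intensity units: the ramp from forbidden to free
diffusion spans 0.1 of the normalized range) and `kappa = 0.5` (gradient
units, per voxel step: a full-contrast step edge, whose central-difference
magnitude is ≈ 0.5, attenuates `g` to `e^{-1}`).  Growth is confined to the
stroke's diffusion domain by forcing `g = 0` outside it; iteration stops at
`max |u' - u| < 1e-4` or after 128 iterations (a 26-connected front crosses
a 64-voxel volume in 64 steps, so the cap is not binding at desk scale).
The continuous field `u` is kept on the mask (binarized at `u >= 0.5`) so
the `diffuse` brush can refine a selection without new seeds; `erase` clears
every voxel projecting into the stroke and is deliberately occlusion-blind,
making select-then-erase with the same stroke an exact inverse in
unoccluded scenes.

**The tube walkthrough.**  The packaged recovery scenario selects the noisy
dim-core tube (wall 0.85, core 0.4, 5% Gaussian noise) with a single sweep
whose diffusion region covers the tube's footprint.  Two parameter choices
depart from the defaults, both for reasons visible in the geometry before
any test is run.  First, the threshold is manual (0.3): the painted columns
are ~80% empty background, so the moment-based automatic rule lands on its
noise floor — a practitioner facing this histogram drags the threshold
slider, exactly the manual path the brush exposes.  Second, `kappa = 1.0`:
the tube's wall–background step has central-difference magnitude ≈ 0.4
(half the 0.85 jump), so at `kappa = 0.5` the edge term sits at
`exp(-0.64) ≈ 0.53` — within noise of the 0.5 binarization cut — on wall
voxels that are part of the ground truth.  With an empty background the
intensity window alone stops the growth, so the scenario relaxes the edge
term; `kappa = 0.5` remains the right default for data where distinct
structures touch.

## Analysis

Selections become channels by masking (`extracted + complement = original`,
exactly).  Connected components are labeled under 6- or 26-connectivity
(via an `igraph` component search over the voxel adjacency), ordered by
voxel count; statistics report volume in µm³ (voxel count × voxel volume)
and intensity on the channel's declared raw scale — a 12-bit channel reports
0–4095, because that is the scale acquisition software shows.  Ruler anchors
are placed by marching the clicked pixel's ray and snapping to the maximum
transferred intensity (ties to the nearest; a first-hit-above-threshold
alternative is a config option), and ruler length is the Euclidean polyline
length in world coordinates, so anisotropic spacing is automatic.  Only
ruler-based length is implemented; skeleton length of a mask would be a
separate estimator and is noted as an extension.

## Synthetic fixtures

All tests run on generated data; each generator is a pure function of its
arguments with a private RNG stream.

* `gen_tube()` — a curved tube whose wall (0.85) outshines its core (0.4),
  with 5% additive Gaussian noise: the intensity profile that makes
  threshold isosurfaces misleading, plus a voxel ground-truth mask.
* `gen_blobs()` — non-overlapping Gaussian blobs with known labels
  (nuclear-stain-like MIP content).
* `gen_atlas()` — n co-registered channels (default 96), each one smooth
  random-walk filament with a distinct hue: the many-channel regime at desk
  scale (64³ per channel), used to show capacity and per-channel isolation.
* `gen_limb()` — three co-registered channels (a dense front sheet, side
  cords, thin branches behind the sheet) built so that depth, composite and
  layered intermixing are visibly and testably different.

What these fixtures do **not** emulate: microscope point-spread functions,
spectral bleed-through, registration error, anisotropic noise, or intensity
falloff with depth.  A passing suite therefore demonstrates the algorithms'
contracts (compositing identities, stream invariance, diffusion
convergence, conservation) and their behavior on idealized fluorescence
geometry — not robustness to every acquisition artifact of real scans.

## Problem sizes and numerical choices

The test suite and the acceptance script use 64³ channels (96 of them for
the capacity check), 12–20³ volumes for brute-force oracle comparisons, and
10⁴-sample histograms; the full suite runs in under two minutes on one CPU
core.  Key tolerances: slice renders match ray marching to `1e-3` per
component on oracle-sized volumes; budget invariance holds to `1e-4`
(differences are pure float-summation reordering); compositing operators are
exact.  Cameras pad their half-extents by `1e-6` µm so boundary voxels
project strictly inside; the first and last view slices of a box can
degenerate to a tangent corner or edge, which the renderer handles as an
empty polygon.

## Known limitations

Orthographic rendering only (perspective projection is supported for
selection, not for the slicer); depth mode requires co-registration,
identical brick grids and DVR channels; brick visibility sorting assumes an
axis-aligned brick grid (exact for any single-brick channel and for axis
views); shadows are the simplified one-ray term; no pyramidal/
multiresolution levels of detail — channels are assumed to fit in memory at
full resolution, consistent with the many-small-channels regime the design
targets.
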