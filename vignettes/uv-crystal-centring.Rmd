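---
title: "Two-stage UV crystal centring: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage UV crystal centring: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvcentre)
```

## The problem

On a macromolecular crystallography beamline the crystal must sit exactly at
the X-ray focus before data collection. The crystal is mounted in a small
loop (a nylon cryoloop or a stamped-polymer litholoop) on a pin held by a
goniometer with x/y/z translation stages and an ω rotation axis. Under
ordinary backlight the crystal is nearly indistinguishable from the
cryoprotectant around it; under ~265–285 nm UV the aromatic residues of the
protein fluoresce, so the crystal appears bright on a dark field (the hutch
lights are switched off during the exposure). `uvcentre` implements the
resulting two-stage centring procedure:

1. **Loop alignment** (visible frames): find the holder silhouette, match
   the "neck and shoulders" pattern common to both holder families, box the
   holder and move its centre of mass to the beam.
2. **UV crystal centring** (UV frames): remove the holder contour from the
   image, detect the crystal's edges with a Laplacian-of-Gaussian (LoG)
   operator, and move the crystal's intensity centre of mass to the beam.

Each stage observes only 2D image offsets, one per rotation angle; a small
least-squares solve turns them into a single 3D stage translation.

## Geometry and the 3D solve

All image coordinates are 0-based `(row, col)` with the origin at the
top-left pixel centre; micron/pixel conversions always go through the
camera calibration `pixel_size_um`. The stage frame is `(x, y, z)`: `x`
along the rotation axis (image-horizontal), `y` image-vertical (downward)
at ω = 0, `z` the viewing direction at ω = 0. A point at position
`(x, y, z)` relative to the beam/rotation-axis intersection appears at a
pixel offset

```
dx = x / p          dy = (y cos ω − z sin ω) / p
```

from the beam centre, with `p = pixel_size_um`. The camera is modelled as
viewing exactly along the beam; the real camera is parallel but slightly
off-axis, and since no offset magnitude is available that parallax is
deliberately ignored.

`solve_centre()` inverts this model by least squares: `x` is the mean of
the observed `dx` (the model makes `dx` angle-independent), and `(y, z)`
solve the cos/sin system. Two angles distinct modulo 180° are the
mathematical minimum; the shipped protocol uses three (0°, 45°, 90°),
which adds one redundant equation and a residual that
flags inconsistent observations (threshold 2 px RMS; the solution is still
returned). Degenerate angle sets raise an `uvc_insufficient_angles` error.
The returned `move_um` is the negated solved position — the translation
that zeroes the offsets. Round-tripping `predict_offset()` through
`solve_centre()` is exact to machine precision, which the test suite
asserts at 1e-9 µm.

## Stage 1: holder recognition

**Tip detection.** Edges are gradient-magnitude pixels above an
Otsu-selected threshold — Otsu because it is parameter-free and the
backlit silhouette is strongly bimodal. The pin enters from the image-left
edge by convention (the simulator follows the same convention), so the tip
is in the rightmost edge column, at the midpoint of the edge rows found
there; the holder is symmetric about its axis, so the midpoint is where
the axis meets the tip. A frame whose gradient range is below
`min_dynamic_range` (default 0.05 intensity units) raises `uvc_no_object`
— the empty-mount signal.

**Pattern match.** The neck-and-shoulders template is generated
parametrically (neck width and length, shoulder width, shoulder drop) at
the frame's pixel scale rather than loaded from stored images: the feature
is a shape family, not a file. Matching is normalized cross-correlation
over every full placement, computed with summed-area tables and an FFT
cross-correlation; scores are clipped to [−1, 1] and flat windows score 0.
The NCC score of the implementation agrees with a brute-force per-window
oracle to 1e-9, which the tests assert placement by placement. Visible
frames are matched on the inverted image so the dark silhouette correlates
positively with the binary template. The acceptance threshold defaults to
0.6 and sits in the configuration: genuine embeddings score near 1,
structureless frames near 0, and a non-standard holder around 0.5, so 0.6
separates the populations with margin in both directions.

**Box and centre of mass.** The holder box spans from the end of the
matched neck to the far extent of the silhouette component hit by the
template. The centre of mass is the intensity-weighted centroid of
foreground pixels in the box, weighted by inverted intensity on visible
frames; it is therefore invariant under global intensity scaling and
shifts exactly with integer translations of the content.

**Spherical fallback.** When no placement is accepted on any frame (or
the accepted frames leave a degenerate angle set), the sample is assumed
spherical with diameter exactly 1.5 × the widest dimension of the observed
foreground, centred at the per-frame foreground centre of mass. "Widest
dimension" is aggregated as the larger bounding-box extent of the
silhouette, maximised over all frames — the aggregation had to be fixed
somewhere, and the maximum is the conservative choice for a sphere that
must enclose the sample. The 1.5 factor is exact by construction and the
suite asserts `diameter_um / widest_dimension_um` is identical to 1.5 for
arbitrary silhouettes.

## Stage 2: UV crystal segmentation

**Holder removal.** Nylon loops often reflect UV brightly, so the loop can
outshine the crystal; removing the known holder geometry first is what
makes a dimmer crystal findable at all. The removal mask is the holder
silhouette — by default taken from the visible frame at the same angle,
configurable to the UV frame itself (`loop_model_source`), since either
reading is defensible — reduced to its largest connected component (noise
speckles must not enter the model) and dilated by `band_px` (default 3 px).
Pixels in the band are replaced by the background estimate; every pixel
outside the band passes through bit-exactly, which the tests assert. The
band is the full silhouette rather than a thin contour ring: with
realistic wire thicknesses a contour-only band would leave an annular
residue of loop material that segmentation would happily report as a
crystal. If no loop geometry is available the frame passes through
unchanged with a logged warning (degraded mode).

**Background estimate.** Median of the pixels below the Otsu threshold. A
global estimate is appropriate because the hutch lights are off: the UV
background is a flat dark field.

**LoG edges.** The frame is convolved with the sampled kernel
`(r² − 2σ²)/σ⁴ · exp(−r²/2σ²)` on a `(2⌈3.5σ⌉+1)²` grid, DC-corrected to
zero sum so a constant frame gives a response of exactly zero. Boundary
handling is symmetric (mirror with edge duplication). Edges are zero
crossings: 4-neighbour pairs of opposite response sign whose difference
exceeds the threshold; both pixels of a crossing are marked so contours
stay closed for region filling. The default scale is σ = 2 px — small
enough to localise a 10 px crystal edge, large enough to suppress
pixel-level texture. The default crossing threshold resolves per frame to
`max(1% of dynamic range, 6 × MAD of the response)`: the 1% rule governs
clean frames, and the MAD floor rejects noise-induced crossings on noisy
ones (at crystal SNR 5 the response MAD is ~25× larger than the 1% rule,
and a fixed 1% threshold would bury the frame in spurious contours). Both
parameters live in `edge_params()`.

**Segmentation.** Zero-crossing contours are filled (`fillHull`) and
labelled; a component qualifies when its mean interior intensity exceeds
the background estimate by 3 robust sigma (the noise-aware reading of
"brighter than background" — without the margin, flat noise patches
enclosed by spurious crossings qualify by luck). Among qualifying
components the largest is the crystal; ties break by proximity to the beam
centre. Multi-crystal scenes therefore deterministically yield the largest
crystal. The centroid is the intensity-weighted centre of mass of the
interior; the extent is the sub-pixel interpolated zero-crossing span
along the horizontal and vertical scans through the centroid — exact for
the convex outlines the pipeline targets, and immune to the corner bulges
of the LoG zero set around polygonal shapes. No qualifying component
raises `uvc_no_crystal`, deliberately distinct from `uvc_no_object`: the
holder was present, the crystal was not.

**Contrast score.** Mean interior intensity over mean background outside
the (dilated) contour and outside the holder band. On paired frames of the
same scene the UV score exceeds the visible score essentially always —
that ordering, not the absolute value, is the meaningful output.

## Dose budget

The UV exposure accounting mirrors the protocol's own bookkeeping. The
reference per-exposure dose is 16 µW in a 200 µm spot (the 1 s reference
value for the characterized LED source); the default protocol takes one
300 ms exposure at each of three angles, accumulating 16 × 3 = 48 µW —
under the published "about 50 µW". Summing powers over exposures is
physically unconventional (power × time is energy), so the report also
carries a time-scaled variant, 16 µW × 0.3 s × 3 = 14.4 µJ, flagged as
alternative accounting; the primary figure reproduces the protocol's
numbers, the variant flags the unit ambiguity.

Safety is a density comparison: a single exposure's dose over its spot
area against the published damage threshold of 0.1 mW in a 150 µm spot.
Spots are treated as circles of the stated diameters — "spot" is otherwise
undefined. The default plan sits at a density ratio of
(16/π·100²)/(100/π·75²) = 0.09, a pass; the verdict is `pass` only
*strictly below* the threshold density, because the threshold is the level
at which damage was observed, not a level known to be safe. Measured beam
profiles enter through `beam_profile()`/`aperture_dose()`, which
integrates the bilinear density surface over the circular measurement
aperture (200 µm, sampled at 200 µm steps in the reference instrument) and
agrees with a 10×-finer-grid integration within 1%.

## The synthetic-scene generator

Every quantitative claim in the package is exercised on rendered scenes
with exact ground truth, because no beamline hardware is attached. The
generator emulates the features the method actually keys on:

* a holder on a pin entering from the left: a nylon loop (elliptical
  annulus), a litholoop (rounded-rectangle film outline around an
  elliptical aperture — a solid paddle would put the crystal inside the
  removal mask), or a non-standard blob with the pin out of frame, the
  case that defeats pattern matching;
* a convex crystal (box, hexagon or ellipse outline) at a 3D offset from
  the rotation axis, projected by the same forward model the solver
  inverts — consistency between the two is a test, not an assumption;
* the two contrast regimes: visible backlight (dark holder on a bright
  field, crystal within 0.05 of the background — the constructor rejects
  visible contrasts above 0.2) and UV (crystal 0.90 > loop 0.35 >
  background 0.05);
* shot noise with standard deviation `shot_scale·√I` plus additive read
  noise (σ = 0.01), a standard camera model; the default `shot_scale`
  gives SNR ≈ 10 at the UV crystal level, and "crystal SNR s" in the tests
  means `shot_scale = √0.9/s`.

Geometry is rendered at 4× supersampling and box-downsampled, so sub-pixel
positions are faithful: the rendered centroid of a noiseless crystal lands
within 0.5 px of the analytic projection (asserted by brute-force centroid
computation). Identical `(spec, angles, seed)` give bit-identical frames;
each `(seed, ω, mode)` triple gets its own deterministic RNG stream, and
the caller's RNG state is restored afterwards.

Default scene parameters, chosen once as plausible for a mid-magnification
beamline camera: 192×192 px frames at 2 µm/px (384 µm field of view), a
220 × 180 µm loop with 20 µm wire, a 60 × 40 µm crystal mounted 10 µm
tip-ward and 6 µm below the loop centre (a crystal is rarely mounted
dead-centre, and that residual offset is exactly why the UV stage exists).
The pin geometry and magnification are free choices — no published values
exist for them.

What the generator does **not** emulate: optical point-spread and
defocus, parallax of the off-axis camera, ice rings, solvent menisci and
drying artefacts, non-convex or twinned crystals, holder damage, and the
ω-dependence of the holder silhouette (the holder is modelled as
rotationally symmetric about the pin axis; a planar loop viewed edge-on
would defeat stage 1 at some angles, and no loop-plane orientation data
is available). Passing tests therefore demonstrate the correctness of the
geometry, the estimators and the protocol accounting under a clean camera
model — not robustness to every artefact of real beamline imagery.

## Pipeline composition and statuses

`run_centring()` consumes a directory of frames named `{mode}_{omega}.tif`
(angle and mode must be recoverable without a database), a fixture set, or
in-memory frames. Stage 1 runs on the visible frames; its move is applied
*virtually* — the beam-centre reference for stage 2 shifts by the forward
model of the solved move, since the frames are static and no motor is
attached — and the final move is the composition, algebraically equal to
the translation that puts the crystal on the beam. Statuses: `centred`,
`fallback_used` (stage 1 fell back to the sphere model but the crystal was
still centred), `no_crystal` (stage 2 found nothing at any angle; the
stage-1 move is still reported, as the best available), and `failed`
(fewer than two usable stage-2 angles remain). Reports are deterministic:
identical inputs and configuration produce byte-identical JSON, with no
timestamps.

Stage 1 and stage 2 default to the same angle set; the configuration
allows them to differ because nothing in the procedure requires them
equal.

## Problem sizes and tolerances in the test suite

The suite renders its fixtures at the generator defaults (192×192 px);
one pipeline test uses 512×512 px frames and asserts completion within
10 s on one CPU. Property suites run 200 seeded scenes for the end-to-end
recovery and contrast claims (the per-module unit tests run 5–25-seed
subsets of the same generators), 100 random moves for the solve
round-trip at 1e-9 µm, and 50 random frames against the brute-force
convolution oracle at 1e-9. Recovery tolerances are expressed in
pixel-equivalents (`pixel_size_um` microns per axis): 1 px for noiseless
scenes, 2 px at crystal SNR ≥ 5.

## Known limitations

* The multi-angle geometry is validated self-consistently (simulator and
  solver share one convention); no external goniometer ground truth
  exists in software.
* The fallback widest-dimension measure includes anything the Otsu
  foreground captures; for standard holders with a visible pin it would
  include the pin, so the simulator renders non-standard holders with the
  pin out of frame and the measure is only used on that path.
* The holder-removal band replaces intensity with a scalar background
  estimate; structured UV background (stray reflections) would survive
  removal and could seed false contours.
* Dose accounting reproduces the protocol's bookkeeping; it is not a
  radiometric model of absorbed energy, and wavelength-dependent damage
  is out of scope.
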