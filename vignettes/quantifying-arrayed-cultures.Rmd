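---
title: "Quantifying arrayed cultures on agar: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying arrayed cultures on agar: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agarQuant)
```

# The problem

Solid-agar fitness screens compare growth of hundreds of micro-organism
cultures arrayed on a rectangular grid. Cell density is estimated from plate
photographs taken at one or more times after inoculation. Two inoculation
styles behave very differently: *pinned* cultures (dense inoculum) grow into
opaque circular colonies and are easy to segment; *spotted* cultures (dilute
liquid inoculum) start out faint and irregular, and their long exponential
phase is precisely what makes them informative for growth-rate estimation.
The obstacle is that a faint culture's intensity is comparable to the
spatial variation of illumination across the plate: without lighting
correction, cultures in dim regions are scored as empty.

agarQuant addresses this with a chain of four ideas: a fast locally adaptive
first-pass segmentation; reconstruction of a *pseudo-empty plate* (the plate
as it would photograph with no cultures) to serve as a lighting map; a
multiplicative regression of all pixels towards the median agar intensity;
and a final plate-wide segmentation by a two-component Gaussian mixture
model of the corrected intensity histogram.

# Models and procedures

## Grid geometry

The user supplies the grid dimensions and the pixel centres of the top-left
and bottom-right cultures (through `gridSpec()` or a plain-text config read
by `readGridConfig()`). Tile dimensions follow from the corner-centre
spacing, `xDim = (xBR - xTL) / (nCols - 1)` (the user's own value is used
when a count is 1), and the top-left tile corner is placed half a tile
before the first centre. Coordinates are 0-based with x rightwards and y
downwards; tiles are half-open rectangles of fixed size. Tile corners are
rounded half-away-from-zero once, at construction; rounding again downstream
would accumulate drift. Tiles that stick out of the image are clamped for
pixel access but keep their nominal size in the output.

## First-pass local thresholding

The greyscale image (ITU-R BT.601 luma; the choice of luma weights is
immaterial at the contrasts involved) is run through a 3×3 Sobel operator
with replicate borders. Per tile, the gradient value below which 95% of the
tile's pixels lie is estimated by nearest-rank percentile, and pixels
strictly above it form the high-gradient mask — colony edges, halos, dirt.
The tile is then re-thresholded at the intensity below which the darkest 33%
of the *masked* pixels lie: every tile pixel above that cutoff is first-pass
culture. Re-thresholding the whole tile (rather than only masked pixels) is
what lets whole colonies, not just their edge rings, survive — necessary
because every first-pass culture pixel is later cut out of the lighting map,
and a culture pixel left in the map would be "corrected" back towards the
agar median, erasing its signal. The converse error, calling agar culture,
costs nothing: those pixels are simply interpolated over.

The 5% and 33% fractions are heuristic defaults exposed as
`keepFraction`/`darkFraction` in `pipelineConfig()`. Thresholding is per
tile, not per pixel neighbourhood, which keeps the pass linear in image
size.

One guard is needed where the two-step rule degenerates: on a tile with no
real signal, the high-gradient mask is pure noise and its darkest-33% cutoff
lands *below* the tile's background level, which would flood most of the
tile. A tile is therefore declared flat (all background) when its cutoff
falls below the median of the unmasked pixels — i.e. when the "signal"
pixels are not brighter than the background they were picked from. Ties
resolve toward background throughout (percentiles by nearest rank, culture
strictly above the cutoff).

## Pseudo-empty plate

The greyscale image is strongly smoothed (Gaussian, sigma defaulting to a
quarter tile width — wide enough to suppress pixel noise at colony scale,
narrow enough to leave plate-scale gradients intact). Smoothing pads borders
by linear extrapolation, so smooth lighting ramps pass through undistorted
right up to the image edge; replicate or reflective padding would flatten
the ramp in a border band three sigma wide, exactly where the outer culture
columns sit.

Each scan line (first rows, then columns on a fresh smoothed copy) is walked
for runs of first-pass culture pixels. At each run edge the darkest pixel
within half a tile dimension is taken as the background edge value — the
minimum skips the bright reflective halos that ring cultures on translucent
agar — and the run is replaced by the linear ramp between its two edge
values. Runs touching the border use the single available side (constant
fill); a scan line that is entirely culture (overgrown plates) falls back to
the plate-wide median of observed pixels. The horizontal and vertical fills
are merged by pixel-wise minimum, which protects against bright islands
inside irregular spotted cultures biasing one direction's fill upwards.

## Lighting correction

The median background intensity `iMed` is taken over the grid bounding box
of the pseudo-empty plate, and every pixel of the original image is scaled
by `iMed / I_PE`. Pseudo-empty intensities are floored at 1 unit and ratios
clipped to [0.2, 5] so a degenerate near-black map pixel cannot blow up a
correction; clip counts are recorded. Corrected values cap at 255 (the
method assumes non-saturated source images; saturated-pixel counts are
reported as a quality warning). For RGB images the greyscale-derived ratio
multiplies all three channels, keeping colour measures comparable across the
plate. The model is purely multiplicative — appropriate for illumination
gradients, not for additive offsets such as stray light, which the method
does not attempt to remove.

## Mixture segmentation

The corrected image's intensity histogram over the grid bounding box
(integer bins 0–255; the saturated bins 0 and 255 are excluded from the fit)
is modelled as

$$g(x) = \theta\, e^{-(x-\mu_1)^2/2\sigma_1^2} + e^{-(x-\mu_2)^2/2\sigma_2^2},$$

a sum of two Gaussian curves whose peak heights stand in ratio θ : 1. To use
this as a likelihood, g is normalised over the fit bins; the binned
log-likelihood \(\sum_x PI[x]\log\hat g(x)\) is maximised by a seeded
multi-start bounded search (a moments-based start plus 24 random starts,
each polished by L-BFGS-B) within μ ∈ [1, 254], σ ∈ [0.5, 128],
θ ∈ [10⁻⁴, 10⁴]. Components are ordered μ₁ < μ₂ afterwards (swapping roles
maps θ to 1/θ and leaves the normalised model unchanged). A fixed seed gives
bit-identical fits.

Constraining the model to exactly two components forces every pixel to be
either culture or agar. The segmentation threshold is the intensity at which
a pixel is equally probable under either component — the intersection of the
two curves, a quadratic in x solved in closed form (linear when the
variances are equal). Among real roots the highest-intensity intersection
inside [μ₁, μ₂] is preferred, then the highest real root; nested components
with no real intersection fall back to the midpoint with a warning. With
equal spreads and equal peaks at μ = (64, 192) this gives exactly 128; with
θ ≠ 1 the threshold shifts from the midpoint by σ²·ln θ/(μ₂ − μ₁).

**No-growth detection.** On a blank plate both components end up modelling
the single agar population, and any threshold inside that noise bump would
call tens of percent of pure agar "culture". Rather than shape heuristics
(component separation, mixing weight), the package uses a likelihood-ratio
comparison: the same histogram is also fitted with a single Gaussian, and if
the second component improves the log-likelihood by less than
`minEvidence = 50` the plate is declared growth-free. Measured on generated
plates, blanks gain under 10 while a plate of cultures only 6 intensity
units above agar (3 noise standard deviations — barely visible) gains over
a thousand, so the boundary sits an order of magnitude from both
populations. The rule's known limit: a plate whose only signal is a single
tiny culture contributes so little likelihood that it may be declared
blank; at the formats this tool targets (dozens to hundreds of cultures per
plate) that case does not arise.

## Tile refinement and measurements

Tiles are refined on the final mask by exhaustive search over offsets in
[−10, +9]² (a 20×20 window), minimising the count of culture pixels on the
tile's one-pixel perimeter; ties break by smallest Euclidean offset, then
row-major order, so an already-centred tile never moves. Then per culture:
area (culture pixels in the tile); IOD, \(\sum \max(I_{corr} - i_{med}, 0)\)
over culture pixels (per-pixel flooring keeps bright-background tiles from
contributing negative density); tile IOD, the same sum over all tile pixels
floored at zero — it also captures sub-threshold signal; granularity, the
count of high-gradient pixels in the tile (a texture measure distinguishing
smooth pinned colonies from grainy spots); and mean culture/agar RGB from
the original image (NA when a pixel class is empty). Edge tiles are measured
normally but flagged: edge cultures enjoy a nutrient advantage and should be
non-experimental on dense formats.

## Logistic growth summaries

Density timecourses (IOD by default) are summarised by
\(G(t) = K G_0 e^{rt} / (K + G_0(e^{rt} - 1))\): G₀ the inoculum density, K
the carrying capacity, r the growth rate per day. Fitting is least squares
on the linear density scale via Levenberg–Marquardt with positivity bounds
(`logScale = TRUE` switches to log-scale residuals, which weight the early
exponential phase more heavily; linear is the default because IOD noise is
roughly additive). Starting values: K from the maximum density, G₀ from the
first positive observation, r from the endpoint log-slope. A seeded
multi-start bounded `optim` serves as fallback. All-zero series return a
flagged no-growth fit; constant series return the r = 0 boundary. At least
four observations are required for the three parameters.

# The synthetic-plate generator

`generatePlate()` renders
`(agar + colonies + halos + glare) × gradient + noise`, clipped to [0, 255],
from a seeded specification, together with exact ground truth (disjoint
label raster, per-colony area and integrated signal, the true background
field). It emulates the phenomena the pipeline must survive: smooth
multiplicative lighting gradients (linear or radial; multiplicative because
that is the physical model the correction inverts), Gaussian agar noise,
dense opaque discs (cosine-rolled edge, 1.5 px) and irregular spotted
cultures (5–30 jittered Gaussian sub-spots, footprint at ≥ 20% of peak),
reflective halos ringing colonies, and glare bands along plate walls.
Colony peak contrast is `density × 90` intensity units over an agar level
of 120 — so density 1 approaches but does not saturate 255 under a 1.2×
gradient — and the default pixel noise is sigma 2, giving the faintest
tested cultures (6 units) a 3-sigma contrast.

What it does **not** emulate: camera optics (vignetting is subsumed in the
gradient, but not defocus or chromatic effects), agar cracks, contamination,
condensation, cross-shaped pin marks, or colony-colony merging on overgrown
plates. Passing tests on generated plates therefore demonstrate the
algorithmic contracts — quantile behaviour, flattening, recovery, exactness
of arithmetic — not robustness to every real-world artefact.

`generateTimecourse()` drives per-position densities along a logistic curve;
disc colonies keep a fixed footprint with contrast tracking G(t)/K, so
integrated signal is proportional to G(t) and closed-loop growth-rate
recovery is well-posed, while spotted colonies also grow their footprint.

# Study conditions used by the tests and acceptance script

Fixture conditions were chosen once, as the regimes the tool is for:

- Plates are 4×6 or 3×4 grids with 40 px tiles (280×200 / 200×160 px
  images), plus one 16×24 (384-format) layout; small enough that the whole
  suite runs in well under a minute, large enough that every stage operates
  in its intended regime.
- *Flattening fixtures*: colony-free plates under linear ±20–30% gradients,
  noise sigma 2. The attainable sd reduction is floored by pixel noise (the
  correction scales noise by the ratio map), so ≥ 80% reduction is asserted
  for gradients that dominate the noise; a weak gradient on a noisy plate
  cannot be flattened by 80% by any method.
- *Faint-spot rescue*: density 0.2 spots (≈ 19 units peak, ≈ 13 after luma
  and the dim corner of a ±20% diagonal gradient) — faint enough that
  uncorrected segmentation loses the dim-corner colonies on every tested
  seed, strong enough that first-pass detection is reliable
  (edge gradients above the noise-gradient 95th percentile).
- *Pseudo-empty accuracy*: dilute spots (density 0.15, radius 8). The
  reconstruction error grows with colony contrast because strong smoothing
  smears bright colonies into the surrounding agar before the cut-out; at
  pinned densities the map is biased upward near colonies. That bias is
  inherent to the smooth-then-interpolate scheme and harmless where it
  occurs: dense cultures do not need accurate correction, faint ones get it.
- *Pinned sizing*: opaque discs of radius 14 px; measured areas agree with
  truth within 5%. The residual is boundary ambiguity: the rendered edge
  rolls off over ±1.5 px and the threshold cuts it slightly outside the
  nominal radius.
- *Mixture recovery*: 20 histograms of 2×10⁵ pixels spanning mixing 0.5–0.99
  and separations 2–10 sigma; median |μ̂ − μ| is ~0.02 intensity units.
- *Closed loop*: 12 frames over 4 days of a 3×4 plate growing at r = 3/day
  from G₀/K = 1%; recovered r is within 2% — the first frames are correctly
  reported as no-growth (IOD 0), and the logistic fit absorbs them.

# Numerical conventions

- Percentiles by nearest rank on sorted values; "strictly above the cutoff"
  resolves ties toward background everywhere.
- Rounding of coordinates and histogram bins is half-away-from-zero.
- Histogram trimming: bins 0 and 255 are zeroed for the fit (saturation
  artefacts), raw counts retained for reporting.
- The mixture optimiser and the logistic fallback derive all randomness from
  an explicit seed and restore the caller's RNG state; the full pipeline is
  a pure function of (image bytes, configuration, seed).
- Degenerate inputs have defined behaviour rather than errors wherever the
  batch contract requires it: zero-contrast tiles (flat flag), blank plates
  (no-growth flag), all-culture scan lines (median fill), zero pseudo-empty
  pixels (ratio clipping), all-zero timecourses (flagged no-growth fit).
  Invalid calibrations and unreadable images are errors; in batch mode a
  failing image is logged and skipped so an overnight run never dies on one
  corrupt file.

# Known limitations

- The lighting model is multiplicative only; additive stray light is not
  corrected.
- Saturated source images violate the correction's assumptions; saturation
  is counted and reported, not repaired.
- The pseudo-empty map is biased upward around high-contrast colonies
  (smoothing smear), slightly deflating their measured contrast; dense
  packing (colony diameter approaching the grid pitch) amplifies this.
- Granularity counts high-gradient pixels over the whole tile, so halos and
  debris inside a tile inflate it.
- No connected-component analysis: measurements are tile-restricted pixel
  statistics, so a culture bleeding far into a neighbouring tile is partly
  credited to that neighbour.
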