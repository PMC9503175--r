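---
title: "Measuring droplet generators from still images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring droplet generators from still images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropmetry)
```

## The measurement problem

A flow-focusing droplet generator emits a train of water-in-oil droplets
through an outlet channel. Its operating state — mean droplet size and,
indirectly, generation rate — drifts over a run as reservoirs deplete and
pressures change. `dropmetry` estimates that state from periodically
captured still images of the outlet channel: each frame yields a set of
droplet diameters; each run yields a time series of per-frame means; and
the run-level result is a quadratic trend of mean diameter against time.

The pipeline is deliberately simple and fully inspectable, in the style
of classical digital image processing rather than learned segmentation:
every stage is a small, testable operation with an exact brute-force
oracle.

## The per-frame model

**Band extraction.** An RGB frame is an `M × N × 3` array of intensities
in [0, 1]. Analysis uses a single colour plane; the red band is the
default because oil transmits strongly in red while dyed water absorbs
it, giving the largest droplet/background separation.

**Thresholding.** A fixed threshold `thr` maps the band image to a
binary mask. The textbook convention marks a pixel foreground when its
value is *greater than or equal to* the threshold; values exactly at the
threshold are foreground. Because dyed-water droplets are *darker* than
oil in the red band, the pipeline's default polarity is inverted
(`foreground_lt`): droplet pixels are those *below* the threshold. The
literal bright-is-foreground convention remains available
(`polarity = "foreground_ge"`) for bright-object scenes.

**Morphological opening.** Erosion followed by dilation with the same
structuring element removes objects smaller than the element while
(approximately) preserving larger shapes. The operators are implemented
from scratch on logical matrices — they are part of the method, not an
imported black box — with the convention that pixels outside the raster
are background: they can veto an erosion but never contribute to a
dilation. The default element is a 3 × 3 full square. Whether the two
noise-suppression stages are read as erosion-then-dilation (one opening)
or as opening-then-size-filtering is configurable; the default is one
opening followed by the size filter.

**Size filtering.** Thresholded scenes contain specks: debris, stray
water particles, wall artefacts. Any 8-connected component with strictly
fewer than `min_area` pixels (default 25 px, roughly a 5 × 5 speck — far
below the ~2000 px² of the smallest real droplet at the default scale)
is cleared; components of exactly `min_area` pixels are kept.

**Region of interest.** Only a rectangular window covering the outlet
channel is analysed, which excludes the channel walls (dark in the red
band, hence foreground under `foreground_lt`) by construction. ROI
coordinates carry their offset so centroids map back to the full frame.

## Boundary tracing

Each droplet is identified by tracing its external boundary with
Moore-neighbour tracing under Jacob's stopping criterion:

1. scan the mask row-major until a foreground pixel is found (it is
   necessarily entered from the west);
2. from the current contour pixel, scan its 8 Moore neighbours clockwise
   starting at the *backtrack* pixel (the background pixel examined
   immediately before the current pixel was found); the first foreground
   pixel becomes the next contour pixel;
3. stop when the start pixel is entered a second time the same way it
   was first entered (same backtrack pixel) — this, rather than "start
   revisited", prevents premature termination where a contour touches
   itself.

A single isolated pixel yields a one-pixel closed boundary. Components
are found by connected-component labelling, so each 8-connected object
is traced exactly once from its topmost-then-leftmost pixel, and holes
inside droplets are ignored.

One property of this algorithm is worth stating precisely, because it is
easy to mis-specify: the traced pixel set of a component is exactly its
pixels with **at least one background 4-neighbour**. A concave-corner
pixel whose only background contact is diagonal (all four side
neighbours foreground) is never entered: whatever the backtrack anchor,
the clockwise ring scan around the adjacent contour pixel reaches the
diagonal continuation first. Such pixels are interior to the walk even
though they touch background within their Moore neighbourhood. The test
suite therefore checks set equality against the 4-exposure edge set and,
separately, that every traced pixel is Moore-exposed.

## Morphometry and calibration

For each traced droplet two radius estimates target the same circle:

- `r_area = sqrt(area / π)`, with `area` the pixel count of the filled
  component;
- `r_perim = perimeter / 2π`, with `perimeter` the cyclic chain length
  of the contour (1 per axial step, √2 per diagonal step).

The reported diameter is `2 × (r_area + r_perim) / 2`, the arithmetic
mean of the two. Pixel diameters convert to millimetres through a
calibration anchored on the known outlet-channel width: 6 mm spanning a
measured `channel_width_px` (default 102.768 px, i.e. 17.128 px/mm).
The conversion is an exact division, so `diameter_mm × px_per_mm`
round-trips to `diameter_px` bit-for-bit.

Two deliberate choices here:

- **Perimeter estimator.** The default is the weighted chain length; a
  raw contour-pixel count is available (`perimeter_method =
  "pixel_count"`) but biases `r_perim` low. The chain estimator has the
  opposite, smaller bias: on digitized circles it overestimates the true
  perimeter by up to ~5%, which propagates to roughly +2% in the
  averaged diameter — the dominant error term of the whole pipeline, and
  comfortably inside the ±3% recovery band the tests enforce for
  droplets ≥ 30 px across.
- **Border exclusion.** A droplet whose contour touches the ROI edge is
  flagged and excluded from the frame mean: a partial disk biases the
  diameter downward. A frame whose only droplets touch the border gets
  droplet count 0 and a *missing* mean, never 0.

## Time-series analysis

Per-frame mean diameters are fitted against capture time by ordinary
least squares with a degree-2 polynomial, `d(t) = a0 + a1·t + a2·t²` —
the empirically adequate model for the slow decay of droplet size over a
run; the degree is configurable for diagnostics. The fit reports
coefficients, residual RMSE and R², and is checked in the tests against
the closed-form normal-equation solution.

Droplet generation *frequency* cannot be measured from stills (no flow
velocity is observable), so the package reports only a per-frame droplet
*count* series and the sign of its least-squares slope, explicitly
labelled a proxy: in a fixed channel segment, a thinning droplet train
tracks a falling generation rate.

**Threshold selection.** The operating threshold is chosen by a sweep:
binarize → open → size-filter → count at each threshold of a grid. The
droplet count is stable for every threshold strictly between the droplet
and oil intensity bands; the sweep takes the maximal contiguous run of
thresholds whose count equals the modal nonzero count and recommends the
run's midpoint. This makes "the value where droplet traces are stable"
operational and reproducible. Note the count outside the plateau is 0
only *below* the droplet band; above the oil band the whole ROI floods
into a single component (count 1), which the modal-count rule ignores.
On the default synthetic scene (droplet red 0.45, oil red 0.9) the
coarse 0.1-step grid recommends 0.7; a 0.025-step grid refines the
plateau to (0.45, 0.9] and recommends 0.6875.

## The synthetic scene generator

No public image set exists for this kind of rig, so the package ships a
ground-truthed scene generator (`scene_spec()`, `render_frame()`,
`render_series()`) whose defaults encode the study conditions:

| parameter | default | meaning |
|---|---|---|
| `image_width × image_height` | 640 × 480 px | camera resolution |
| `px_per_mm` | 17.128 | pixel pitch |
| `channel_width_mm` | 6 mm (≈ 103 px) | known outlet-channel width |
| `oil_rgb[1]` / `droplet_rgb[1]` | 0.90 / 0.45 | red-band contrast |
| `diameter_trend` | (4.1411, −6.8743·10⁻³, 9·10⁻⁶) | mean diameter mm vs s |
| `diameter_jitter_sd` | 0.05 mm | per-droplet size jitter |
| `droplet_spacing_mm` | 6 mm | centre-to-centre spacing |
| `speck_density` | 0 (tests use 0.02/kpx) | debris specks |
| `pixel_noise_sd` | 0 (tests use 0.03) | additive Gaussian noise |
| `brightness_drift_per_s` | 0 | ambient-light drift |

The trend coefficients are chosen so the mean diameter is 4.04 mm at
t = 15 s and 3.05 mm at t = 225 s — the observed operating range — with
a curvature of 9·10⁻⁶ mm/s², monotone decreasing over the run. Frames
are sampled at 15 s intervals from 15 s to 225 s (15 frames per test;
the five-test protocol expects 75).

Design decisions, made once:

- **No anti-aliasing.** A pixel belongs to a droplet iff its centre lies
  inside the disk. This makes the digitized area, the edge set and the
  component count exactly computable by brute force, which is what turns
  the generator into an oracle for the pipeline.
- **Circular droplets on the channel axis.** Only the diameter is
  measured, so ellipticity and off-axis placement add nothing testable.
- **Drift as a global additive offset** clipped to [0, 1] — the simplest
  model that reproduces the failure mode of a fixed threshold under
  changing illumination. `strict = TRUE` refuses to render frames whose
  drift closes the oil/droplet red gap below 0.2.
- **Single-seed determinism.** Every stochastic draw (layout phase, size
  jitter, specks, pixel noise) flows from `seed` and the frame time, so
  the same `(spec, t)` always renders bit-identical rasters regardless
  of the caller's RNG state, and ground truth can be drawn without
  rasterizing (`render = FALSE`, `truth_series()`) for cheap Monte
  Carlo.
- **Whole droplets only.** Droplets that would clip the image edge are
  not emitted, so ground-truth counts are unambiguous; border-touching
  behaviour is tested with hand-built masks instead.
- A positive `spacing_drift_mm_per_s` thins the droplet train over time,
  giving the frequency proxy a known-sign target.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: fluid dynamics (necking, detachment,
satellites), out-of-round or overlapping droplets, partial droplets at
the frame edge, illumination *gradients* (only global drift), sensor
blur/PSF, and JPEG-style artefacts. Results on real rigs depend on the
threshold sweep and ROI being set up for the actual optics.

## Numerical conventions and degenerate inputs

- Coordinates are 1-based `(row, col)`, row-major scan order, matching R
  matrix indexing.
- Intensities are doubles in [0, 1]; 8-/16-bit files are normalized on
  read.
- Threshold comparison: `value ≥ thr` is foreground under
  `foreground_ge`; its complement (`value < thr`) under `foreground_lt`.
- Size filter removes components with area strictly `< min_area`.
- A single-pixel boundary has chain perimeter 0 (pixel count 1); its
  measure is still defined (area 1).
- Empty frames (or frames whose droplets all touch the border) summarize
  to count 0 with `NA` means and are dropped from trend fits.
- Threshold grids should be given at the intended printed precision
  (e.g. `round(seq(0.1, 0.9, by = 0.1), 3)`): binary comparison against
  exact two-level scenes is sensitive to accumulated floating-point
  error in `seq()`.
- Plateau ties: the *longest* run at the modal count wins; among equal
  table frequencies the smaller count is taken first by `which.max`.

## Problem sizes used by the shipped tests

The test suite and the acceptance script are sized to run comfortably on
a laptop: 200 seeded 32 × 32 masks for the morphology and tracing oracle
batteries, digitized disks of radius 3–30 px, four rendered 640 × 480
frames per noise condition for diameter recovery, one rendered 15-frame
series for the measured trend, and 200 ground-truth-only series for
Monte-Carlo trend recovery. These sizes were chosen as the package's own
validation budget; all scale linearly if larger batteries are wanted.

## Known limitations

- The chain-length perimeter bias (~+2% on the averaged diameter) is
  systematic, not random; sub-pixel contour refinement is explicitly out
  of scope.
- Frequency is a count proxy with a sign, never a rate in Hz.
- Touching or overlapping droplets are not split (no watershed); the
  generator never produces them, and on real images they would merge
  into one component.
- A fixed global threshold assumes controlled lighting; the brightness
  drift the generator can emulate is exactly the failure mode that
  requires re-running the threshold sweep.
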