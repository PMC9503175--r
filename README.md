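# dropmetry

Vision-based droplet morphometry for microfluidic droplet generators.

A flow-focusing droplet generator emits a train of water-in-oil droplets
through an outlet channel; its mean droplet size and generation rate
drift over a run. `dropmetry` estimates that state from periodically
captured still images (640 × 480 RGB stills of the outlet channel, one
every 15 s in the reference protocol) and is aimed at anyone monitoring
a droplet generator with a fixed camera: no learned models, just a
classical, fully inspectable digital-image-processing pipeline where
every stage has an exact brute-force oracle in the test suite.

## The method

For each frame, with band image `RBI` (the red colour plane, values in
[0, 1]):

1. **Binarize** at a fixed threshold `ThrV` (default 0.7). Dyed-water
   droplets are darker than oil in the red band, so the default polarity
   marks `RBI(x, y) < ThrV` as droplet; the textbook `≥` convention is
   available.
2. **Open** the mask: `A ∘ B = (A ⊖ B) ⊕ B` with a 3 × 3 structuring
   element `B` (erosion and dilation implemented from scratch), then
   clear components below `min_area` = 25 px. Both stages remove specks
   and debris, not droplets.
3. **Trace** each droplet's external boundary by Moore-neighbour tracing
   (clockwise, backtrack-anchored scan of the 8-neighbourhood) with
   Jacob's stopping criterion: stop when the start pixel is re-entered
   the same way it was first entered.
4. **Measure**: `r_area = √(area/π)` from the filled pixel count,
   `r_perim = perimeter/2π` from the weighted chain length of the
   contour (1 per axial, √2 per diagonal step); the droplet diameter is
   `2·(r_area + r_perim)/2`, converted to millimetres via the known 6 mm
   channel width (default 102.768 px, i.e. 17.128 px/mm).
5. **Summarize and fit**: per-frame mean diameter over whole
   (non-border-touching) droplets, then an ordinary-least-squares
   quadratic trend `d(t) = a0 + a1·t + a2·t²` across the run, plus a
   droplet-count series as a (sign-only) generation-frequency proxy.

A ground-truthed synthetic scene generator (`scene_spec()`,
`render_series()`) emulates the rig — 6 mm channel, droplets decaying
from 4.04 mm to 3.05 mm over 225 s, specks, pixel noise, brightness
drift — so the whole pipeline is validated end to end without any
external data. A threshold sweep (`threshold_sweep()`) operationalizes
threshold selection as the midpoint of the droplet-count plateau.

## Worked example

```r
library(dropmetry)

spec   <- scene_spec(seed = 42)                       # study-condition defaults
series <- render_series(spec, start = 15, interval = 15, duration = 225)
cfg    <- pipeline_config(roi = channel_roi(spec))    # red band, thr 0.7
summaries <- lapply(series, function(el) process_frame(el$frame, cfg))

summaries[[1]]
#> <frame_summary frame_000015> t = 15 s, 5 droplet(s), mean diameter 4.108 mm

head(summaries[[1]]$droplets[, c("area_px2", "perimeter_px", "diameter_mm")], 3)
#>   area_px2 perimeter_px diameter_mm
#> 1     3651     225.1371    4.082321
#> 2     3759     226.3087    4.122431
#> 3     3802     227.1371    4.141647

fit <- fit_diameter_trend(summaries)
fit
#> <trend_fit> d(t) = +4.22655 -0.00718614 t +9.92488e-06 t^2 (mm), n = 15, RMSE 0.02284 mm
round(predict(fit, c(15, 225)), 3)
#> [1] 4.121 3.112
```

The first frame contains five whole droplets of ~4.1 mm; over the
15-frame run the fitted quadratic's negative linear term captures the
shrinking droplets, and the predicted means at t = 15 s and t = 225 s
(4.12 mm and 3.11 mm) recover the generator's true endpoints (4.04 mm
and 3.05 mm) to within the pipeline's ~2% systematic chain-perimeter
bias. A thinning droplet train shows up in the count proxy:

```r
thinning <- scene_spec(spacing_drift_mm_per_s = 0.05, seed = 81)
frequency_proxy(truth_series(thinning))$trend_sign
#> [1] -1
```

See `vignettes/droplet-morphometry.Rmd` for the full account of the
model, parameter defaults, and design decisions.

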