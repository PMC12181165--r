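---
title: "Methods: segmentation, tracking and locomotion metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, tracking and locomotion metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormtrackr)
```

`wormtrackr` turns a recording of dark *C. elegans* on a light substrate
into per-frame and per-worm values of six locomotion metrics. This
vignette documents the model behind each stage, the tunable parameters,
the numerical choices, and what the synthetic validation does and does not
demonstrate about real footage.

## Recording model and user parameters

A recording is an ordered stack of 8-bit grayscale frames at a known frame
rate (7.5 fps is typical for plate crawling, 14 fps for thrashing in
liquid; color input is collapsed to luma first). Three user parameters
govern the analysis:

* **Worm Minimum Size** (`min_size_px`, pixels): smallest contour accepted
  as a worm, applied inclusively (`area ≥ min`). Default 60 px; set it just
  below the area of your smallest animal at your magnification.
* **Unit Conversion Factor** (`ucf`, µm/pixel): scale factor measured from
  a ruler photo at the recording position. Every reported value is in
  micrometer-derived units; `ucf` enters area quadratically, lengths and
  speeds linearly, and curvature inversely.
* **Frame Percentage** (`min_pct`, %): minimum share of the video's frames
  a worm must be observed in to be reported. Transient detections — drifting
  debris, animals at the field edge — rarely persist, so this one filter
  suppresses most false positives. 50% with at least 200 total frames is a
  practical operating point; the filter is applied once, globally, against
  total frame count, and self-collision frames count as observed (the worm
  was detected) even though they carry no metric data.

## Segmentation

The background is the per-pixel temporal median over sampled frames (at
most ~25, evenly strided). Anything that moves vanishes from the median;
anything static — substrate texture, debris, uneven illumination — stays
and cancels in the subtraction, so static debris can never become a
tracked worm. The assumption this buys is that **no pixel is worm-covered
in half or more of the sampled frames**: a worm that advances through its
own body length over the recording satisfies it easily, while an animal
that is both stationary and not undulating will partially absorb into the
background. That is the main failure mode on real footage of paralyzed
animals; for such assays a clean-plate reference frame should replace the
median (the `background_model` type accepts any reference grid).

Each frame's absolute difference from the reference is thresholded at
Otsu's level, floored at five times the robust noise scale
(`5 × mad(diff)`) so that frames containing little or no foreground do not
have Otsu split the sensor noise itself. Speckle is then removed by
opening-by-reconstruction: a 3×3 morphological opening decides which
8-connected components survive, and the survivors are kept pixel-exact.
(A plain opening would also shave single-pixel corners off the worm
outline; reconstruction keeps the measured mask identical to the true
body silhouette on noiseless renderings.) Contours whose area falls below
the minimum size, or whose mask touches the frame border (a clipped body
has unmeasurable area and length), are discarded.

Segmentation of a frame depends only on that frame and the background
model. This is what makes chunked parallel processing safe: frames are
partitioned into chunks that tile the sequence, chunks may be processed in
any order or concurrency, and results merged in frame-index order are
bit-identical to sequential processing. Tracking then consumes frames
strictly in order.

## Midline extraction

Each contour is thinned (Guo–Hall) to a 1-pixel-wide skeleton. On a clean
elongated body the skeleton is a tree whose longest endpoint-to-endpoint
path (found by double breadth-first search with √2-weighted diagonal
steps) is the midline; side branches shorter than 10% of that path are
pruning artifacts of thinning and are ignored. Because thinning retracts
the tips by about half the body width, both midline ends are extended
along their local tangents until they leave the mask — the reported length
therefore spans the full head-to-tail extent rather than stopping short of
the tips.

Two numerical choices matter for accuracy:

* **Arclength-weighted length.** The "midline pixel count" is computed as
  1 + the Euclidean arclength of the pixel path (diagonal steps weigh √2).
  A raw pixel count underestimates oblique paths by up to 29% at 45°,
  which would make length orientation-dependent; the two definitions
  coincide exactly for axis-aligned paths.
* **Path smoothing.** A digital path staircases around the true curve,
  inflating arclength by a few percent on curved bodies. A 5-pixel moving
  average (endpoints pinned) removes the zigzag before length measurement
  and tracking-point placement; on rendered serpenoid worms this brings
  length recovery from about +5% to within 1% of the analytic arclength.

Seven tracking points are placed at arclength fractions 0, 1/6, …, 1; the
midpoint (fraction 1/2, "the middle pixel along the midline") is the
position used for all speed measures.

**Self-collisions.** A worm curled into a closed loop or overlapping its
own body has no unambiguous midline. The posture is flagged when the mask
contains an interior hole, the skeleton contains a cycle, or a pruned
branch exceeds 10% of the main path (body overlap produces genuine
junctions). Flagged frames keep their track ID — the animal never merged
with another — but contribute no metric samples until the posture opens.

## Tracking and collision censoring

Association is greedy best-overlap: an observation is matched to the
active track whose previous mask it overlaps most, with nearest-centroid
within one median body length as a fallback gate (at 7.5–14 fps,
inter-frame motion is small relative to body size, so overlap is almost
always decisive). An observation overlapping **two or more** active tracks
is a worm–worm collision: the participating IDs are terminated, the merged
blob is followed (and drawn in the collision style) but never measured,
and when it resolves into two or more separate size-gated observations,
each emerging worm receives a fresh, never-reused ID. Tracking through
collisions with a geometric body model is deliberately out of scope — data
during contact is confounded for every metric reported here, so it is
censored instead. A track unmatched for more than 5 consecutive frames is
closed; a later detection starts a new ID rather than risking a false
continuation.

## The six metrics

With `A` the contour pixel count, `M` the midline pixel measure, `u` the
conversion factor and `r` the frame rate:

* **Worm area** `= A·u²` (µm²) and **worm length** `= M·u` (µm), per
  un-censored frame.
* **Crawl speed** `= |p₁ − p₀|·u·r` (µm/s) from midpoint positions of
  consecutive observed frames; no value is emitted across gaps or censored
  frames.
* **Curvature** at interior tracking points 1–5 is the signed Menger
  curvature of the triple of consecutive tracking points (in µm):
  magnitude `4·area(x,y,z)/(|x−y||y−z||z−x|)` — the inverse circumradius —
  signed by turn direction (cross-product z-component). Menger curvature
  is unsigned by definition, but stroke detection needs zero *crossings*,
  which only a signed series has. The skeleton has no head/tail identity,
  so each frame's point order is aligned to the previous frame's by end
  proximity; a flip reverses indices and sign together, and the alignment
  memory resets across censored gaps.
* **Strokes** are sign changes at the end-most interior point (index 1 —
  the closest point to the worm's end at which curvature is defined;
  configurable). The new nonzero sign is compared with the last nonzero
  sign, so exact zeros pass through without counting, and no stroke spans
  a censored gap. **Wave initiation rate** `= ⌊strokes/2⌋ /
  tracked-minutes`: partial strokes round down, and the denominator counts
  only un-censored tracked time.
* **Swim speed** takes the midpoint position only at every second stroke —
  one full undulation period — because the lateral jitter of each stroke
  cancels over a period (the treadmill-runner's bobbing head). Intervals
  containing any censored or missing frame are dropped. On simulated
  thrashing with pure drift this recovers the drift speed almost exactly,
  while raw per-frame midpoint speed overestimates it several-fold.
* **Dynamic amplitude** `= |max c| − |min c|` over all defined points and
  frames of a two-stroke interval, exactly as printed; the maximum and
  minimum need not come from the same tracking point. Note this measures
  how far the body bends one way *beyond* the other (symmetric undulation
  gives ≈ 0), not peak-to-peak bend; `amplitude_prose_variant = TRUE`
  switches to `max − min` for the peak-to-peak reading. The discrepancy
  between the two readings is real and deliberate — the printed formula is
  the default.

Per-worm summaries are arithmetic means of defined samples only; gaps are
excluded, never zero-filled.

## The synthetic generator, and what validation shows

`worm_spec`/`render_scene` rasterize serpenoid worms — centerline
curvature `κ(s,t) = κ₀ sin(2πs/λ − 2πft + φ)` integrated into a unit-speed
curve — as tubes of the body width, anchored at a drifting midpoint, over
a light background with additive Gaussian noise, quantized to 8 bits. The
tube is stamped over arclength `[w/2, L − w/2]`, so with its rounded caps
the rendered animal spans exactly the nominal length. Defaults follow the
standard assays: adult-scale bodies (0.7–1 mm long, 55–80 µm wide),
crawling scenes at 7.5 fps with drifts of 95–130 µm/s, thrashing scenes at
14 fps for 30 s at 0.5–2 Hz, κ₀ = 0.003–0.005 µm⁻¹ (bend radii of a
quarter to half a body length). Field worm counts of 20–50 are scaled to
1–3 worms per scene so the full suite runs in minutes; nothing in the
algorithm depends on worm count except collision frequency, which has its
own scripted scene. The curled pose closes the rendered tube into a ring
with about one body-width of end overlap, guaranteeing an interior hole.

The sidecar records, per frame and worm: rendered mask pixel count,
analytic midpoint, signed curvature at the seven tracking fractions, and
measured (not scheduled) collision/border flags — a frame is collision-
flagged only if two rendered masks actually intersect. With the seed
fixed, rendering is byte-identical across runs.

Validation on these scenes demonstrates: length within 1% of analytic
arclength, crawl speed within ~4% of drift, swim speed within 1% of drift
despite lateral jitter, wave rates exact to the wave count at 0.5/1/2 Hz,
peak per-point curvature within 15% of κ₀, zero metric samples inside any
collision or curl interval, and bit-identical output across chunkings and
worker counts. What it does **not** exercise: non-uniform illumination,
defocus, body-width variation along the animal, omega turns short of full
self-contact, occlusions by debris, and contrast regimes where the noise
floor approaches the worm–substrate contrast. On real footage the
segmentation contrast assumption (worm several noise standard deviations
darker than substrate) and the background-motion assumption above are the
two things to check first — the annotated output video makes both failures
visible immediately.

## Degenerate inputs and tie-breaks

Masks that thin to fewer than 7 midline pixels (e.g. a disc) are dropped
with a log message; coincident points raise an undefined-curvature error
and the sample is skipped; collinear triples return exactly zero
curvature; a zero-length observation window is an undefined-rate error.
Greedy association breaks overlap ties by first maximum; tracking-point
placement snaps each arclength fraction to the nearest path vertex, with
the two end points pinned to the path ends.

## Output

`run_analysis()` writes per-metric frame-by-frame and per-worm summary
CSVs (units in the headers), a combined long-format CSV, metric-vs-time
plots, a plain-text run manifest (version, configuration, stage timings,
track/event counts), and an annotated copy of the recording: outlines and
midlines per worm with ID labels, blue while tracked and yellow during
collisions, matching the censoring intervals exactly.
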