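---
title: "Tracking and freezing analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and freezing analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavtrack)
```

behavtrack implements the two standard measurements of single-animal
behavioral video analysis: **where the animal is** (center-of-mass location
tracking) and **whether it is moving** (changed-pixel motion counting with a
freezing classifier). Both are deliberately simple, parameter-sparse
pixel-domain methods — no learned models, no training sets — which makes
their behavior easy to reason about, easy to audit, and fast enough for
batch processing on a laptop. This vignette describes the algorithms, their
assumptions, every tunable parameter, and the design decisions taken where a
convention had to be chosen.

## Location tracking

### The model

Tracking rests on a single assumption: the camera and arena are fixed, so
the only thing that changes between frames is the animal (plus sensor
noise). Each frame is compared against a **reference frame** — an image of
the arena as if the animal were absent — and the animal's position is the
intensity-weighted center of mass (COM) of the suprathreshold difference.

The reference is estimated without an empty-arena recording: sample
`reference_sample_n` frames uniformly at random (default 100, seeded), and
take the **pixel-wise median** across them. A pixel is contaminated only if
the animal occludes it in at least half of the sampled frames, so for any
animal that keeps moving, the median reconstructs the background exactly.
The one failure mode — an animal parked in one spot for most of the session
— is handled by passing an external empty-arena video to `make_reference()`;
batch processing always derives the reference from each video itself so that
slow drift in lighting between sessions cannot leak across files.

Per frame, the pipeline is:

1. **Difference**: `absolute` mode uses `|frame − reference|` and is
   polarity-blind (dark animal on light floor or vice versa);
   `animal_darker` / `animal_lighter` impose a known contrast sign and clip
   the other tail, which halves the noise the later stages see.
2. **Prior-position weighting** (optional): multiply difference values
   outside a `window_size × window_size` square centered on the previous
   frame's COM by `1 − ω`. With `ω = 1` the outside is erased; with
   intermediate `ω` the window can "snap back" if the animal escapes it.
3. **Percentile threshold**: compute the `loc_thresh`-th percentile (linear
   interpolation) of the (weighted) difference image and zero every value at
   or below it. Because the cutoff is relative to each frame's own
   distribution, tracking is invariant to global illumination scaling.
4. **Center of mass** over the surviving values, at sub-pixel resolution.

Step distances are Euclidean norms between consecutive COMs (the first frame
contributes 0), optionally scaled to physical units by a two-point
calibration, and ROI occupancy is scored per frame by even-odd polygon
membership of the COM.

### Why weighting precedes the threshold

The two orders are not equivalent, and the difference matters exactly in the
situation the window exists for. If the threshold ran first, an interfering
object (a hand, a cable) would always survive it — its contrast is as high
as the animal's — and would retain a fraction `1 − ω` of its mass in the
COM. An equal-contrast object 150 px away then biases the COM by roughly
`(1 − ω)/(2 − ω) × 150` px, i.e. about 14 px even at `ω = 0.9`: the window
would need `ω ≈ 1` to be useful, defeating the purpose of fractional
weights. Applying the weight *before* the percentile cut instead lets the
threshold — which is computed from the weighted image and therefore set by
the retained neighborhood around the animal — remove the down-weighted
object entirely. This is what makes fractional `ω` an effective control on
outside influence, and it is the order this package uses.

### Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `diff_mode` | `"absolute"` | — | use a signed mode when contrast polarity is known |
| `loc_thresh` | 99 | percentile | see operating notes below |
| `use_window` | off | — | enable for noisy video or possible intruding objects |
| `window_size` | 61 | px | should comfortably contain the animal plus one step |
| `window_weight` (ω) | 0.9 | — | 0.8–0.9 works well; 1 hard-gates the window |
| `reference_sample_n` | 100 | frames | median sample size |
| `rng_seed` | 1 | — | only stochastic step; recorded in the reference |

Operating notes on `loc_thresh`: the survivor share is `1 − loc_thresh/100`
of the frame (1% by default). Tracking is most accurate when the animal
occupies *less* than that share, so all of it survives together with a thin
margin of noise; crop generously rather than tightly. A pathological case
worth knowing: a perfectly uniform target that occupies *more* than the
survivor share puts the cutoff inside its own (tied) values and can zero the
frame entirely — the tracker then falls back to the prior position with a
warning. Real animals are never uniform, but synthetic tests must respect
this.

### Degenerate inputs and conventions

* Coordinates are 0-based, `x` = column, `y` = row; crops and frame ranges
  are half-open. Sub-pixel COMs refer to pixel centers.
* Survival at the threshold is strict (`> cutoff`); with discrete noise this
  means the cutoff typically lands on the noise ceiling and removes it
  completely.
* An all-zero difference frame yields the prior position (frame center on
  the first frame) plus a warning, so batches never crash on an empty arena.
* The weighting window is clipped at frame borders, not wrapped, and is not
  applied on the first frame (no prior exists).
* Thresholded values keep their magnitudes in the COM; a `binarize` option
  exists but is off by default.

## Freezing analysis

Freezing — immobility barring respiration — is scored from the **motion
signal**: each frame is smoothed with a Gaussian filter (`sigma = 1` px,
reflect boundary, kernel truncated at 4σ), and motion at frame *t* is the
count of pixels whose filtered absolute change from frame *t − 1* strictly
exceeds the **motion threshold MT**. The first frame's motion is defined
as 0 so CSV outputs have no undefined leading value.

MT is calibrated from a short recording of the arena *without* an animal:
pool the filtered absolute differences of all consecutive frame pairs and
take twice the 99.99th percentile of that null distribution. The percentile
is computed on *filtered* differences for consistency with measurement (the
same pipeline sees both), and `calibrate_motion_threshold()` returns the
whole null distribution plus a histogram plot so the choice can be audited.
MT should be held fixed across all animals in an experiment.

A frame is a freezing candidate when its motion falls strictly below the
**freezing threshold FT** (chosen by inspecting the motion trace: freezing
shows as conspicuous low plateaus); a frame is scored freezing iff it
belongs to a maximal run of candidates at least `min_freeze_frames` long.
The minimum duration is supplied in seconds (0.5 s is typical) and converted
via the frame rate, rounding to the nearest frame with a floor of 1.
Freezing is encoded 0/100 so bin means are percentages directly. Both
boundary conventions are strict (`> MT`, `< FT`), matching "exceeds" and
"falls below"; frame 0 may join a freezing run.

## The synthetic-fixture generator

`scene_spec()` / `render_scene()` build videos whose ground truth is known
by construction: an anti-aliased disk (4× supersampled coverage, so
sub-pixel centroid truth is meaningful to <0.1 px) over a constant or
gradient background, plus i.i.d. **uniform integer** noise in `[−a, a]`, an
optional second disk with its own schedule (an "experimenter's hand"), and
scripted freeze epochs. Integer noise is a deliberate choice: its bounded,
heavily tied distribution pins the 99th-percentile cutoff to the noise
ceiling, which keeps fixtures analytically predictable; real sensor noise is
approximately Gaussian and unbounded, so sub-pixel accuracy on these
fixtures demonstrates correctness of the machinery, not a field accuracy
claim. Fixtures also do not emulate shadows, fur texture, perspective, or
lens distortion.

The standard validation conditions (the `fixture_*` presets) are:

* **Tracking**: 300-frame 200×400 video, disk radius 6, intensity 20 on
  background 245 (a black mouse on a light floor), moving 2 px/frame around
  a centered circle; noise amplitude 5 for the noisy variants. Noisy-video
  scenarios are analyzed with the recommended window settings
  (`ω = 0.9`, 61 px): with a 113-px target in an 80,000-px frame, the 1%
  survivor share is mostly noise-adjacent pixels, and the handful of pixels
  where the 100-frame median reference retains a ±1.5–2 gray-level error
  can otherwise carry percent-level COM mass.
* **Distance**: 50 independent traversals of an exact 400-px out-and-back
  path (201 frames, 120×280, noise amplitude 5).
* **ROI**: a 320-frame circular path and a rectangle whose edge bisects the
  gap between trajectory points so that exactly 120 frames (37.5%) are
  inside.
* **Interference**: an equal-area distractor disk of 38 gray-level contrast
  riding 150 px from the animal on the second half of the frames. The
  contrast is chosen so the distractor genuinely corrupts unweighted
  tracking (>20 px error) while its down-weighted value (3.8) sits below
  the threshold the retained window noise sets (≥4).
* **Freezing**: a 300-frame 120×160 walk (3 px/frame) holding still during
  scripted epochs `[45,95) ∪ [130,170) ∪ [220,253)` — 123 frames = 41%,
  each epoch ≥ 0.5 s at 30 fps — with noise amplitude 3 and MT calibrated
  from a 50-frame empty fixture. A freeze interval `[a, b)` means zero
  displacement at frames `a..b−1`, so the frame-differencing motion signal
  is low on exactly those frames and the scripted epochs equal the detected
  epochs under the same run-length rule.

These problem sizes keep the full validation suite comfortably within a few
minutes on one CPU while leaving every mechanism (median reference,
percentile tie structure, window rescue, run-length logic) genuinely
exercised.

## Numerical choices

* Percentiles everywhere use linear interpolation between order statistics
  (R's default `type = 7`); an explicit sort-and-interpolate oracle in the
  test suite pins this down.
* The pixel-wise median over sampled frames matches `median()` (mean of the
  two central order statistics for even counts) and is computed in C++ for
  speed; a brute-force R oracle checks it.
* Gaussian filtering is separable band-matrix convolution with half-sample
  reflect boundaries; the test suite compares it against a dense
  convolution oracle. The in-package implementation exists because the
  reflect-boundary convention had to be controlled exactly.
* 8-bit grayscale PNG frame sequences are the on-disk video format, so
  written fixtures round-trip bit-exactly; in-memory and lazily generated
  streams skip the codec entirely. Streams expose one frame at a time, so
  memory use is independent of video length.
* CSV output is plain comma-separated UTF-8 with `.` decimals and no row
  names, making batch and single-file outputs byte-comparable.

## Known limitations

Single animal only; center-of-mass only (no pose, heading, or multi-point
tracking); rectangular crops (no polygonal masks); freezing is not
distinguishable from sleep; no real-time operation. Container video formats
(avi/mp4/wmv/mpg) require conversion to an image sequence before analysis;
any ffmpeg-style tool can produce one (`ffmpeg -i in.mp4 frame_%06d.png`)
together with a one-line JSON sidecar giving the frame rate.
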