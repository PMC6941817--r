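---
title: "Motion-predictive MR imaging of a crawling worm: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-predictive MR imaging of a crawling worm: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cartesian MRI fills one k-space line per repetition time TR; a 64-line
image therefore integrates over `64 * TR` of real time. A freely crawling
*C. elegans* translates about one body length in ten seconds and undulates
continuously, so over a 5.3 s acquisition (TR = 83 ms) the target slice
moves by hundreds of micrometres — far more than the field of view of a
microscopy-grade sequence. The package simulates the closed-loop remedy: an
optical camera tracks the worm, a predictor anticipates where a selected
cross-sectional slice will be at each upcoming repetition, and the gradient
center is steered there before the line is encoded.

Because real worm videos and the electron-microscopy slice stack used to
texture the cross-sections are not distributable, the package ships a
synthetic-data module that generates both with exact ground truth. Every
quantitative claim made by the test suite is measured on that synthetic
data.

# The locomotion model

The generator represents crawling as *sliding along the body's own track*:
a static planar curve (the track) is built from a slowly drifting heading
(a random walk in curvature, `heading_drift_std` radians per frame of
forward travel) decorated with a sinusoidal lateral wave (amplitude
`undulation_amplitude`, wavelength `undulation_wavelength`). The body
occupies a fixed 1.2 mm arc-length window of this curve and the window
advances at `speed` = 130 um/s. This makes "each segment follows its
predecessor" — the assumption behind the coordinate predictor — exactly
true in the limit, which is also what the tracks of real crawling worms
look like.

Two perturbations break the ideal:

* **Wave slip** (`undulation_frequency`, default 0.01 Hz): the lateral wave
  drifts slowly relative to the substrate. Real worms do not retrace their
  own track perfectly; without slip a *fixed* (no-prediction) field of view
  keeps being fed body content forever and the no-prediction arm of the
  simulations becomes unrealistically good. The default is chosen so that
  the wave phase moves little within the longest prediction horizon
  (0.83 s) but appreciably within a 5.3 s acquisition — the regime in which
  prospective prediction is useful at all.
* **Head jitter** (`head_jitter_std`, default 0.25 rad/frame): the anterior
  10% of the body is rigidly rotated about the s = 0.1 point by an
  independent random angle each frame (rigid rotation preserves arc
  length exactly). This models the fast exploratory head movements that
  make the head region unpredictable.

The undulation amplitude (120 um) and wavelength (800 um, i.e. 2/3 of the
body length) are free parameters of the model chosen to match typical
crawling postures; neither is prescribed by the tracking or imaging code.
The half-width profile (max 45 um) uses a blunt head ramp, near-constant
mid-body caliber and a conical posterior quarter, as in adult worms; the
profile also sets the radii of the cross-section phantoms, so tail slices
genuinely contain less tissue.

Randomness is fanned out from one integer seed into independent substreams
(track shape, head jitter, phantom texture, background texture, per-frame
pixel noise), so datasets are bit-reproducible and any single frame can be
regenerated in isolation.

# Phantoms

The cross-section library emulates an electron-microscopy slice stack and
is labelled synthetic throughout. Source images are bright-background
sections with an outer cuticle ring, four muscle quadrants and an off-center
intestine lumen whose size and orientation vary smoothly along the body;
the processing chain then (1) zeroes the border-connected bright
background, (2) inverts intensities inside the body so low-density regions
appear dark as they would in MR, and (3) block-averages to 64 x 64
(area-weighted, to avoid aliasing). Slab k of 50 is centered at
s = (k - 0.5)/50; a 1.2 mm body yields 24 um slabs. Inversion is an
involution on the background-removed source, which the tests exploit.

# Detection chain

* **Preprocessing**: grayscale block-mean downsampling by 9 (partial edge
  blocks are partial means), preserving the [0, 1] range.
* **Background**: the worm is darker than the background, so the default
  estimator is an upper temporal quantile (0.975) followed by one masked
  re-averaging pass. A per-pixel temporal median is also provided, but note
  that it is only exact when the worm covers a pixel in under half the
  frames — false for a slow worm that largely retraces its own track over
  a 10 s video.
* **Segmentation**: Otsu threshold on the absolute difference image, with
  a hysteresis extension (growth into the 0.4 x Otsu level) that recovers
  the thin tail, largest connected component, hole filling, and a
  minimum-area gate (~25% of the expected worm area) for the worm-absent
  signal.
* **Skeleton**: Zhang–Suen thinning, longest-geodesic path extraction
  (which drops spurs), ordering from the endpoint nearest the detected
  head, light smoothing, extension of both tips to the mask boundary
  (thinning retracts tips by about the local half-width), and a
  raw-resolution refinement that moves every node to the darkness-weighted
  centroid of the intensity profile across the body. The refinement is
  what brings the center line from downsampled-pixel accuracy (~27 um
  grid) to roughly raw-pixel accuracy; without it the prediction errors
  are several MR voxels even for a perfect predictor.
* **Head**: the endpoint with the larger accumulated absolute
  inter-frame-difference mass over the last 10 frames; scores within 10%
  of each other are low-confidence and fall back to the endpoint nearest
  the previous head.
* **Speed**: for an inextensible body sliding along its own shape, the COG
  velocity equals (V/L) times the head-to-tail chord vector, so the
  tracker projects the per-frame COG displacement (least-squares slope of
  the last five smoothed positions) on the chord and divides by its
  squared length. This is exact for both sliding and rigid translation and
  well conditioned for bent postures, unlike projection on a single local
  tangent, which underestimates V by the mean cosine of body bending. The
  instantaneous estimate genuinely oscillates with the undulation cycle,
  so it is exponentially smoothed over time (weight 0.2) before use by the
  predictor. On a bending, slipping worm the estimate carries a few percent
  of bias and noise; the tests assert 10% accuracy under the estimator's
  stated conditions (pure translation at 0.13 mm/s).

# Prediction

The COG is extrapolated by a least-squares line through its last five
smoothed positions (a two-point mode is available). A POI at coordinate s
is predicted dk frames ahead at `s_c = max(0, s - v * dk)` *on the current
center line*: body parts move along the shape, so the material that will
occupy the slice is the material currently ahead of it. Predictions past
the head clamp to s = 0 (the stated behaviour); past the tail they clamp
to 1 and are flagged. No future-shape estimation is attempted.

# Acquisition model

The sequence is a gradient-echo Cartesian acquisition reduced to its
Fourier-sampling contract: per repetition (TR = 83 ms, locked to the frame
interval) the field of view — 64 x 64 voxels centered at the gradient
center G_C, phase-encode axis xi in the dish plane along the local
center-line normal, frequency-encode axis eta vertical (xi . eta = 0
exactly) — is sampled from the posed phantoms, and line J receives row J of
the centered 2-D DFT of that image (DC at J = N/2 + 1; line 1 carries the
initial phase -pi). No relaxation, no off-resonance, uniform coil
sensitivity, and motion within one line is ignored (very-short-echo
assumption). The echo time TE (4 ms) therefore only participates in
validation (TE < TR) and in the imageability bookkeeping.

Each FoV column is projected onto the frame's center-line polyline,
yielding an arc coordinate and a signed in-plane offset; content then comes
from the slab containing that arc position, sampled at that offset. An
off-center G_C thus shifts the cross-section with zero-fill (in-plane
error) and/or substitutes neighbouring-slice content (along-body error
beyond half a slab) — the two artifact mechanisms of a mis-steered
gradient. Slab boundaries belong to the lower-index slab, and a requested
slice coordinate is snapped to the nearest slab center (the imaged slice is
always one of the 50 slabs; without snapping, s = 0.5 sits exactly on a
boundary and per-line projection noise flips between adjacent phantoms).

Four gradient-center policies are provided: `prediction` (G_C and xi from
the predicted coordinate on the detected center line, predicted `horizon`
frames before each line), `no_prediction` (fixed at the slice's
ground-truth position at a reference frame — the acquisition start for the
body-position paradigm, start + horizon for the horizon paradigm),
`oracle` (follows the ground truth; upper bound), and `static` (worm
frozen; exact round trip, used as a numerical identity check).

The MR voxel defaults to the phantom's in-plane resolution (1.6 um, FoV
102 um); the resolution paradigm instead anchors it to the optical pixel:
a ratio r:1 means r MR voxels per optical pixel, voxel size 3/r um.

# Evaluation

`ssim()` is the mean local structural similarity with the canonical
settings (11 x 11 Gaussian window, sigma 1.5, K1 = 0.01, K2 = 0.03),
dynamic range from the reference image, computed over the interior region
whose windows lie fully inside the image, with negative means clipped to 0
so the score lies in [0, 1]. Note one property relevant to interpretation:
where both reference and reconstruction are empty (background), local
similarity is 1, so slices whose cross-section fills little of the FoV
(head tip, tail tip) carry an optimistic floor for *any* reconstruction,
including an empty one. At the extreme tail (s = 1, a ~12 um disc in the
102 um FoV) this floor can even rank an empty no-prediction reconstruction
above a slightly misplaced prediction-based one; per-slice mode comparisons
are therefore only meaningful where the cross-section carries substantive
content, and the package's tests assert them there.

The three simulation paradigms reproduce the study design: body position
(s = 0.02, 0.5, 1.0 at horizon 1), resolution ratio (s = 0.72 at ratios
1:1, 2:1, 4:1), and horizon (s = 0.52, horizons 1–10, plus the four-slice
grid s = 0.1, 0.3, 0.5, 0.9 for the statistical summary). The improvement
ratio aggregates per-video means first, then across videos.
`classify_imageability()` encodes the three timescale regimes
(t_motion <= TR: not imageable; TR below both t_motion and t_pred:
imageable with contrast restrictions; t_pred < TR < t_motion: imageable
without restrictions); ties are resolved conservatively (equality with TR
counts as the more restricted regime).

# Problem sizes and numerical choices

The test suite and the acceptance checks run on eight seeded default
videos (120 frames each, 1024 x 384 px at 3 um/px), a 4-slice x 10-horizon
x 2-mode acquisition grid, and a single-slice horizon sweep; the whole
suite completes in a few minutes on one core. Other fixed choices:
bilinear interpolation for all off-grid sampling (with zero fill outside),
arc-length quantities on a 2 um fine grid, pose polylines of 101 points,
skeleton tie-breaks by first occurrence, and fftshift-based centering
(valid for even grid sizes, which the 64-point contract guarantees; the
encoder is verified against a direct double-sum DFT oracle to 1e-10).

# What passing tests do and do not show

The synthetic worm reproduces the kinematic facts the study states (length,
speed, frame rate, duration, undulation style, erratic head) and the
qualitative regime of the published evaluation (prediction quality ~0.5 at
an 83 ms horizon decaying roughly linearly to ~0.25 at 830 ms; an overall
improvement factor of roughly 3x over no prediction). It does not model
3-D torsion, omega turns or reversals, illumination drift, defocus, or
non-worm debris; segmentation and head detection on real videos are
correspondingly harder than the tests demonstrate. TEM-to-MR contrast
conversion is explicitly cosmetic — any morphologically correct slice
library supports the conclusions, which concern geometry, not contrast.
Absolute similarity values on real data depend on optical resolution,
detection accuracy and cross-section size in ways the resolution paradigm
only samples coarsely; the supported conclusions are the ordering and
trend properties the tests assert, not absolute scores.
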