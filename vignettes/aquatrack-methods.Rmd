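---
title: "Tracking camouflaged aquatic animals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking camouflaged aquatic animals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquatrack)
```

aquatrack is a tracking-by-detection pipeline for underwater animals that are
camouflaged, move nonlinearly, and disappear for long stretches — the
monitoring situation typified by the Chinese giant salamander in stream
enclosures. A detector (outside the scope of this package) proposes per-frame
bounding boxes with confidences; aquatrack links them into identity-stable
trajectories and converts those trajectories into behavior labels and
day/night rhythm summaries. This vignette explains the models, the parameters
that matter, the synthetic data the package tests itself on, and the numerical
choices behind the implementation.

## The association metric: BIOU

Per-frame association compares each track's *predicted* box with each
detection. Plain intersection-over-union saturates in exactly the situations
this application cares about: low-contrast detections jitter, non-rigid bodies
deform, and overlap ties cannot distinguish candidates. BIOU extends IoU with
two penalties,

$$\mathrm{BIOU} = \mathrm{IoU} - \frac{\rho^2(b_p, b_d)}{c^2} - \alpha v,$$

where $\rho^2$ is the squared center distance, $c$ the diagonal of the
smallest box enclosing both, and
$v = \tfrac{4}{\pi^2}\left(\arctan\tfrac{w_p}{h_p} - \arctan\tfrac{w_d}{h_d}\right)^2$
the aspect-ratio disagreement. By default $\alpha$ is the CIoU-style adaptive
weight $v / ((1 - \mathrm{IoU}) + v)$; a fixed $\alpha$ is available in
`biou_params()`.

What makes BIOU biological is the *elongation prior*. Swimming giant
salamanders keep a body length-to-width ratio in roughly $[4, 8]$;
square-ish boxes are rocks, not animals. The prior is applied as a
multiplicative escalation of the aspect weight,
$\alpha \leftarrow \alpha \cdot \exp(\beta \cdot d(e, [e_{lo}, e_{hi}]))$,
where $e = \max(w,h)/\min(w,h)$ is the predicted box's elongation and $d$ its
distance to the prior interval (zero inside). We chose the exponential factor
as the minimal smooth realization of an "escalating" penalty; $\beta$
defaults to 2 per elongation unit. Because axis-aligned boxes of diagonally
oriented or bent animals are less elongated than the body itself, the default
box-frame interval is relaxed to $[1.5, 8]$ and is configurable. The prior
fires on the predicted box only: a track that has drifted onto a square
structure is penalized when it tries to continue, while a legitimate animal
track is never punished for meeting a deformed detection. Note the penalty
multiplies $v$: it acts exactly when the two boxes *disagree* in aspect,
which is the hijacking case, and stays silent for square-matching-square
(that case is handled by track lifecycle, not geometry).

`iou()`, `giou()`, `diou()` and `ciou()` are provided both as ablation
baselines and because the identities between them (`BIOU <= DIoU <= IoU`,
equality under zero penalties, `biou(prior_beta = 0)` ≡ `ciou`) give the test
suite sharp correctness oracles.

## The trajectory predictor

The package replaces the constant-velocity (Kalman-style) motion model with a
small sequence model. Each track's recent history is a sequence of 6-D states
$h_i = (x_i, y_i, w_i, h_i, \Delta x_i, \Delta y_i)$ over the last $L = 10$
frames (0.33 s at 30 fps). Two *parameter-independent* Transformer encoder
branches process strictly separated inputs: a geometric branch sees
$(x, y, w, h)$ — where the animal is and how its silhouette evolves — and a
motion branch sees only $(\Delta x, \Delta y)$ — accelerations, direction
changes, stop-and-go transitions. Each branch has 2 encoder layers with 4
attention heads and a feed-forward width of 128. The final-time-step features
of the two branches are concatenated and decoded by an MLP (hidden sizes 128
and 64) into a 4-D offset $(\Delta\hat x, \Delta\hat y, \Delta\hat w,
\Delta\hat h)$; the predicted box is the previous box plus the offset, with
sides clamped to a positive floor.

Histories shorter than $L$ are left-padded by repeating the earliest state
with zero displacement, so one code path serves young and mature tracks;
tracks with fewer than two observations use the persistence fallback.

Training minimizes $L_{total} = L_{reg} + L_{velocity}$. $L_{reg}$ is a
smooth-L1 distance between predicted and target box parameters. The velocity
constraint encodes a physiological fact — burst swimming tops out around
$v_{max} = 2$ m/s for an adult — as a one-sided quadratic:
$L_{velocity} = \lambda \max(0, v_{pred} - v_{max})^2$ with
$v_{pred} = k \cdot \mathrm{fps} \cdot \lVert \text{pixel offset} \rVert$,
$k$ the meters-per-pixel calibration. The de-normalization chain (normalized
offset → pixels → meters → per second) is the only dimensionally consistent
reading that yields m/s; `predicted_speed()` implements it and the behavior
module reuses the same convention. $\lambda$ defaults to 1.

### Numerical choices

The encoder, its backward pass and the Adam optimizer are implemented
directly in vectorized R; every layer's analytic gradient is checked against
central finite differences in the test suite. Offset regression through a
small Transformer is numerically delicate, and five conditioning choices
matter enough to record:

* **Input standardization.** Normalized per-frame displacements are $O(10^{-3})$,
  far below the scale of the positional encoding. Internally, geometric
  positions are centered on the sequence's final state, and displacements and
  offsets are scaled to $O(1)$. This is an affine reparameterization; the
  interface stays in normalized image units.
* **Pre-normalization layers.** Encoder layers normalize *before* each
  sub-block (`H + MHA(LN(H))`, `H + FFN(LN(H))`) rather than after. The
  unnormalized residual stream preserves input amplitudes end to end —
  essential for a regressor whose output is a small displacement, since
  post-norm layers whiten exactly the magnitude information the decoder
  must reproduce.
* **Persistence skip.** The decoder predicts a residual around the last
  observed displacement. A freshly initialized model therefore *is* the
  constant-velocity baseline, and training learns the nonlinear correction
  (turn curvature, oscillation phase) rather than re-deriving persistence.
* **Component-balanced loss.** The smooth-L1 regression is evaluated on
  residuals standardized per box component, relative to the persistence
  initialization. Raw normalized units would put gradients below Adam's
  $\epsilon$; and because the persistence skip already explains most of the
  center offsets, the center residuals are an order of magnitude smaller
  than the size residuals — without balancing, the size terms monopolize
  the shared encoder's gradient and center accuracy stalls at (or below)
  the constant-velocity baseline. Standardizing preserves each component's
  minimizer.
* **Leaky activations.** The feed-forward and decoder nonlinearities are
  leaky ReLU (slope 0.01): the small decoder is otherwise prone to a
  dead-unit plateau at learning rates a few times the default.

Default training parameters follow the reference schedule (500 epochs, batch
size 8, learning rate 0.001, Adam). The package's own tests and the
acceptance script train smaller models (embedding width 16) for tens of
epochs on a few thousand histories — sizes chosen so the full suite runs
comfortably on a single CPU; the loss curves show convergence at those sizes,
and `predictor_config()` exposes every knob for larger runs.

## Three-stage cascaded association

Matching proceeds from cheap and confident to expensive and forgiving; each
stage consumes only the residue of the previous one, and no track or
detection is ever matched twice.

1. **Motion consistency.** Hungarian assignment on $1 - \mathrm{BIOU}$
   between predicted boxes and detections, gated at $\tau_{biou}$. The gate
   adapts to the scene: 0.30 in daytime and occlusion scenes, 0.20 at night
   and in turbid water, where localization degrades and a stricter gate would
   sever tracks prematurely. The same scene switch lowers the detection
   confidence floor (0.5 day, 0.3 night/turbid), keeping low-contrast
   animals in play and letting association vouch for them.
2. **Feature fusion.** Leftover pairs are scored by
   $S = \omega S_a + (1 - \omega) S_m$ with $\omega = 0.7$: appearance cosine
   between the track's memory and the detection embedding, and the
   Bhattacharyya coefficient between flow-direction histograms (8 angular
   bins, magnitude-weighted). Track memories update by exponential moving
   average (momentum 0.9) while the track is active. Pairs missing one
   feature fall back to the other; the assignment is gated at
   $\tau_s = 0.5$, the midpoint of the fused range. When raw frames are
   unavailable the embeddings and histograms arrive via the feature sidecar
   table; the tracker never fabricates optical flow.
3. **Dormant reactivation.** Tracks unmatched for more than `max_age` (30)
   frames move to a dormant buffer that freezes their appearance memory and
   last predicted position. A detection still unmatched after stage 2 can
   revive a dormant track only if every gate holds: dormancy younger than
   `dormant_ttl` (300 frames = 10 s), center within a motion-consistency
   radius (3x the track's median pre-dormancy speed per elapsed frame,
   floored at 0.01), appearance cosine at least 0.5, and combined confidence
   $0.5 S_a + 0.5 (1 - d / r_{gate}) \ge 0.8$. The equal-weight combination
   and the 0.8 bar are package choices — the criterion is deliberately a
   high one, since a wrong reactivation is worse than a new identity.

Elapsed dormancy is measured from the track's last successful update rather
than from the formal dormancy transition; the track has been drifting since
it was last seen, and the spatial gate should scale with that full interval.

The assignment solver is a Jonker-Volgenant shortest-augmenting-path
implementation (the same algorithm family as SciPy's
`linear_sum_assignment`), with infeasible pairs excluded and equal-cost ties
broken toward lexicographically smaller (row, column) pairs via an
infinitesimal cost tilt — this makes every association, and hence every
tracker run, bit-reproducible. The test suite checks it against an
exhaustive-permutation oracle on hundreds of random rectangular matrices.

## Track lifecycle

New detections spawn *tentative* tracks that confirm after `n_init = 3`
consecutive hits (a tentative track dies on its first miss). On
confirmation, the buffered boxes are emitted retroactively, so a clean run
reproduces its input from the first frame. Active tracks that miss a frame
coast internally on their own predictions — these predicted boxes are never
emitted, only matched detections reach the output — and turn dormant after
`max_age` misses. Dormant tracks die after `dormant_ttl` frames. Identifiers
are strictly increasing and never reused. Frames are 0-based internally;
MOTChallenge files are 1-based pixel top-left and are converted only at the
I/O boundary.

Scene classification, when image statistics are available, uses a simple
rule: nighttime when mean brightness falls below `b_night`, turbid when both
pixel variance and edge density are low, occlusion only by explicit
override. The default thresholds are placeholders to be calibrated per
deployment; every test in this package sets the scene explicitly.

## Behavior classification and rhythm

Trajectories are reduced to per-frame kinematics: normalized center
displacement $\Delta d$, speed $v$ in m/s (same calibration chain as the
predictor, smoothed by a width-5 centered running median), and heading. The
rule set is:

* **stationary** — $\Delta d < 0.005$ and $v < 0.02$ m/s sustained for at
  least 3 s;
* **swim-breathing** — $\Delta d > 0.01$ and $v > 0.08$ m/s;
* **foraging** — $0.02 \le v \le 0.08$ m/s with cumulative absolute heading
  change above 60° within some sliding 10 s window.

$\Delta d$ thresholds are in normalized image units, matching the state
encoding's normalization. Body undulation, which accompanies ventilatory
swimming in the field, is not computable from boxes alone and is omitted
from the rule; an aspect-ratio-oscillation proxy can be enabled in
`behavior_rules()` if desired. Rule conflicts resolve by precedence
stationary > swim-breathing > foraging (most to least restrictive
evidence). "Direction change" is read as cumulative absolute heading change
(an `instantaneous` alternative is selectable). Runs shorter than 1 s merge
into their predecessor to suppress frame-level flicker. `rhythm_summary()`
splits wall-clock time at 06:00/18:00 into day and night and reports
time-weighted label proportions, excluding unclassified time from the
denominator.

## The synthetic benchmark

The study's videos are not deposited, so the package carries a seeded
generator that emulates their statistical structure rather than their
pixels. Ground truth alternates per target among four regimes — stationary
jitter around a resting point, smooth-ramped bursts capped below 2 m/s,
constant-speed arcs of sampled radius, and sinusoidal transverse oscillation
— with boxes derived from an elongated body reorienting with heading
(projection of the body ellipse, which keeps elongation realistic without
modeling rotation) and reflecting off the image border. Detection corruption
is scene-dependent: miss probabilities and confidence distributions differ
between daytime, nighttime and turbid presets; localization jitter is
Gaussian; false positives are Poisson, square-ish and low-confidence;
scripted occlusion events silence a target completely; optional persistent
clutter objects emit rock-like repeated false detections. Appearance
embeddings are per-identity Gaussian means with isotropic noise at a
separation-to-noise ratio of 4 — informative, deliberately not perfect — and
flow histograms concentrate around the true heading (uniform when nearly
still).

Default condition values (jitter 0.002 of image width in daytime, night miss
rate 0.15, confidence means 0.8 day / 0.55 night, and so on) were fixed once
as plausible magnitudes for fixed-camera underwater monitoring; presets only
vary what the corresponding field condition varies. What the generator does
*not* emulate: correlated (non-Gaussian) localization errors, partial-box
truncation at occlusion boundaries, appearance drift with lighting, and
detector-specific confidence calibration. Tests passing on this benchmark
demonstrate that each mechanism does its job under controlled degradation;
they do not certify field performance.

The `occlusion` preset uses 2 s full disappearances — deliberately longer
than the tracker's 30-frame dormancy onset, so reactivation (not mere
coasting) is what preserves identity. The `maneuver` preset (turning and
oscillation regimes only) is the predictor's training diet: it is exactly
the motion family where constant-velocity extrapolation is systematically
wrong.

## Evaluation

`mot_metrics()` implements CLEAR-MOT accounting: per-frame gt-hypothesis
correspondence by Hungarian IoU matching at a 0.5 gate with the standard
carryover rule (a surviving pair keeps its match before re-assignment), FP
and FN accumulation, identity switches counted against the last known match
of each ground-truth identity, fragmentations counted as resumed coverage
gaps, and $\mathrm{MOTA} = 100 (1 - (FP + FN + IDs) / \#gt)$. `idf1()`
solves the global track-to-track assignment (with FP/FN dummies) and reports
the identity F1. The suite validates both against hand-counted fixtures and
an independent brute-force CLEAR implementation that matches by exhaustive
permutation search. HOTA is intentionally absent. `predictor_aed()` reports
the mean Euclidean center distance of next-frame predictions on held-out
histories — the predictor's accuracy measure.

## Known limitations

* The tracker consumes detections; there is no video decoding, detector, or
  optical-flow computation in-package (features arrive via the sidecar).
* The appearance model is a pluggable embedding; no re-identification
  network is trained here.
* Rotated boxes and mask overlap are out of scope; elongation is the
  rotation-agnostic proxy.
* Scene classification thresholds ship uncalibrated; supply explicit scene
  labels where possible.
* At synthetic scale some ablation contrasts are small: fragmentation counts
  are driven mostly by detection gaps, which no association variant can
  remove, so ablations separate most clearly on identity metrics (IDs,
  IDF1).
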