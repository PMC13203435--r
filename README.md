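# aquatrack

Multi-object tracking and behavioral rhythm analysis for camouflaged
aquatic animals.

Fixed underwater cameras watching animals like the Chinese giant salamander
produce detection streams that defeat off-the-shelf trackers: the animals
hold still for hours, then burst, turn and oscillate nonlinearly; detection
confidence collapses at night and in turbid water; bodies are elongated and
deform; and individuals vanish into caves for many seconds. aquatrack is a
tracking-by-detection pipeline built around that regime, for ecologists and
computer-vision practitioners who already have per-frame detections (e.g.
from a YOLO-family detector) and need identity-stable trajectories and
behavior budgets.

Four mechanisms do the work:

* **BIOU association.** Boxes are compared by
  `BIOU = IoU − ρ²(b_p, b_d)/c² − α·v`, overlap minus a center-distance
  penalty and an aspect-consistency penalty `v = (4/π²)(arctan(w_p/h_p) −
  arctan(w_d/h_d))²`. The weight `α` escalates exponentially when the
  predicted box's elongation (long/short side) leaves the biological prior
  interval — swimming salamanders stay near body ratios 1:4 to 1:8, so
  square boxes are rocks. IoU/GIoU/DIoU/CIoU are included as baselines.
* **A dual-branch Transformer trajectory predictor** replacing the
  constant-velocity/Kalman assumption: one encoder branch reads the
  geometric sequence `(x, y, w, h)`, a second reads displacements
  `(Δx, Δy)` over the last `L = 10` frames; their final-step features are
  fused and decoded to the next-frame box offset. Training adds a
  biomechanical velocity-cap loss `λ·max(0, v_pred − v_max)²` with
  `v_max = 2 m/s`. The network, backprop and Adam are implemented in plain
  R and gradient-checked in the tests.
* **Three-stage cascaded matching**: gated BIOU + Hungarian fast matching;
  fused appearance/motion re-matching (`S = 0.7·S_a + 0.3·S_m`, cosine on
  embeddings and Bhattacharyya on flow-direction histograms); and
  reactivation of dormant tracks from a long-term memory buffer, so a
  30-second disappearance does not cost the identity.
* **Rule-based behavior classification** (stationary / swim-breathing /
  foraging from displacement, calibrated speed and heading change) with
  day/night (06:00–18:00) rhythm summaries.

A seeded synthetic scenario generator emulates the study conditions
(motion regimes, scene-dependent misses and confidences, jitter, false
positives, scripted occlusions, appearance embeddings), and a CLEAR-MOT
evaluator (MOTA, IDF1, identity switches, fragmentations, FP, FN, AED)
closes the loop so every mechanism is testable without the original videos.

## Worked example

```r
library(aquatrack)

# 1. Simulate a nighttime scenario: 3 targets, 600 frames at 30 fps
sc <- simulate_scenario(preset("nighttime"), seed = 1)
sc
#> <aquatrack_scenario> 3 targets, 600 frames, scene nighttime, 1568 detections

# 2. Track it (constant-velocity prediction; pass a trained predictor via
#    tracker_config(predictor = ...) to use the Transformer)
trk <- track_sequence(sc$detections, tracker_config(scene = "nighttime"))

# 3. Score against ground truth
mot_metrics(sc$truth, trk)
#> # A tibble: 1 x 8
#>    MOTA  IDF1   IDs  Frag    FP    FN  n_gt n_matches
#>   <dbl> <dbl> <int> <int> <int> <int> <int>     <int>
#> 1  84.4  77.0     1   227     5   274  1800      1526

# 4. Behavior budget of the tracked trajectories
kin <- kinematics(trk, k = 0.01, fps = 30, image_size = c(1000, 1000))
lab <- classify_behavior(kin, behavior_rules(), fps = 30)
rhythm_summary(lab, start_time = "20:00:00", fps = 30)
#> # A tibble: 2 x 4
#>   period label          seconds proportion
#>   <chr>  <chr>            <dbl>      <dbl>
#> 1 night  swim_breathing   43.0           1
#> 2 night  unclassified      7.87         NA
```

MOTA of 84.4% means the sum of false positives, misses and identity
switches is 15.6% of the 1800 ground-truth boxes — with a 15% nighttime
miss rate injected by the generator, most of that is unavoidable FN, and
the 227 fragmentations are the coverage gaps those misses leave behind.
The single identity switch over 600 frames of night footage is the cascade
at work. In the behavior budget, all classified time lands in
swim-breathing: the generator's default motion regimes keep these targets
moving fast, and the tracked (not ground-truth) trajectories carry
detection jitter, so sub-threshold stationary displacement is rare — see
the methods vignette for how the rules behave on purpose-built segments.

Trajectories, training curves and rhythm summaries all have `autoplot()` /
`plot_rhythm()` methods; the predictor has `tidy()` and `glance()`.

Training the predictor on trajectories (ground truth or your own tracks):

```r
ex <- make_history_examples(generate_truth(preset("maneuver")), L = 10)
cfg <- predictor_config(model_dim = 16, epochs = 40, batch_size = 256,
                        learning_rate = 3e-3, seed = 1)
model <- train_predictor(ex, cfg)
glance(model)
predictor_aed(heldout_examples, model)   # held-out mean center error
```

A thin command-line wrapper over these functions lives at
`inst/cli/aquatrack.R` with subcommands `simulate`, `train-predictor`,
`track`, `evaluate`, `behavior`; MOTChallenge-style det/gt/result files and
a CSV feature sidecar are the interchange formats (`read_mot()`,
`write_mot()`, `read_features()`).

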