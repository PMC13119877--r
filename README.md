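# motionfuse

Robust human motion-state perception from three heterogeneous sensing
streams: 2-D skeleton keypoints from video pose estimation (~30 Hz),
wearable inertial measurement units (~100 Hz) and surface
electromyography (~1000 Hz). The streams disagree in sampling rate,
carry residual clock offsets, and the EMG *leads* the kinematics by the
electromechanical delay — so naive fusion mixes misaligned evidence and
propagates whichever stream happens to be corrupted.

`motionfuse` implements a complete framework for this problem, natively
in R (all neural components have hand-derived, finite-difference-checked
backpropagation):

* **Synthetic multimodal generator** — per-class sinusoidal joint motifs
  (class-specific fundamental frequencies in the 0.5–2.5 Hz cadence
  band), IMU channels that are exact second derivatives of limb
  trajectories, EMG as activation-envelope-modulated 20–450 Hz noise
  with a neuromuscular lead, known per-modality clock offsets, balanced
  subject-independent 70/10/20 splits, and quantified perturbations
  (joint occlusion, viewpoint rotation, additive noise at a stated SNR,
  total modality loss).
* **Preprocessing** — per-frame keypoint normalization (centroid and
  torso-length scale), zero-phase Butterworth band-pass, Z-scores frozen
  on the training partition, cubic-spline resampling to a unified grid,
  sliding windows with validity masks.
* **Model** — a temporal-transformer skeleton encoder, a bidirectional
  LSTM IMU encoder and a dilated-convolution EMG encoder emit token
  sequences in a shared latent space; *cross-modal temporal alignment
  attention* (vision-anchored, local neighbourhood, with a learnable
  per-modality temporal offset `delta` carried by a continuous-lag
  relative position bias) absorbs inter-stream lag; an interleaved
  multimodal transformer backbone models cross-modal interactions with
  relative-time and modality-relation biases; *uncertainty-aware fusion*
  turns per-timestep softplus uncertainties into convex weights
  `omega = softmax(-sigma)` and fuses `z_t = sum_m omega_t^m h_t^m`.
* **Multi-task heads and training** — 12-way action class, frame-level
  motion phase, scalar stability score; AdamW, cosine annealing,
  modality dropout, early stopping, k-fold cross-validation by subject.
* **Evaluation suite** — accuracy, macro precision/recall/F1, mAP
  (exact PR-curve integral), segmental F1@25, temporal stability
  `1 - mean_t ||y_t - y_{t-1}||`, a robustness protocol over the
  quantified perturbations, and a six-variant ablation harness.

The expected-lag diagnostic makes alignment interpretable: an attention
row's expectation `E[k - t]` estimates the temporal offset the module
has absorbed, and training only `delta` and the bias table on a lagged
copy of the anchor recovers injected offsets to within half a token.

## Worked example

```r
library(motionfuse)

# a balanced 10-subject dataset; every subject performs all 12 classes
gen <- generator_config(n_subjects = 10, trial_duration = 10, seed = 11)
ds  <- generate_dataset(gen)
ds
#> <motion_dataset> 120 sessions, 10 subjects, 12 classes (test=24, train=84, val=12)

# preprocess onto a 16 Hz grid, 2 s windows
pp  <- preprocess_config(grid_rate = 16, window_seconds = 2,
                         window_stride_seconds = 2)
dat <- build_windows(ds, pp)
length(dat$windows)
#> [1] 600

# train the full model at desk scale and evaluate on held-out subjects
fitres <- fit(dat, desk_model_config(),
              desk_train_config(epochs = 12, lr_start = 1.5e-3,
                                batch_size = 48, seed = 1))
ev <- evaluate_windows(fitres, NULL, dat$windows[dat$split == "test"])
ev$metrics
#> <metrics_report> n=120  acc 0.7333 | P 0.6781 R 0.7333 F1 0.6811 | mAP 0.9235 | F1@25 0.1047 | stability 0.9969

# where does the model place its confidence?
round(colMeans(ev$predictions$omega), 3)
#>     S     I     E
#> 0.436 0.268 0.295
```

The metrics line reads: 73% of the 120 held-out windows (two unseen
subjects) are classified correctly; macro F1 aggregates one-vs-rest
performance over the 12 classes; mAP integrates the per-class
precision–recall curves; F1@25 scores predicted motion-phase segments
against ground-truth segments at 25% overlap (coarse at an 8 Hz token
rate); stability near 1 means phase predictions barely flicker between
consecutive tokens. The `omega` columns are the mean fusion weights the
uncertainty module assigned to skeleton, IMU and EMG — the visual
stream dominates, as intended. With only two held-out subjects the
accuracy depends strongly on the subject draw; at the 20-subject scale
used by the test suite and the reproduction script the same pipeline
reaches the high-80s to high-90s percent, again depending on the draw.

Single operations are exposed too — for example the alignment module on
its own:

```r
cfg <- alignment_config(window_radius = 5, heads = 2, layers = 1,
                        d_model = 8, relpos_span = 12)
anchor <- with_seed(2, matrix(rnorm(320), 40, 8))
sensor <- rbind(matrix(0, 3, 8), anchor[1:37, ])  # delayed by 3 tokens
st  <- with_seed(3, init_alignment_state(cfg))
out <- fit_alignment(anchor, sensor, cfg, st, steps = 120, lr = 0.08)
round(tail(out$history$lag, 1), 2)
#> [1] 2.93  # mean expected lag ~ the injected 3-token delay
```

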