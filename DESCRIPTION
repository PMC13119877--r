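Package: motionfuse
Title: Multimodal Temporal Fusion of Skeleton, IMU and EMG Streams for Human Motion Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for robust human motion-state perception from three
    heterogeneous sensing streams: 2-D skeleton keypoint sequences from video
    pose estimation (30 Hz), wearable inertial measurement units (100 Hz) and
    surface electromyography (1000 Hz). Implements the full pipeline as a set
    of composable modules: a synthetic multimodal session generator with
    class-discriminative kinematic motifs and cross-modally consistent
    IMU/EMG signals; the preprocessing chain (keypoint normalization,
    Butterworth band-pass filtering, Z-score standardization, cubic-spline
    resampling to a unified temporal grid, sliding-window segmentation);
    modality-specific neural encoders (temporal transformer, bidirectional
    LSTM, dilated temporal convolutions); cross-modal temporal alignment
    attention with learnable per-modality offsets; an interleaved multimodal
    temporal transformer backbone; uncertainty-aware fusion with per-timestep
    confidence weighting; multi-task heads (action class, motion phase,
    stability score) with an AdamW training loop under a subject-independent
    split; and an evaluation suite (macro precision/recall/F1, mAP, segmental
    F1@25, temporal stability) with quantified robustness perturbations and
    an ablation harness. All neural components are implemented natively with
    hand-derived backpropagation and are gradient-checked in the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
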