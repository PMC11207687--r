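# vimsnet

EEG-based detection of visually induced motion sickness (VIMS) — the
nausea and disorientation caused by conflicting visual and vestibular
motion cues in virtual reality — from phase-locking-value functional
connectivity and a convolutional-recurrent classifier.

The package is aimed at neurophysiology and BCI researchers who want a
complete, testable reference implementation of this pipeline:

1. **Ingestion & preprocessing** — EDF/BDF reading (BioSemi 64-channel
   10-20 montage), exclusion of 12 noisy electrodes down to 52 working
   channels, zero-phase Butterworth 0.5–45 Hz band-pass and 49–51 Hz
   notch, downsampling 2048 → 1024 Hz, whole-brain average re-reference,
   and decomposition into the six canonical bands (delta 0.5–4, theta 4–8,
   alpha 8–14, beta 15–30, gamma 30–45, full 0.5–45 Hz).
2. **Connectivity** — per-subject state windows (rest / light / heavy
   sickness, 60 s each), 3-s non-overlapping segments, Hilbert
   instantaneous phase, and one 52×52 phase-locking-value matrix per
   segment:

   PLV = | (1/N) Σₙ exp( j·(φₓ(n) − φᵧ(n)) ) |  ∈ [0, 1],

   plus matrix averaging per (band, state) and network-topology
   thresholding (edges with PLV ≥ 0.55).
3. **Classification** — a CNN-LSTM: conv(64, 3×3) → BN → ReLU → 2×2 pool →
   dropout 0.5, conv(128) → … → dropout 0.3 (feature maps 64×26×26 and
   128×13×13 from a 52×52 input), the block-2 map read as 13 row-steps of
   1664 features into LSTM(100) → LSTM(50) → softmax (2 or 3 VIMS states);
   Adam (1e-3), cross-entropy, batch 32, ≤ 50 epochs with patience-10
   early stopping, 5-fold cross-validation.
4. **Evaluation** — accuracy, per-class recall, row-normalized confusion
   matrices, per-fold and fold-averaged reports.
5. **Synthetic cohorts** — a phase-coupled EEG generator with a
   closed-form synchrony oracle: channels share a band-limited oscillator
   and differ by slowly varying von Mises phase jitter with concentration
   κ, so the expected PLV between two channels is the squared Bessel ratio
   (I₁(κ)/I₀(κ))², available as `expected_plv()`. The study's recordings
   are not public; the generator reproduces their geometry (25 subjects ×
   3 states × 20 segments = 1500 matrices per band) and makes every stage
   verifiable.

The classifier engine (im2col/GEMM convolutions, backprop-through-time,
Adam) is implemented in RcppArmadillo and is fully reproducible from a
single seed, including dropout.

## Worked example

Generate a small synthetic cohort in which gamma-band synchrony collapses
with sickness severity (κ = 8 → 2 → 0.5), run it through preprocessing and
PLV, and cross-validate the 3-class CNN-LSTM:

```r
library(vimsnet)

cfg <- synth_config(
  n_subjects = 8,
  bands = eeg_bands("gamma"),
  kappa = matrix(c(8, 2, 0.5), 3, 1,
                 dimnames = list(c("VIMS_0", "VIMS_1", "VIMS_2"), "gamma")),
  seed = 301)

sessions <- lapply(1:8, function(s) generate_session(cfg, s))
events   <- do.call(rbind, lapply(sessions, `[[`, "events"))
ds <- cohort_datasets(lapply(sessions, `[[`, "recording"), events,
                      bands = eeg_bands("gamma"))$gamma
ds
#> <connectivity_dataset> 480 matrices (52x52), band gamma
#> state
#> VIMS_0 VIMS_1 VIMS_2
#>    160    160    160

cv <- cross_validate(ds, model_config(n_classes = 3),
                     train_config(max_epochs = 8, early_stop_patience = 3,
                                  seed = 31))
cv
#> 5-fold cross-validation (3 classes, split by segment)
#> accuracy: 1.0000 +/- 0.0000  (folds: 1.000, 1.000, 1.000, 1.000, 1.000)
#> average confusion (rows = true):
#>         predicted
#> true     VIMS_0 VIMS_1 VIMS_2
#>   VIMS_0      1      0      0
#>   VIMS_1      0      1      0
#>   VIMS_2      0      0      1
```

The three states differ only in how tightly channel phases lock (mean
segment PLV ≈ 0.91 / 0.60 / 0.24), and the classifier separates them
perfectly at this separation level; the fold-averaged confusion matrix has
the per-class recalls on its diagonal. With a "null" profile (identical κ in every state) the same
pipeline stays at 3-class chance — the no-leakage control.

An averaged connectivity matrix converts to a brain-network topology with

```r
mats <- session_plv(sessions[[1]]$recording, events[1, ],
                    bands = eeg_bands("gamma"))$gamma
avg <- average_matrices(mats[sapply(mats, attr, "state") == "VIMS_0"])
threshold_topology(avg, 0.55)
#> <network_topology> 1326 edges over 52 channels (threshold 0.55)
```

`run_pipeline()` wires all stages together (optionally through BDF files
on disk, the same ingestion path as real data) and emits a band × task
accuracy grid, per-fold JSON reports and a reproducibility manifest. A
command-line front end with `synth`, `preprocess`, `plv`, `train` and
`run-all` subcommands is installed under `inst/cli/vimsnet`.

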