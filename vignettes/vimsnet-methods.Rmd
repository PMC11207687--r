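---
title: "Phase-locking connectivity and CNN-LSTM classification of motion-sickness EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking connectivity and CNN-LSTM classification of motion-sickness EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vimsnet)
```

## The problem

Visually induced motion sickness (VIMS) is the nausea, dizziness and
disorientation produced by conflicting visual and vestibular motion cues,
a central obstacle for virtual-reality applications. Its severity is graded
here into three states: resting (`VIMS_0`), light (`VIMS_1`) and heavy
(`VIMS_2`) sickness. `vimsnet` implements an objective EEG-based detector of
these states built on two ideas:

1. **Phase synchrony as the feature.** Inter-channel phase locking of
   band-limited EEG summarizes large-scale functional connectivity, and
   cortical synchrony reorganizes as sickness develops (connectivity
   weakens with increasing severity, most visibly in the high-frequency
   bands).
2. **A convolutional-recurrent classifier.** The 52 x 52 matrix of pairwise
   phase-locking values (PLV) is treated as an image; convolutional blocks
   extract spatial structure and a stacked LSTM reads the resulting feature
   maps as a sequence, capturing cross-row dependencies before a softmax
   head assigns the state.

Because the clinical recordings that motivated this design are not openly
distributable, the package ships a synthetic phase-coupled EEG generator
whose ground-truth synchrony is known in closed form. Every stage of the
pipeline is validated against that oracle, and the whole pipeline runs on
synthetic cohorts with the same geometry as the study data (BioSemi
64-electrode 10-20 montage reduced to 52 working channels, 2048 Hz
acquisition, 60-s state windows).

## Preprocessing

The chain is: exclusion of the twelve conventionally noisy electrodes
(leaving 52), a 0.5-45 Hz band-pass, a 49-51 Hz notch against mains
interference, downsampling 2048 to 1024 Hz, and whole-brain average
re-referencing. The notch is retained even though the band-pass already
attenuates 50 Hz, mirroring common practice of suppressing mains
interference explicitly.

All filters are order-4 Butterworth prototypes applied forward and
backward, so the net phase response is zero — a hard requirement, since the
downstream statistic is a phase statistic and any group delay would be
misread as synchrony structure. Numerically the filters are realized as
cascades of second-order sections: at EEG rates a 0.5 Hz corner puts poles
within 1e-3 of the unit circle, and the expanded single-polynomial form of
the same filter is unstable in double precision (its computed poles land
outside the circle), while biquads are well-conditioned. Signals are padded
with an odd reflection long enough to absorb the slowest pole's transient
(several seconds for a 0.5 Hz edge) before the two filter passes.

Filtering is always applied to whole recordings, never to 3-s segments, so
segment boundaries carry no filter transients. Downsampling applies an
order-8 anti-alias low-pass at 0.9 of the target Nyquist and then decimates
by the integer factor; non-integer ratios are refused. An
artifact-removal hook (`remove_artifacts()`) exists as an identity
placeholder: the synthetic data carry no EMG/EOG artifacts, and a real-data
workflow can plug an ICA step into the same slot.

Band decomposition uses the six canonical bands: delta 0.5-4, theta 4-8,
alpha 8-14, beta 15-30, gamma 30-45 and full 0.5-45 Hz. The 14-15 Hz gap
between alpha and beta is reproduced as printed in the band definitions; no
energy is lost elsewhere.

## PLV connectivity

For two channels with instantaneous phases $\phi_x(t), \phi_y(t)$ the
phase-locking value over $N$ samples is

$$\mathrm{PLV} = \left| \frac{1}{N} \sum_{n=1}^{N}
   e^{\,j(\phi_x(n) - \phi_y(n))} \right| \in [0, 1],$$

the modulus of the time-averaged unit phasor of the phase difference: 1 for
perfect locking, 0 for independence. Instantaneous phase is the angle of
the analytic (Hilbert-transform) signal of each band-passed channel — the
standard construction for PLV. Phase is extracted once per 60-s state
window and the phase series is then cut into 3-s non-overlapping segments
(20 per window); extracting phase per 3-s segment instead would put the
FFT construction's circular edge leakage at every segment boundary.

The three state windows are: the first 60 s of rest (`VIMS_0`), 30 s either
side of the light-sickness report (`VIMS_1`), and the 60 s immediately
before the heavy-sickness report (`VIMS_2`), the session ending at that
report. Windows that would leave the recording raise an error naming the
state; if the two reports are closer than 30 s the windows overlap, which
is permitted but messaged.

Each 3-s segment yields one 52 x 52 symmetric unit-diagonal PLV matrix
(`plv_matrix()`, computed for all pairs at once as $|E E^H|/N$ with $E$ the
channels-by-samples matrix of unit phasors). A default cohort of 25
subjects x 3 states x 20 segments gives 1500 matrices per band. Matrices
average element-wise within (band, state) across subjects and segments, and
a network topology is obtained by keeping edges with PLV at or above a
threshold, 0.55 by default. The threshold is read as an absolute cutoff;
since "sparsity" is sometimes read as an edge-density target instead,
`threshold_topology(..., proportional = TRUE)` provides that semantics
behind a flag.

## The classifier

The model is a two-block CNN feeding a two-layer LSTM:

* block 1: conv 3x3 (stride 1, pad 1, 64 channels) -> batch norm -> ReLU ->
  2x2 max pool -> dropout 0.5, mapping 1x52x52 to 64x26x26;
* block 2: the same with 128 channels and dropout 0.3, mapping to
  128x13x13;
* the block-2 output is read as a sequence of 13 row-steps with
  128 x 13 = 1664 features per step — a spatial scan that preserves row
  adjacency while matching the stated hidden sizes — into LSTM(100) then
  LSTM(50);
* the final hidden state feeds a single linear layer and softmax over 2 or
  3 classes. The binary task merges the two sickness states against rest.

Training uses Adam (learning rate 1e-3), cross-entropy loss, batch size 32,
at most 50 epochs, and early stopping once the validation loss has not
improved for 10 consecutive epochs, restoring the best-validation-loss
weights. Evaluation is 5-fold cross-validation; every sample appears in
exactly one test fold, and the reported figure is the mean and standard
deviation of the fold accuracies.

Design points that were genuinely open and how they were resolved:

* **CNN-to-LSTM bridge.** Rows of the block-2 feature map are the sequence
  steps. Any fixed unrolling is compatible with the stated hidden sizes;
  the row scan is the one that preserves a spatial interpretation.
* **Dropout placement.** After pooling, following the block's listed layer
  order (conv, batch norm, ReLU, pool, dropout).
* **Head width.** A single linear layer 50 -> n_classes.
* **Fold assignment.** Stratified at the segment level by default, matching
  evaluation on a pooled sample set. Segment-level splitting leaks subject
  identity between train and test folds and is optimistic about
  generalization to new subjects; `split_by = "subject"` is provided as the
  stricter protocol and is the right choice for any real-data use.
* **Input scaling.** PLV matrices are already in [0, 1] and are fed raw.

The engine is implemented in compiled code (im2col + GEMM convolutions,
batch-norm with running statistics, backpropagation through time) in
single precision for training throughput; a double-precision instantiation
of the same templated code exists solely so the test suite can verify
analytic gradients against central finite differences (median relative
error below 1e-5 over sampled parameters of every tensor). Dropout masks
draw from R's RNG, so a `set.seed()` makes entire training runs
reproducible; with dropout active the model is still deterministic given
the seed, and in evaluation mode forward passes are exactly deterministic.
`lstm_step()` exports the gate recurrence in plain R both as documentation
and as an independent reference implementation.

## The synthetic generator and its oracle

Each channel $k$ is a sum over active bands $b$ of
$A_{b}\cos(\Phi_b(t) + \mu_k + \varepsilon_{kb}(t))$ plus white noise,
where $\Phi_b$ is a band-carrier phase trajectory shared by all channels
(carrier at the band midpoint with a slow ~1% random frequency wander),
$\mu_k$ is a fixed per-channel phase lag, and $\varepsilon_{kb}$ is a
slowly varying von Mises phase jitter with concentration
$\kappa(\text{state}, b)$ scaled by a per-region multiplier. Since two
independent von Mises deviates with concentrations $\kappa_1, \kappa_2$
satisfy

$$\mathbb{E}\, e^{\,j(\varepsilon_1 - \varepsilon_2)} =
  \frac{I_1(\kappa_1)}{I_0(\kappa_1)} \cdot
  \frac{I_1(\kappa_2)}{I_0(\kappa_2)},$$

the generator has a closed-form PLV oracle, `expected_plv()`: the squared
Bessel ratio for an equal-concentration pair, 0 for uniform jitter and 1 in
the jitter-free limit.

Three details make the oracle usable through the real pipeline:

* **Slow jitter with an exact marginal.** A unit-variance AR(1) Gaussian
  process (correlation time 0.25 s, i.e. sub-hertz bandwidth) is pushed
  through the probability-integral transform and the von Mises quantile
  function. The marginal is exactly von Mises at every instant while the
  trajectory is slow enough to survive band-pass filtering and Hilbert
  phase extraction; per-sample independent jitter would be filtered away,
  and constant jitter would give PLV 1 regardless of $\kappa$.
* **Fixed phase lags.** The $\mu_k$ (uniform on the circle, drawn per
  recording) leave PLV untouched — it ignores constant offsets — but make
  the cross-channel average scale as $1/\sqrt{K}$, so average
  re-referencing does not inject a common-mode component. Without them,
  two-channel toy recordings become exactly antiphase after re-referencing
  and every PLV degenerates to 1.
* **Realistic nuisance.** Per-subject band amplitudes jitter by +-20%
  (PLV must ignore amplitude, and the tests confirm it does), and additive
  white noise (SD 0.3 relative to unit band amplitude) leaves a negligible
  in-band phase perturbation.

The default cohort emulates the study layout: 25 subjects, 52 channels,
2048 Hz native (so downsampling is exercised), 60 s per state, and a
"separable" profile in which gamma-band synchrony collapses with severity
($\kappa$ = 8, 2, 0.5 for rest, light, heavy — mean segment PLV about 0.91,
0.60, 0.24) with a milder beta trend and uninformative slow bands. A
"null" profile holds $\kappa$ fixed across states for leakage checks.
Sessions are continuous 180-s recordings — the three state stretches
abut, the shared oscillator runs through the whole session, and only
$\kappa$ switches at the boundaries — with the rest onset at 0 s, the
light report at 90 s and the heavy report at 180 s, so the state windows
tile the session exactly. `generate_dataset()` writes standard BDF (24-bit
BioSemi) files plus a plain-text event sidecar, and the pipeline ingests
them through the same reader a real study would use.

What the generator does **not** emulate: 1/f broadband spectra, EMG/EOG
artifacts, volume conduction (which inflates zero-lag synchrony between
neighboring electrodes), non-stationary amplitude dynamics, and any actual
VIMS physiology. Passing tests therefore demonstrate that the pipeline
measures imposed phase synchrony correctly and that the classifier
recovers state-dependent synchrony differences — not that real VIMS is
detectable at any particular accuracy.

## Estimator behavior and test tolerances

The plug-in PLV estimator $|\text{mean phasor}|$ is biased upward on finite
samples: for true synchrony $R^2$ and $M$ effectively independent phase
draws, its expectation is near $\sqrt{R^4 + (1 - R^4)/M}$. With 0.25-s
jitter correlation a 3-s segment contains only a handful of independent
draws, so *per-segment* PLV at low $\kappa$ sits well above the oracle
value — a property of the estimator, not an implementation error, and the
tests compare per-segment statistics against a Monte-Carlo simulation of
the same estimator rather than against the asymptote. Pooling the phasor
mean across 200 segments of one continuous recording drives the floor down
far enough that the pooled estimate matches the closed form to within a
few percent at moderate and high $\kappa$ — the oracle acceptance check
asserts 5% relative agreement at $\kappa \in \{2, 8\}$. At
$\kappa = 0.5$ the target is 0.059, smaller than what the residual floor
plus filter smoothing can resolve relatively, so the check there uses an
absolute band of 0.05 PLV (five points of phase locking), which the
measurement meets with a wide margin.

Other numerical choices: filter stop-band attenuation is asserted against
the designed cascade's own frequency response (an order-4 zero-phase
band-pass leaves 8.5% RMS of a 60 Hz tone — the squared magnitude response
— and the test expects exactly that, plus a hard ceiling); steady-state
RMS is measured on the central 80% of tone fixtures, away from the
zero-phase edge transients; an identically-zero channel gets phase 0 with
a warning rather than an error mid-pipeline; finite-difference gradient
checks accept isolated large deviations at ReLU/max-pool kinks but require
median agreement below 1e-5.

## Problem sizes in the test suite

The suite runs the real study geometry where the check depends on it (52
channels for every matrix-shape and architecture assertion; a full
25-subject cohort for the 1500-matrix bookkeeping check) and scales the
rest to what the checks actually need: oracle measurements use 200
segments per concentration level on a 24-channel montage; classifier
recovery uses an 8-subject cohort (480 matrices) with an 8-epoch budget,
which is past convergence for the separable profile (validation accuracy
saturates within 3-4 epochs); the null-profile chance check uses 5
epochs, as chance behavior is epoch-independent. Training on the
full 25-subject default with the 50-epoch budget is the same code path
and is what `run_pipeline()` executes outside the test suite.

## Known limitations

* The EDF/BDF layer covers continuous equal-rate recordings — the only
  kind this pipeline produces and consumes — not annotations, variable
  rates or discontinuous records.
* PLV is sensitive to volume conduction in real EEG; no leakage correction
  (e.g. imaginary coherence or phase-lag index) is implemented, as other
  connectivity indices are out of scope.
* Segment-level cross-validation, kept as the default for comparability,
  is optimistic for subject generalization; use `split_by = "subject"` for
  honest new-subject estimates.
* The classifier trains on CPU in single precision; there is no GPU path.
* Graph-theoretic network metrics (clustering, path length) are not
  computed; topologies are exported as edge lists / GraphML for external
  tools.
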