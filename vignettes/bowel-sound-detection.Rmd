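---
title: "Detecting and quantifying bowel sounds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying bowel sounds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsound)
```

## The problem and the model

Bowel sounds are short acoustic bursts — typically 20–130 ms, with energy
concentrated between 60 and 1500 Hz — produced by gastrointestinal
motility and recordable with a contact microphone on the abdominal wall.
`bsound` reduces their detection to a binary classification of 10-ms
*frames* of a decibel spectrogram, followed by a run-length merge of
positive frames into discrete events and a statistical summary of the
event series.

The front end is a literal short-time Fourier transform: windows of
`L = 441` samples (10 ms at 44.1 kHz) tapered by a Hann (or Hamming)
function, shifted by `hop = 110` samples, with no centering and no
zero-padding — only complete windows are transformed, so a fragment of
`n` samples yields `floor((n − L)/hop) + 1` columns. Amplitudes are
mapped to `20·log10|X|` and the band is cropped to 0–1500 Hz.

Assumptions inherited from this design:

* all internal processing happens at 44.1 kHz — other rates are resampled
  on ingest, because every printed constant (441-sample frames, 110-sample
  hop, 100-Hz bin spacing) presumes that rate;
* recordings are mono; multi-channel input is mean-downmixed;
* a 2-s fragment is the unit of model input (200 frames), and fragments
  are processed independently.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `size_L` (window) | 441 | samples | 10 ms at 44.1 kHz; best event visibility |
| `hop` | `floor(L/4)` = 110 | samples | 25 % step smooths the time axis |
| window kind | `hann` | — | slightly better than Hamming in validation |
| `max_freq` | 1500 | Hz | upper edge of bowel-sound band |
| `db_floor` | −100 | dB | silence clamp for `log10(0)` |
| `frame_ms` | 10 | ms | smallest unit that avoids fusing adjacent sounds |
| `cols_per_frame` | 4 | columns | `floor(441/110)`; one frame of context per block |
| CDNN `context` | 9 | frames | ±4 frames; near-plateau of accuracy vs. cost |
| dropout | 0.4 | — | regularization of both networks |
| decision threshold | 0.5 | — | neutral operating point on the sigmoid |

When `size_L` is swept, the hop is recomputed as `floor(L/4)` and the
columns per frame as `floor(F/hop)` with `F = 441` the frame length in
samples, so every configuration keeps frames exactly `cols_per_frame`
columns wide.

## Numerical choices

* **Decibel convention.** Only "decibel spectrogram" is specified by the
  method; this package fixes *amplitude* decibels (`20·log10`), reference
  1.0, floored at −100 dB. The floor only matters for digitally silent
  input.
* **DC exclusion.** With 100-Hz bin spacing, 0–1500 Hz spans 16 bins
  including DC. The classifier input height is 15, so the crop keeps bins
  1…15 (100–1500 Hz) and drops DC, which carries sensor offset rather
  than sound. This reconciles the printed input shape exactly.
* **Frame–column alignment.** A frame covers samples `[mF, (m+1)F)` with
  `F = 441`, but `441 = 4·110 + 1`, so frame starts drift by one sample
  per frame relative to the column grid. The block of frame `m` starts at
  column `floor(mF/hop)`, absorbing the drift; the final frames of a
  fragment zero-pad the columns that fall off the spectrogram's end.
* **Standardization.** Global scalar mean and *population* standard
  deviation (divisor `N`) over all cells of all training spectrograms,
  applied before classification. The baseline cut-off is calibrated in
  these standardized units.
* **Frame labeling.** A frame is positive if (a) annotated sound covers
  strictly more than half the frame, or (b) strictly more than half of a
  single sound's duration lies inside the frame. Frames are half-open
  `[mΔ, (m+1)Δ)` so boundary instants are never double counted, and the
  strict comparisons carry a 1-ns guard so that an overlap of exactly
  half a frame — which floating-point subtraction may round either way —
  is deterministically negative.
* **Resampling** is Fourier-domain (spectrum zero-pad/truncate with
  Nyquist-bin splitting), which preserves in-band tone frequencies
  exactly and duration to within one sample period.

## The classifiers

The **baseline** scores each frame by the mean of its standardized
15×4 block and thresholds it; it is monotone in the cut-off by
construction and serves as the floor any learned model must beat.

The **CRNN** applies, identically at each of the 200 frames, two valid
2-D convolutions (30 filters 3×3, then 60 filters 4×2, both ReLU),
taking the 15×4 block through 13×2×30 to 10×1×60, flattened to 600
features, then a bidirectional GRU (80 units per direction) over the
sequence and a per-frame sigmoid unit. The GRU uses the *reset-after*
(double-bias) gate formulation; this is what makes the parameter count
well defined: conv stack 300 + 14,460, biGRU 2·3·(600·80 + 80·80 + 2·80)
= 327,360, head 161 — 342,281 in total, truncating to the printed
342,000. The candidate activation is ReLU, matching the stated use of
ReLU at every convolutional and recursive output. No pooling layers are
used: the enumerated shapes only reconcile without them.

The **CDNN** maps each frame's flattened 60 values through a dense ReLU
layer of 120 units, concatenates the vectors of the 9 adjacent frames
(zero vectors beyond the sequence edges, so every frame stays
classifiable), and classifies through dense 100 (ReLU) and a sigmoid
unit: 61·120 + 1081·100 + 101 = 115,521 parameters, truncating to
115,000.

Design choices where the published description is silent:

* weight initialization is Glorot-uniform everywhere (a common default;
  recurrent kernels are not specially orthogonalized) with zero biases,
  seeded for reproducibility;
* the decision threshold on the sigmoid output is 0.5, exposed as
  configuration;
* no class weighting is applied despite the class imbalance — imbalance
  is handled by reporting sensitivity and specificity separately;
* the retained checkpoint is the epoch with the best validation
  *accuracy* (earliest on ties), accuracy being the headline metric;
* training is full-batch-shuffled minibatch Adam (defaults 0.001, 0.9,
  0.999, 1e-7) on binary cross-entropy; batch size 16 sequences. Batch
  size is not specified by the method and is exposed in
  `train_config()`.

Both networks are implemented natively (no external deep-learning
runtime): the forward pass, analytic backpropagation — including
backpropagation through time for the bidirectional GRU — and Adam are
package code, and the test suite checks every gradient against central
finite differences on reduced-size models.

Augmentation adds i.i.d. Gaussian noise to standardized spectrogram
values, producing 5 noisy replicas per sequence by default and keeping
the originals.

## The synthetic world

The generator emulates what the clinical recordings are described to
contain: sparse short bursts in broadband noise.

* Background: white Gaussian noise, RMS 0.01 full scale — a quiet
  recording with ample headroom, as expected from a 24-bit recorder.
* Events: exponentially damped sinusoids (decay constant a quarter of
  the duration), carrier uniform in 60–1500 Hz, duration uniform in
  20–130 ms, random phase. Damped sinusoids match the "single burst"
  phenomenology and have analytically known band content.
* Onsets: Poisson process at `events_per_min` (default 40, a plausible
  active-period rate), thinned to prevent overlap, events clipped to lie
  wholly inside the recording. Thinning removes of order
  `rate × mean duration` of candidates (≈5 % at the defaults), so the
  realized rate sits slightly below the configured one at high
  densities; the calibration test runs at a density where this bias is
  negligible.
* Amplitude: the burst's RMS over its support is set
  `snr_db` above the noise's *in-band* RMS (band power fraction
  `(1500−60)/22050` of total). Default 15 dB keeps sounds clearly present
  but not dominant — the task is meant to be nontrivial.

What the generator does **not** emulate: heartbeat and respiration
artifacts, amplitude/duration distributions of real pathology, sound
types beyond single bursts, recorder nonlinearities. A green test on
synthetic data therefore establishes that the pipeline recovers planted
structure under controlled conditions — not clinical-grade accuracy.
The published full-scale benchmark (five-fold cross-validation and a
held-out test set on the public annotated dataset, where the recurrent
model reaches ≈97.7 % frame accuracy) requires the clinical recordings
and hours of training; it is documented here as an external check only
and is not part of the test suite.

## Event statistics

Intervals between events are **onset-to-onset** — the convention of the
heart-rate-variability literature from which RMSSD and the Porta/Guzik
indices are borrowed; the alternative (end-to-next-onset) is not what
those statistics assume. With `d_i` the successive interval differences:
RMSSD = `sqrt(mean(d²))`, Porta's index = share of negative `d` among
nonzero `d`, Guzik's index = share of squared distance above the
Poincaré identity line, `Σ_{d>0} d² / Σ_{d≠0} d²` (the constant `1/√2`
cancels). Undefined statistics (fewer than 2 intervals, or all `d = 0`)
are reported as `NA`, never as 0.

The per-minute series covers complete minutes only, and the overall
events-per-minute rate is normalized by complete minutes whenever the
recording has at least one, so an event-free trailing remainder cannot
dilute any reported statistic. Three-minute windows report mean, median
and quartiles (Q1/Q3) of the per-minute counts. The duration histogram
uses right-closed 10-ms bins, `((b−1)·10, b·10]` ms.

Event merging applies no minimum duration and no gap bridging by
default — a single sound occasionally splits into two detections, and
the method applies no correction; an optional `bridge_frames` parameter
and a cross-fragment merge of touching events are provided for
experimentation, both off by default.

## Data splitting

The train/test split and the k-fold assignment operate on whole 2-s
fragments, never on individual frames: adjacent 10-ms frames are nearly
identical, and splitting them across sets would leak. Where the
published protocol is ambiguous about whether "records" were split at
10-ms or 2-s granularity, fragment-level splitting is the conservative
choice. Sounds spanning a fragment boundary are clipped to each side
before labeling; fragments are classified independently.

## Known limitations

* CRNN training in native R is roughly an order of magnitude slower than
  the CDNN (sequential backpropagation through 200 time steps); at desk
  scale both are fine, but the CDNN is the workhorse for sweeps and the
  automated parameter-recovery checks.
* The ReLU GRU candidate can produce large hidden states on
  unstandardized input; the pipeline always standardizes, and training
  on standardized data is stable in practice.
* WAV support covers RIFF PCM 16/24/32-bit and IEEE float, mono or
  multi-channel; compressed codecs are out of scope.
* Synthetic defaults are stand-ins for unpublished clinical amplitude
  and duration distributions, and are stated as such.
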