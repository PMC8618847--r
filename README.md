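# bsound — bowel sound detection and quantification from abdominal audio

Gastrointestinal motility produces short acoustic events — bowel sounds —
that can be captured overnight with a contact microphone taped to the
abdomen. Detecting and counting them non-invasively is of interest to
gastroenterologists studying motility (e.g. migrating motor complexes,
irritable bowel syndrome), but the events are brief (tens of
milliseconds), sparse and often quiet relative to the broadband recording
noise. `bsound` implements a complete detection and quantification
pipeline for such recordings, aimed at researchers who want a
reproducible, scriptable reference implementation that runs on an
ordinary CPU.

## Method

The recording (mono WAV, nominally 24-bit / 44.1 kHz) is cut into 2-s
fragments and converted to a decibel spectrogram with the short-time
Fourier transform

```
X[k, m] = Σ_{n=0..L-1}  w_n · x[m·h + n] · e^(−2πikn/L)
```

with window length `L = 441` samples (10 ms), hop `h = 110` (25 %), and a
Hann taper `w_n = 0.5 (1 − cos 2πn/N)` (Hamming available). Amplitudes
become `20·log10|X|`, the band is cropped to 0–1500 Hz (15 bins at 100 Hz
spacing, DC excluded), and values are standardized by the global mean and
standard deviation of the training recordings. Each 10-ms *frame* is a
15 × 4 block of this spectrogram; a 2-s fragment is a sequence of 200
frames.

Frames are classified as bowel sound vs noise by one of three detectors:

* **baseline** — frame mean of the standardized block against a fixed
  cut-off;
* **CRNN** — per-frame 2-D convolutions (30 filters 3×3, then 60 filters
  4×2, valid padding, ReLU) flattened to 600 features, a bidirectional
  GRU with 80 units per direction over the 200-frame sequence, and a
  per-frame sigmoid unit (342,281 trainable parameters);
* **CDNN** — per-frame dense features (60 → 120, ReLU), concatenation of
  the 9 adjacent frames' vectors, dense 100 (ReLU) and a sigmoid unit
  (115,521 parameters).

Both networks are implemented natively in R (forward pass, analytic
backpropagation, Adam, binary cross-entropy, dropout 0.4, optional
Gaussian spectrogram-noise augmentation); gradients are verified against
finite differences in the test suite. Ground-truth interval annotations
are converted to frame labels by a two-condition rule: a frame is
positive if annotated sound covers more than half the frame, or if more
than half of a single sound's duration falls inside the frame.

Runs of positive frames are merged into discrete sound events, and a
clinical report summarizes the recording: event counts overall and per
minute, per-3-minute statistics (mean, median, quartiles), a duration
histogram in 10-ms bins, and interval statistics — RMSSD, standard
deviation of inter-onset intervals, and Porta's and Guzik's asymmetry
indices from the Poincaré-plot construction.

A synthetic-recording generator (damped-sinusoid bursts of 20–130 ms,
60–1500 Hz, Poisson onsets, calibrated burst-to-noise ratio, exact
ground-truth annotations) makes every stage testable without clinical
data.

## Worked example

Train the CDNN on a 4-minute synthetic recording (40 events/min, 20 dB
burst-to-noise) and analyze the result:

```r
library(bsound)
syn   <- synth_generate(synth_config(duration_s = 240, events_per_min = 40,
                                     snr_db = 20, seed = 1))
ds    <- build_dataset(syn$recording, syn$annotations)
split <- split_dataset(ds$items, test_frac = 0.15, seed = 1)
model <- train_model(build_model(model_spec("cdnn"), seed = 1),
                     split$train, split$test,
                     cfg = train_config(epochs = 12, seed = 1),
                     norm = ds$norm)
model$history[model$best_epoch,
              c("epoch", "val_accuracy", "val_sensitivity", "val_specificity")]
#>    epoch val_accuracy val_sensitivity val_specificity
#> 10    10     99.41667        89.07563        99.77018

res <- run_detect_pipeline(syn$recording, model)
res$report
#> Bowel sound activity report
#>   recording length  : 240.0 s
#>   sounds detected   : 139 (34.75 per minute)
#>   per-minute counts : 28 38 37 36
#>   duration histogram: 10 ms: 6 (4.3%), 20 ms: 1 (0.7%), 40 ms: 24 (17.3%), ...
#>   RMSSD             : 2.598 s
#>   SD of intervals   : 1.709 s
#>   Porta's index     : 50.36 %
#>   Guzik's index     : 50.78 %
```

The best-epoch row says the trained classifier labels 99.4 % of held-out
10-ms frames correctly, catching 89 % of true sound frames while keeping
the false-alarm rate among noise frames below 0.3 %. The report then
quantifies the detected activity: 139 events against 134 planted bursts,
a stable per-minute series, and asymmetry indices near 50 % — as expected
for the generator's memoryless event process.

The same pipeline is scriptable from a shell via `inst/cli/bsound`
(subcommands `synth`, `fragment`, `spectrogram`, `label`, `train`,
`detect`, `analyze`, `evaluate`, `sweep`).

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch —
synthesize a 240-s recording, train the CDNN, detect events and compute
the report — under a given seed:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/audio_io.R` — WAV read/write (PCM 16/24/32, float), resampling,
  fragmentation
* `R/spectro.R` — windows, STFT, dB spectrograms, standardization, frame
  tensors
* `R/annotate.R` — annotation I/O, frame labeling, train/test and k-fold
  splits
* `R/synthetic.R` — synthetic recording generator
* `R/nn.R`, `R/detectors.R` — baseline, CRNN, CDNN, training,
  augmentation, prediction
* `R/events.R`, `R/report.R` — event merging and the statistics report
* `R/evaluation.R` — confusion metrics, cross-validation, hyperparameter
  sweeps
* `R/pipeline.R` — dataset builder and the end-to-end detection pipeline
* `vignettes/bowel-sound-detection.Rmd` — methods notes: model,
  parameters, design choices, limitations
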