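Package: bsound
Title: Bowel Sound Detection and Quantification from Abdominal Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of bowel sounds in abdominal audio
    recordings. Builds standardized decibel spectrograms with short-time
    Fourier transforms (Hann or Hamming windows), labels 10-ms frames from
    interval annotations, and classifies frames with either a mean-amplitude
    threshold baseline, a convolutional-recurrent network (CRNN with a
    bidirectional GRU), or a convolutional-dense network (CDNN with adjacent
    frame context), both implemented natively with Adam training and Gaussian
    spectrogram augmentation. Detected frames are merged into discrete sound
    events and summarized in a clinical report: counts per minute, three-minute
    window statistics, duration histograms, RMSSD and standard deviation of
    inter-event intervals, and the Porta and Guzik asymmetry indices. A
    synthetic recording generator with ground-truth annotations makes the full
    pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
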