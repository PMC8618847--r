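# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by direct summation/enumeration, never by calling the
# implementation under test.

# Direct double-loop evaluation of the windowed DFT.
brute_stft <- function(x, w, hop) {
  L <- length(w)
  M <- floor((length(x) - L) / hop) + 1
  X <- matrix(0 + 0i, L, M)
  n <- 0:(L - 1)
  for (m in 0:(M - 1)) {
    seg <- w * x[m * hop + n + 1]
    for (k in 0:(L - 1)) {
      X[k + 1, m + 1] <- sum(seg * exp(-2i * pi * k * n / L))
    }
  }
  X
}

# Literal per-frame application of the two-condition labeling rule
# (strict ">" realized with the same 1-ns boundary guard the package
# documents, so exact half-overlaps count as negative).
brute_labels <- function(starts, ends, n_frames, frame_ms = 10) {
  D <- frame_ms / 1000
  out <- integer(n_frames)
  for (m in 0:(n_frames - 1)) {
    a <- m * D; b <- (m + 1) * D
    total <- 0
    pos <- FALSE
    for (i in seq_along(starts)) {
      ov <- min(ends[i], b) - max(starts[i], a)
      if (ov > 0) {
        total <- total + ov
        if (ov > (ends[i] - starts[i]) / 2 + 1e-9) pos <- TRUE
      }
    }
    if (total > D / 2 + 1e-9) pos <- TRUE
    out[m + 1] <- as.integer(pos)
  }
  out
}

# Exhaustive tally over the four confusion cells.
brute_confusion <- function(pred, truth) {
  cells <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) cells["tp"] <- cells["tp"] + 1
    else if (pred[i] == 1 && truth[i] == 0) cells["fp"] <- cells["fp"] + 1
    else if (pred[i] == 0 && truth[i] == 0) cells["tn"] <- cells["tn"] + 1
    else cells["fn"] <- cells["fn"] + 1
  }
  cells
}

# Small standardized synthetic dataset shared by detector tests.
make_tiny_dataset <- function(duration_s = 8, snr_db = 20, seed = 2,
                              events_per_min = 40) {
  syn <- synth_generate(synth_config(duration_s = duration_s,
                                     events_per_min = events_per_min,
                                     snr_db = snr_db, seed = seed))
  build_dataset(syn$recording, syn$annotations)
}
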