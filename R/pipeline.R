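#' Build a labeled frame dataset from a recording and its annotations
#'
#' Runs the preprocessing front end: split into 2-s fragments, decibel
#' spectrogram per fragment, global standardization, regrouping into
#' frame tensors, and per-frame labels from the annotated intervals.
#' Fragments are treated independently: a sound spanning a boundary is
#' clipped to each side before the labeling rule is applied.
#'
#' @param rec A [bs_recording()] (resampled to `params$sample_rate` if
#'   needed).
#' @param ann A [bs_annotations()] object; `NULL` yields all-negative
#'   labels.
#' @param params An [stft_params()].
#' @param fragment_s Fragment length in seconds.
#' @param frame_ms Frame width in milliseconds.
#' @param cols_per_frame Spectrogram columns per frame.
#' @param norm Optional `c(mean, sd)`; when `NULL`, statistics are pooled
#'   from all fragments of this recording.
#' @return List with `items` (one `list(x = blocks, y = labels,
#'   offset_s = )` per fragment), `norm`, `n_bins`, `n_frames`, `params`.
#' @export
build_dataset <- function(rec, ann = NULL, params = stft_params(),
                          fragment_s = 2.0, frame_ms = 10,
                          cols_per_frame = 4L, norm = NULL) {
  if (rec$sample_rate != params$sample_rate) rec <- resample(rec, params$sample_rate)
  frags <- fragment(rec, fragment_s)
  if (length(frags) == 0L) stop("recording shorter than one fragment")
  specs <- lapply(frags, function(fr) to_db_spectrogram(stft(fr, params)))
  if (is.null(norm)) norm <- compute_norm_stats(specs)
  items <- lapply(specs, function(sp) {
    sp <- standardize(sp, norm[["mean"]], norm[["sd"]])
    ft <- frame_tensor(sp, frame_ms = frame_ms, cols_per_frame = cols_per_frame)
    n_frames <- dim(ft$blocks)[1]
    y <- if (is.null(ann) || nrow(ann) == 0L) integer(n_frames) else {
      local_ann <- .clip_annotations(ann, ft$offset_s, fragment_s)
      label_frames(local_ann, n_frames, frame_ms)
    }
    list(x = ft$blocks, y = y, offset_s = ft$offset_s)
  })
  list(items = items, norm = norm, n_bins = dim(items[[1]]$x)[2],
       n_frames = dim(items[[1]]$x)[1], params = params)
}

# Intersect annotations with [offset, offset + dur) and shift to local time.
.clip_annotations <- function(ann, offset, dur) {
  s <- pmax(ann$start - offset, 0)
  e <- pmin(ann$end - offset, dur)
  keep <- e > s & s < dur & e > 0
  bs_annotations(s[keep], e[keep])
}

#' Default pipeline configuration
#'
#' The selected operating point of the published method: 441-sample Hann
#' window, 110-sample hop (25%), 0-1500 Hz crop, 10-ms frames of 4
#' spectrogram columns, 2-s fragments, decision threshold 0.5.
#'
#' @return Nested list of defaults consumed by [run_detect_pipeline()].
#' @export
default_config <- function() {
  list(
    spectro = list(fft = 441L, hop = 110L, window = "hann",
                   max_freq = 1500, db_floor = -100,
                   frame_ms = 10, cols_per_frame = 4L),
    audio = list(sample_rate = 44100L, fragment_s = 2.0),
    events = list(bridge_frames = 0L, merge_across_fragments = FALSE),
    stats = list(bin_ms = 10, window_min = 3),
    threshold = 0.5
  )
}

#' Run the full detection pipeline on a recording
#'
#' fragment -> spectrogram -> standardize -> frame -> classify -> merge
#' -> report. The classifier can be a trained [build_model()] (its stored
#' `norm` is used when present) or a [baseline_config()] (standardization
#' statistics are then pooled from the recording itself).
#'
#' @param rec A [bs_recording()] or a WAV path.
#' @param model A trained `bs_model` or a `bs_baseline`.
#' @param config Pipeline configuration, see [default_config()].
#' @param verbose Log stage progress to stderr.
#' @return List with `events` (a `bs_events` data frame over absolute
#'   recording time), `report` (a `bs_stats_report`), `predictions`
#'   (per-fragment [bs_predictions()]), and `recording_length_s`.
#' @export
run_detect_pipeline <- function(rec, model, config = default_config(),
                                verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(rec)) {
    say("reading %s", rec)
    rec <- read_wav(rec)
  }
  sc <- config$spectro
  params <- stft_params(window = sc$window, size_L = sc$fft, hop = sc$hop,
                        sample_rate = config$audio$sample_rate,
                        max_freq = sc$max_freq, db_floor = sc$db_floor)
  if (rec$sample_rate != params$sample_rate) {
    say("resampling %d Hz -> %d Hz", rec$sample_rate, params$sample_rate)
    rec <- resample(rec, params$sample_rate)
  }
  total_s <- duration_s(rec)
  frags <- fragment(rec, config$audio$fragment_s)
  if (length(frags) == 0L) stop("pipeline: recording shorter than one fragment")
  say("fragmented into %d x %.1f s", length(frags), config$audio$fragment_s)
  specs <- lapply(frags, function(fr) to_db_spectrogram(stft(fr, params)))
  norm <- if (inherits(model, "bs_model") && !is.null(model$norm))
    model$norm else compute_norm_stats(specs)
  say("standardizing with mean %.2f dB, sd %.2f dB", norm[["mean"]], norm[["sd"]])
  preds <- lapply(specs, function(sp) {
    sp <- standardize(sp, norm[["mean"]], norm[["sd"]])
    ft <- frame_tensor(sp, frame_ms = sc$frame_ms,
                       cols_per_frame = sc$cols_per_frame)
    if (inherits(model, "bs_baseline")) baseline_classify(ft, model)
    else predict(model, ft, threshold = config$threshold)
  })
  ev_list <- lapply(preds, function(p)
    merge_frames(p, frame_ms = p$frame_ms, offset_s = p$offset_s,
                 bridge_frames = config$events$bridge_frames))
  events <- do.call(rbind, ev_list)
  events <- structure(events[order(events$start), , drop = FALSE],
                      class = c("bs_events", "data.frame"))
  rownames(events) <- NULL
  if (isTRUE(config$events$merge_across_fragments))
    events <- merge_touching_events(events)
  say("detected %d events", nrow(events))
  report <- compute_report(events, total_s, bin_ms = config$stats$bin_ms,
                           window_min = config$stats$window_min)
  list(events = events, report = report, predictions = preds,
       recording_length_s = total_s)
}
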