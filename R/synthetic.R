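#' Synthetic abdominal recording configuration
#'
#' The generator emulates the phenomenology of overnight abdominal audio:
#' sparse short bursts (default 20-130 ms) with energy concentrated in
#' 60-1500 Hz, embedded in broadband Gaussian background noise. Bursts are
#' exponentially damped sinusoids; onsets follow a Poisson process thinned
#' to prevent overlap; burst amplitude is set so the in-band RMS exceeds
#' the in-band noise RMS by `snr_db`.
#'
#' @param duration_s Recording length in seconds.
#' @param sample_rate Sampling rate in Hz (default 44,100).
#' @param events_per_min Mean event rate per minute (default 40).
#' @param duration_range_ms Burst duration range in milliseconds.
#' @param freq_range_hz Burst carrier frequency range in Hz.
#' @param snr_db Burst-to-noise ratio in dB, measured on in-band RMS
#'   (default 15: sounds remain quiet relative to the broadband noise).
#' @param noise_level RMS amplitude of the background noise.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `bs_synth_config`.
#' @export
synth_config <- function(duration_s = 60, sample_rate = 44100L,
                         events_per_min = 40,
                         duration_range_ms = c(20, 130),
                         freq_range_hz = c(60, 1500),
                         snr_db = 15, noise_level = 0.01, seed = 1L) {
  stopifnot(duration_s > 0, sample_rate > 0, events_per_min >= 0,
            duration_range_ms[1] <= duration_range_ms[2],
            freq_range_hz[1] <= freq_range_hz[2], noise_level > 0)
  structure(
    list(duration_s = duration_s, sample_rate = as.integer(sample_rate),
         events_per_min = events_per_min,
         duration_range_ms = duration_range_ms,
         freq_range_hz = freq_range_hz, snr_db = snr_db,
         noise_level = noise_level, seed = as.integer(seed)),
    class = "bs_synth_config"
  )
}

#' Generate a synthetic recording with ground-truth annotations
#'
#' @param config A [synth_config()].
#' @return List with `recording` (a [bs_recording()]) and `annotations`
#'   (a [bs_annotations()] of the exact burst supports).
#' @export
synth_generate <- function(config = synth_config()) {
  mean_dur_s <- mean(config$duration_range_ms) / 1000
  if (config$events_per_min / 60 * mean_dur_s > 0.8)
    stop("infeasible event density: rate x mean duration exceeds 80% of the recording")
  fs <- config$sample_rate
  n <- as.integer(round(config$duration_s * fs))
  with_seed(config$seed, {
    x <- stats::rnorm(n, 0, config$noise_level)
    starts <- ends <- numeric(0)
    n_ev <- stats::rpois(1L, config$events_per_min * config$duration_s / 60)
    if (config$events_per_min > 0 && n_ev > 0) {
      onset <- sort(stats::runif(n_ev, 0, config$duration_s))
      dur <- stats::runif(n_ev, config$duration_range_ms[1],
                          config$duration_range_ms[2]) / 1000
      carrier <- stats::runif(n_ev, config$freq_range_hz[1], config$freq_range_hz[2])
      phase <- stats::runif(n_ev, 0, 2 * pi)
      # white noise RMS sigma spreads power uniformly over [0, fs/2]
      band_frac <- (config$freq_range_hz[2] - config$freq_range_hz[1]) / (fs / 2)
      target_rms <- config$noise_level * sqrt(band_frac) * 10^(config$snr_db / 20)
      prev_end <- -Inf
      for (i in seq_len(n_ev)) {
        s <- onset[i]; e <- s + dur[i]
        if (s < prev_end || e > config$duration_s) next # thin overlaps, keep in range
        i0 <- as.integer(floor(s * fs)) + 1L
        i1 <- min(n, as.integer(ceiling(e * fs)))
        t <- (seq(i0, i1) - i0) / fs
        burst <- exp(-t / (dur[i] / 4)) * sin(2 * pi * carrier[i] * t + phase[i])
        rms <- sqrt(mean(burst^2))
        if (rms > 0) x[i0:i1] <- x[i0:i1] + burst * (target_rms / rms)
        starts <- c(starts, s); ends <- c(ends, e)
        prev_end <- e
      }
    }
    list(recording = bs_recording(pmin(pmax(x, -1), 1), fs),
         annotations = bs_annotations(starts, ends))
  })
}

#' Fraction of positive frames implied by an annotation set
#'
#' Applies the frame-labeling rule of [label_frames()] over the whole
#' recording and reports the positive share, e.g. to match a target class
#' balance such as the 15% positive frames of a clinical test set.
#'
#' @param ann A [bs_annotations()] object.
#' @param duration_s Recording length in seconds.
#' @param frame_ms Frame width in milliseconds.
#' @return Fraction in `[0, 1]`.
#' @export
positive_fraction <- function(ann, duration_s, frame_ms = 10) {
  n_frames <- floor(duration_s * 1000 / frame_ms)
  if (n_frames == 0L) return(0)
  mean(label_frames(ann, n_frames, frame_ms))
}
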