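#' Analysis window weights
#'
#' Cosine taper applied to each short-time block before the Fourier
#' transform: Hann `w(n) = 0.5 (1 - cos(2 pi n / N))` or Hamming
#' `w(n) = 0.54 - 0.46 cos(2 pi n / N)`, with `N = size_L - 1` and
#' `n = 0 ... N`.
#'
#' @param kind `"hann"` or `"hamming"`.
#' @param size_L Window length in samples (at least 2).
#' @return Numeric vector of `size_L` weights.
#' @export
window_weights <- function(kind = c("hann", "hamming"), size_L) {
  if (!is.character(kind) || !all(kind %in% c("hann", "hamming")))
    stop("unknown window kind: ", paste(kind, collapse = ", "))
  kind <- match.arg(kind)
  stopifnot(size_L >= 2)
  n <- 0:(size_L - 1)
  N <- size_L - 1
  if (kind == "hann") 0.5 * (1 - cos(2 * pi * n / N))
  else 0.54 - 0.46 * cos(2 * pi * n / N)
}

#' Spectrogram parameters
#'
#' Defaults are the selected operating point: 441-sample window (10 ms at
#' 44.1 kHz), 110-sample hop (25 %), Hann window, 0-1500 Hz band, amplitude
#' decibels floored at -100 dB.
#'
#' @param window Window kind, `"hann"` or `"hamming"`.
#' @param size_L Window length L in samples.
#' @param hop Window shift in samples; `NULL` means `floor(size_L / 4)`.
#' @param sample_rate Sampling rate in Hz.
#' @param max_freq Highest retained frequency in Hz (`<= sample_rate / 2`).
#' @param db_floor Decibel floor clamping `20 log10 |X|`.
#' @return An object of class `bs_stft_params`.
#' @export
stft_params <- function(window = "hann", size_L = 441L, hop = NULL,
                        sample_rate = 44100L, max_freq = 1500,
                        db_floor = -100) {
  if (is.null(hop)) hop <- floor(size_L / 4)
  stopifnot(size_L >= 2, hop > 0, hop <= size_L,
            max_freq > 0, max_freq <= sample_rate / 2)
  structure(
    list(window = window, size_L = as.integer(size_L), hop = as.integer(hop),
         sample_rate = as.integer(sample_rate), max_freq = max_freq,
         db_floor = db_floor),
    class = "bs_stft_params"
  )
}

#' Short-time Fourier transform
#'
#' `X[k, m] = sum_{n=0}^{L-1} w_n x[m hop + n] exp(-2 pi i k n / L)` for
#' `m = 0 ... M - 1`, `M = floor((n_samples - L) / hop) + 1`. No centering
#' and no zero padding: only complete windows are transformed.
#'
#' @param rec A [bs_recording()] with at least `size_L` samples.
#' @param params An [stft_params()] object.
#' @return List with `coeffs` (complex `L x M` matrix, bin k in row k + 1),
#'   `params`, and `n_samples` of the source signal.
#' @export
stft <- function(rec, params = stft_params()) {
  x <- rec$samples
  L <- params$size_L
  if (length(x) < L) stop("signal shorter than the analysis window (", L, " samples)")
  if (rec$sample_rate != params$sample_rate)
    stop("recording rate ", rec$sample_rate, " Hz does not match params rate ",
         params$sample_rate, " Hz; resample first")
  hop <- params$hop
  M <- floor((length(x) - L) / hop) + 1L
  idx <- outer(seq_len(L), (seq_len(M) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = L) * window_weights(params$window, L)
  list(coeffs = stats::mvfft(frames), params = params,
       n_samples = length(x), offset_s = rec$offset_s)
}

#' Decibel spectrogram restricted to the analysis band
#'
#' Amplitude decibels `20 log10(max(|X|, eps))` with
#' `eps = 10^(db_floor/20)`, keeping bins with frequency
#' `0 < k sample_rate / L <= max_freq`. The DC bin is excluded, which at
#' the defaults (100 Hz bin spacing) leaves exactly 15 bins at
#' 100, 200, ..., 1500 Hz; this crop realizes the low-pass stage.
#'
#' @param coeffs Output of [stft()].
#' @param params Parameters; defaults to those stored with the STFT.
#' @return An object of class `bs_spectrogram`: `values` is an
#'   `n_cols x n_bins` matrix (time rows, frequency columns), with
#'   `freq_axis` (Hz), `time_axis` (window start, seconds), `params`,
#'   `n_samples`, and a `standardized` flag.
#' @export
to_db_spectrogram <- function(coeffs, params = NULL) {
  if (is.null(params)) params <- coeffs$params
  L <- params$size_L
  fs <- params$sample_rate
  kmax <- floor(params$max_freq * L / fs)
  if (kmax < 1L) stop("max_freq below the first frequency bin (", fs / L, " Hz)")
  bins <- seq_len(kmax) # k = 1 ... kmax; DC excluded
  eps <- 10^(params$db_floor / 20)
  amp <- Mod(coeffs$coeffs[bins + 1L, , drop = FALSE])
  structure(
    list(values = t(20 * log10(pmax(amp, eps))),
         freq_axis = bins * fs / L,
         time_axis = (seq_len(ncol(coeffs$coeffs)) - 1L) * params$hop / fs,
         params = params,
         n_samples = coeffs$n_samples,
         offset_s = if (is.null(coeffs$offset_s)) 0 else coeffs$offset_s,
         standardized = FALSE),
    class = "bs_spectrogram"
  )
}

#' @export
print.bs_spectrogram <- function(x, ...) {
  cat(sprintf("<bs_spectrogram: %d cols x %d bins, %.0f-%.0f Hz, %s>\n",
              nrow(x$values), ncol(x$values), min(x$freq_axis),
              max(x$freq_axis),
              if (x$standardized) "standardized" else "dB"))
  invisible(x)
}

#' Global decibel statistics of a spectrogram collection
#'
#' Scalar mean and standard deviation pooled over every cell of every
#' spectrogram, used to standardize inputs before classification. The
#' standard deviation is the population form (divisor `N`).
#'
#' @param spectrograms A `bs_spectrogram` or a list of them.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
compute_norm_stats <- function(spectrograms) {
  if (inherits(spectrograms, "bs_spectrogram")) spectrograms <- list(spectrograms)
  if (length(spectrograms) == 0L) stop("no spectrograms supplied")
  cells <- unlist(lapply(spectrograms, function(s) as.vector(s$values)),
                  use.names = FALSE)
  if (length(cells) < 2L) stop("need at least 2 spectrogram cells")
  mu <- mean(cells)
  c(mean = mu, sd = sqrt(mean((cells - mu)^2)))
}

#' Standardize a spectrogram
#'
#' @param spec A `bs_spectrogram`.
#' @param mean,sd Decibel statistics, typically from [compute_norm_stats()]
#'   over the training recordings. `sd` must be positive.
#' @return The spectrogram with `values' = (values - mean) / sd` and the
#'   `standardized` flag set.
#' @export
standardize <- function(spec, mean, sd) {
  if (!is.finite(sd) || sd <= 0) stop("degenerate statistics: sd must be > 0")
  spec$values <- (spec$values - mean) / sd
  spec$standardized <- TRUE
  spec
}

#' Regroup spectrogram columns into classification frames
#'
#' Frame `m` (0-based) covers samples `[m F, (m+1) F)` with
#' `F = frame_ms * sample_rate / 1000` (441 at the defaults). Its block is
#' the `cols_per_frame` consecutive spectrogram columns starting at column
#' `floor(m F / hop)`, zero-padded on the right where the spectrogram ends.
#' A 2-s fragment at the defaults yields exactly 200 frames of 15 bins x 4
#' columns.
#'
#' @param spec A `bs_spectrogram` built from one fragment.
#' @param frame_ms Frame width in milliseconds.
#' @param cols_per_frame Spectrogram columns per frame block.
#' @return An object of class `bs_frame_tensor`: `blocks` is an array
#'   `n_frames x n_bins x cols_per_frame`; carries `frame_ms`,
#'   `standardized`, and the fragment `offset_s`.
#' @export
frame_tensor <- function(spec, frame_ms = 10, cols_per_frame = 4L) {
  if (cols_per_frame < 1L) stop("cols_per_frame must be at least 1")
  p <- spec$params
  Fsamp <- frame_ms * p$sample_rate / 1000
  n_frames <- floor(spec$n_samples / Fsamp)
  n_cols <- nrow(spec$values)
  n_bins <- ncol(spec$values)
  blocks <- array(0, dim = c(n_frames, n_bins, cols_per_frame))
  for (m in seq_len(n_frames)) {
    c0 <- floor((m - 1L) * Fsamp / p$hop) # 0-based first column
    cols <- (c0 + 1L):(c0 + cols_per_frame)
    ok <- cols <= n_cols
    if (any(ok))
      blocks[m, , seq_len(sum(ok))] <- t(spec$values[cols[ok], , drop = FALSE])
  }
  structure(
    list(blocks = blocks, frame_ms = frame_ms, n_bins = n_bins,
         cols_per_frame = as.integer(cols_per_frame),
         standardized = isTRUE(spec$standardized),
         offset_s = if (is.null(spec$offset_s)) 0 else spec$offset_s),
    class = "bs_frame_tensor"
  )
}

#' @export
print.bs_frame_tensor <- function(x, ...) {
  d <- dim(x$blocks)
  cat(sprintf("<bs_frame_tensor: %d frames x %d bins x %d cols (%g ms frames%s)>\n",
              d[1], d[2], d[3], x$frame_ms,
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}
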