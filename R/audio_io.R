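#' Recording objects
#'
#' A recording is a mono sequence of amplitude samples in `[-1, 1]` together
#' with its sample rate. All downstream processing (spectrograms, frame
#' classification) assumes this container.
#'
#' @param samples Numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param offset_s Offset of the first sample relative to the source
#'   recording, in seconds. Fragments produced by [fragment()] carry their
#'   source offset here.
#' @return An object of class `bs_recording` with fields `samples`,
#'   `sample_rate` and `offset_s`.
#' @seealso [read_wav()], [fragment()], [resample()]
#' @export
bs_recording <- function(samples, sample_rate, offset_s = 0) {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.integer(round(sample_rate)),
         offset_s = as.numeric(offset_s)),
    class = "bs_recording"
  )
}

#' @export
print.bs_recording <- function(x, ...) {
  cat(sprintf("<bs_recording: %d samples @ %d Hz, %.3f s, offset %.3f s>\n",
              length(x$samples), x$sample_rate, duration_s(x), x$offset_s))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [bs_recording()].
#' @return Length in seconds (`n_samples / sample_rate`).
#' @export
duration_s <- function(rec) length(rec$samples) / rec$sample_rate

# ---- RIFF WAV reading/writing -------------------------------------------
# Hand-written little-endian RIFF parser: supports PCM 16/24/32-bit integer
# and IEEE float 32/64, including WAVE_FORMAT_EXTENSIBLE headers.

.wav_fmt_pcm <- 1L
.wav_fmt_float <- 3L
.wav_fmt_extensible <- -2L # 0xFFFE read as signed 16-bit

#' Read a WAV file as a mono recording
#'
#' Integer PCM samples are scaled to `[-1, 1]` by the full-scale value of
#' their bit depth (`2^(bits-1)`); multi-channel audio is averaged to mono.
#'
#' @param path Path to a RIFF WAV file (PCM 16/24/32-bit or IEEE float).
#' @return A [bs_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        code = readBin(body[1:2], "integer", 1L, size = 2L, endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, size = 2L, endian = "little"),
        rate = readBin(body[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, size = 2L, endian = "little")
      )
      if (fmt$code == .wav_fmt_extensible && sz >= 26L) {
        # subformat GUID starts at byte 25; first two bytes give the code
        fmt$code <- readBin(body[25:26], "integer", 1L, size = 2L, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0L) stop("WAV file contains no audio data: ", path)

  x <- .decode_pcm(data_raw, fmt)
  if (length(x) == 0L) stop("WAV file contains no audio data: ", path)
  if (fmt$channels > 1L) {
    n <- floor(length(x) / fmt$channels)
    x <- colMeans(matrix(x[seq_len(n * fmt$channels)], nrow = fmt$channels))
  }
  bs_recording(x, fmt$rate)
}

.decode_pcm <- function(raw, fmt) {
  if (fmt$code == .wav_fmt_float) {
    if (fmt$bits == 32L) {
      return(readBin(raw, "double", length(raw) %/% 4L, size = 4L, endian = "little"))
    } else if (fmt$bits == 64L) {
      return(readBin(raw, "double", length(raw) %/% 8L, size = 8L, endian = "little"))
    }
    stop("unsupported float WAV bit depth: ", fmt$bits)
  }
  if (fmt$code != .wav_fmt_pcm) stop("unsupported WAV format code: ", fmt$code)
  if (fmt$bits == 16L) {
    readBin(raw, "integer", length(raw) %/% 2L, size = 2L, signed = TRUE,
            endian = "little") / 2^15
  } else if (fmt$bits == 24L) {
    n <- length(raw) %/% 3L
    b <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
    v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else if (fmt$bits == 32L) {
    readBin(raw, "integer", length(raw) %/% 4L, size = 4L, endian = "little") / 2^31
  } else {
    stop("unsupported PCM WAV bit depth: ", fmt$bits)
  }
}

#' Write a recording to a WAV file
#'
#' @param rec A [bs_recording()].
#' @param path Output path.
#' @param format One of `"pcm16"`, `"pcm24"`, `"pcm32"`, `"float32"`.
#'   Integer formats clamp and quantize (lossy within 1 LSB); `"float32"`
#'   round-trips within float precision.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, format = c("pcm24", "pcm16", "pcm32", "float32")) {
  format <- match.arg(format)
  x <- rec$samples
  bits <- switch(format, pcm16 = 16L, pcm24 = 24L, pcm32 = 32L, float32 = 32L)
  code <- if (format == "float32") .wav_fmt_float else .wav_fmt_pcm
  block <- bits %/% 8L
  byte_rate <- rec$sample_rate * block
  data_sz <- length(x) * block

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little") # mono
  writeBin(as.integer(rec$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(block), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4L, endian = "little")

  if (format == "float32") {
    writeBin(x, con, size = 4L, endian = "little")
  } else {
    full <- 2^(bits - 1L)
    v <- round(x * full)
    v <- pmin(pmax(v, -full), full - 1)
    if (format == "pcm16") {
      writeBin(as.integer(v), con, size = 2L, endian = "little")
    } else if (format == "pcm32") {
      writeBin(as.integer(v), con, size = 4L, endian = "little")
    } else {
      v <- ifelse(v < 0, v + 2^24, v)
      b <- rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)
      writeBin(as.raw(as.vector(b)), con)
    }
  }
  if (data_sz %% 2L == 1L) writeBin(as.raw(0L), con)
  invisible(path)
}

#' Resample a recording to a target rate
#'
#' Fourier-domain resampling (zero-pad or truncate the spectrum), which
#' preserves in-band tone frequencies exactly. A no-op when the rates
#' already match. Duration is preserved to within one sample period.
#'
#' @param rec A [bs_recording()].
#' @param target_rate Target sampling rate in Hz.
#' @return A resampled [bs_recording()].
#' @export
resample <- function(rec, target_rate) {
  stopifnot(target_rate > 0)
  target_rate <- as.integer(round(target_rate))
  if (target_rate == rec$sample_rate) return(rec)
  n <- length(rec$samples)
  m <- max(1L, as.integer(round(as.numeric(n) * target_rate / rec$sample_rate)))
  bs_recording(.fft_resample(rec$samples, m), target_rate, rec$offset_s)
}

.fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  keep <- min(n, m)
  half <- (keep - 1L) %/% 2L # strictly-positive frequencies kept per side
  Y[1L] <- X[1L]
  if (half > 0L) {
    Y[2L:(half + 1L)] <- X[2L:(half + 1L)]
    Y[(m - half + 1L):m] <- X[(n - half + 1L):n]
  }
  if (keep %% 2L == 0L) {
    k <- keep %/% 2L
    if (m > n) { # upsampling: split the source Nyquist bin
      Y[k + 1L] <- X[k + 1L] / 2
      Y[m - k + 1L] <- X[k + 1L] / 2
    } else {     # downsampling: fold the aliased pair onto the new Nyquist
      Y[k + 1L] <- X[k + 1L] + X[n - k + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Split a recording into fixed-length fragments
#'
#' Consecutive non-overlapping fragments of exactly `fragment_s` seconds;
#' a trailing remainder shorter than one fragment is discarded. Each
#' fragment records its source offset in `offset_s`.
#'
#' @param rec A [bs_recording()].
#' @param fragment_s Fragment length in seconds (default 2, the model input
#'   length of 200 frames).
#' @return A list of [bs_recording()] fragments (possibly empty).
#' @export
fragment <- function(rec, fragment_s = 2.0) {
  stopifnot(fragment_s > 0)
  nf <- as.integer(round(fragment_s * rec$sample_rate))
  k <- floor(length(rec$samples) / nf)
  if (k < 1L) return(list())
  lapply(seq_len(k), function(i) {
    bs_recording(rec$samples[((i - 1L) * nf + 1L):(i * nf)],
                 rec$sample_rate,
                 offset_s = rec$offset_s + (i - 1L) * fragment_s)
  })
}
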