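test_that("window weights match their closed forms and symmetry", {
  h <- window_weights("hann", 441)
  hm <- window_weights("hamming", 441)
  expect_equal(h[1], 0)                       # cos(0) = 1
  expect_equal(hm[1], 0.08)                   # 0.54 - 0.46
  # N = 440 even: midpoint n = N/2 reaches exactly 1
  expect_equal(h[221], 1)
  expect_equal(hm[221], 1)
  # symmetry w(n) = w(N - n), non-negativity
  for (w in list(h, hm)) {
    expect_equal(w, rev(w))
    expect_true(all(w >= 0))
  }
  expect_error(window_weights("blackman", 64), "unknown window")
})

test_that("stft equals the brute-force windowed DFT", {
  set.seed(11)
  x <- rnorm(1000)
  p <- stft_params(size_L = 64L, hop = 16L, sample_rate = 8000L,
                   max_freq = 4000)
  S <- stft(bs_recording(x, 8000), p)
  oracle <- brute_stft(x, window_weights("hann", 64), 16)
  expect_equal(dim(S$coeffs), dim(oracle))
  expect_lt(max(Mod(S$coeffs - oracle)) / max(Mod(oracle)), 1e-9)
})

test_that("DC concentration, tone bins and short-signal errors", {
  # constant signal: X[0, m] = c * sum(w); mid bins ~ 0
  p <- stft_params(size_L = 64L, hop = 32L, sample_rate = 8000L,
                   max_freq = 4000)
  S <- stft(bs_recording(rep(0.5, 256), 8000), p)
  expect_equal(Re(S$coeffs[1, ]), rep(0.5 * sum(window_weights("hann", 64)), 7),
               tolerance = 1e-12)
  # symmetric Hann is not DFT-periodic, so mid bins carry small leakage
  expect_lt(max(Mod(S$coeffs[17:49, ])) / Mod(S$coeffs[1, 1]), 1e-3)

  # 1500 Hz tone at the defaults lands in bin 15 (100 Hz spacing)
  tone <- sin(2 * pi * 1500 * (0:88199) / 44100)
  sp <- to_db_spectrogram(stft(bs_recording(tone, 44100), stft_params()))
  expect_equal(which.max(colMeans(sp$values)), 15L)
  expect_equal(sp$freq_axis[15], 1500)

  expect_error(stft(bs_recording(rnorm(100), 44100), stft_params()),
               "shorter than")
})

test_that("decibel conversion, floor clamp and the 15-bin crop", {
  # |X| = 1 -> 0 dB on a synthetic coefficient set
  fake <- list(coeffs = matrix(1 + 0i, 441, 3), n_samples = 441 + 2 * 110,
               params = stft_params(), offset_s = 0)
  sp <- to_db_spectrogram(fake)
  expect_equal(unname(as.vector(sp$values)), rep(0, 15 * 3))

  # |X| = 0 clamps at the -100 dB floor
  fake$coeffs <- matrix(0 + 0i, 441, 3)
  expect_equal(unname(as.vector(to_db_spectrogram(fake)$values)),
               rep(-100, 15 * 3))

  # default crop: 15 bins at 100, 200, ..., 1500 Hz (DC excluded)
  expect_equal(sp$freq_axis, seq(100, 1500, by = 100))
  expect_equal(ncol(sp$values), 15L)
})

test_that("global normalization statistics match a two-pass oracle", {
  mk <- function(vals) {
    structure(list(values = vals, standardized = FALSE), class = "bs_spectrogram")
  }
  one <- mk(matrix(-40, 10, 5))
  expect_equal(compute_norm_stats(one), c(mean = -40, sd = 0))
  expect_equal(compute_norm_stats(mk(matrix(c(-10, -20, -30, -40), 2)))[["mean"]],
               -25)

  set.seed(3)
  sps <- lapply(1:4, function(i) mk(matrix(rnorm(200, -50, 12), 20)))
  got <- compute_norm_stats(sps)
  cells <- unlist(lapply(sps, function(s) as.vector(s$values)))
  mu <- sum(cells) / length(cells)
  sd2 <- sqrt(sum((cells - mu)^2) / length(cells))
  expect_equal(got[["mean"]], mu, tolerance = 1e-12)
  expect_equal(got[["sd"]], sd2, tolerance = 1e-12)
  expect_error(compute_norm_stats(list()), "no spectrograms")
})

test_that("standardization centers and scales as defined", {
  rec <- bs_recording(rnorm(88200, 0, 0.1), 44100)
  sp <- to_db_spectrogram(stft(rec, stft_params()))
  expect_identical(standardize(sp, 0, 1)$values, sp$values)
  ns <- compute_norm_stats(sp)
  z <- standardize(sp, ns[["mean"]], ns[["sd"]])
  expect_true(z$standardized)
  expect_equal(mean(z$values), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((z$values - mean(z$values))^2)), 1, tolerance = 1e-9)
  expect_error(standardize(sp, -40, 0), "sd must be > 0")
})

test_that("frame tensor shape, column alignment and zero padding", {
  set.seed(4)
  rec <- bs_recording(rnorm(88200, 0, 0.1), 44100)
  sp <- to_db_spectrogram(stft(rec, stft_params()))
  ft <- frame_tensor(sp)
  expect_equal(dim(ft$blocks), c(200L, 15L, 4L))

  # frame 0 takes columns 0-3; frame 1 starts at floor(441/110) = 4
  expect_equal(ft$blocks[1, , ], t(sp$values[1:4, ]))
  expect_equal(ft$blocks[2, , ], t(sp$values[5:8, ]))

  # every block is a slice (or zero-padded slice) of the spectrogram
  n_cols <- nrow(sp$values)
  for (m in sample(200, 20)) {
    c0 <- floor((m - 1) * 441 / 110)
    for (j in 1:4) {
      col <- c0 + j
      expected <- if (col <= n_cols) sp$values[col, ] else rep(0, 15)
      expect_equal(ft$blocks[m, , j], expected)
    }
  }
  expect_error(frame_tensor(sp, cols_per_frame = 0), "cols_per_frame")
})
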