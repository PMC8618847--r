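test_that("generation is seeded, bounded and event-free at rate zero", {
  cfg <- synth_config(duration_s = 5, events_per_min = 0, seed = 4)
  syn <- synth_generate(cfg)
  expect_equal(nrow(syn$annotations), 0L)
  expect_equal(sqrt(mean(syn$recording$samples^2)), cfg$noise_level,
               tolerance = 0.05)

  a <- synth_generate(synth_config(duration_s = 5, seed = 8))
  b <- synth_generate(synth_config(duration_s = 5, seed = 8))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(as.data.frame(a$annotations), as.data.frame(b$annotations))

  expect_error(synth_generate(synth_config(events_per_min = 1000)),
               "infeasible")
})

test_that("annotations stay in range and never overlap", {
  for (seed in 1:5) {
    syn <- synth_generate(synth_config(duration_s = 30, events_per_min = 60,
                                       seed = seed))
    ann <- syn$annotations
    expect_true(all(ann$start >= 0 & ann$end <= 30))
    if (nrow(ann) > 1)
      expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
  }
})

test_that("in-band energy concentrates inside annotated intervals", {
  syn <- synth_generate(synth_config(duration_s = 60, events_per_min = 40,
                                     snr_db = 20, seed = 13))
  x <- syn$recording$samples
  fs <- syn$recording$sample_rate
  # FFT band-pass 60-1500 Hz as the independent band filter
  X <- fft(x)
  freqs <- (seq_along(x) - 1) * fs / length(x)
  freqs <- pmin(freqs, fs - freqs)
  X[freqs < 60 | freqs > 1500] <- 0
  xb <- Re(fft(X, inverse = TRUE)) / length(x)
  inside <- logical(length(x))
  for (i in seq_len(nrow(syn$annotations))) {
    i0 <- floor(syn$annotations$start[i] * fs) + 1
    i1 <- ceiling(syn$annotations$end[i] * fs)
    inside[i0:i1] <- TRUE
  }
  expect_gt(sqrt(mean(xb[inside]^2)), sqrt(mean(xb[!inside]^2)))
})

test_that("realized event rate matches the configured rate", {
  # overlap thinning removes ~ rate*duration/60 of candidate events, so the
  # calibration check runs at a density where that bias is negligible
  rate <- 20
  counts <- vapply(1:100, function(seed) {
    nrow(synth_generate(synth_config(duration_s = 30, events_per_min = rate,
                                     seed = seed))$annotations)
  }, numeric(1))
  realized <- mean(counts) * 2        # per minute
  se <- sd(counts) * 2 / sqrt(length(counts))
  expect_lt(abs(realized - rate), 3 * se)
})

test_that("snr monotonically raises baseline sensitivity at fixed cutoff", {
  sens_at <- function(snr, seed) {
    syn <- synth_generate(synth_config(duration_s = 30, events_per_min = 40,
                                       snr_db = snr, seed = seed))
    ds <- build_dataset(syn$recording, syn$annotations)
    pred <- unlist(lapply(ds$items, function(it) {
      ft <- structure(list(blocks = it$x, frame_ms = 10, standardized = TRUE,
                           offset_s = it$offset_s),
                      class = "bs_frame_tensor")
      baseline_classify(ft, baseline_config(0.5))$decisions
    }))
    truth <- unlist(lapply(ds$items, `[[`, "y"))
    confusion(pred, truth)$sensitivity
  }
  sens <- vapply(c(5, 15, 25), function(snr)
    mean(vapply(1:5, function(s) sens_at(snr, s), numeric(1))), numeric(1))
  expect_true(all(diff(sens) > 0))
})

test_that("positive_fraction reflects coverage and is tunable by bisection", {
  expect_equal(positive_fraction(bs_annotations(), 10), 0)
  expect_equal(positive_fraction(bs_annotations(0, 10), 10), 1)

  # bisection on events_per_min reaches a 15% positive-frame target
  target <- 0.15
  frac_at <- function(rate) {
    mean(vapply(1:3, function(s)
      positive_fraction(synth_generate(
        synth_config(duration_s = 60, events_per_min = rate,
                     seed = s))$annotations, 60), numeric(1)))
  }
  lo <- 10; hi <- 300
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (frac_at(mid) < target) lo <- mid else hi <- mid
  }
  expect_lt(abs(frac_at((lo + hi) / 2) - target), 0.02)
})
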