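mk_events <- function(starts, dur = 0.03) {
  structure(data.frame(start = starts, end = starts + dur,
                       n_frames = as.integer(round(dur / 0.01)),
                       mean_probability = 0.9),
            class = c("bs_events", "data.frame"))
}

test_that("inter-event intervals are onset-to-onset", {
  expect_equal(event_intervals(mk_events(c(1.0, 2.0, 3.5))), c(1.0, 1.5))
  expect_length(event_intervals(mk_events(1.0)), 0L)
  expect_equal(event_intervals(mk_events(seq(0, 4, by = 0.5))), rep(0.5, 8))
})

test_that("rmssd matches its definition and a brute-force oracle", {
  expect_equal(rmssd(c(1, 2, 3)), 1.0)
  expect_equal(rmssd(rep(0.7, 10)), 0)
  expect_true(is.na(rmssd(c(1))))
  set.seed(41)
  for (rep in 1:20) {
    iv <- runif(sample(2:30, 1), 0.1, 3)
    acc <- 0
    for (i in seq_len(length(iv) - 1)) acc <- acc + (iv[i + 1] - iv[i])^2
    expect_equal(rmssd(iv), sqrt(acc / (length(iv) - 1)), tolerance = 1e-12)
  }
})

test_that("Porta's index counts negative interval changes", {
  expect_equal(porta_index(c(1.0, 0.8, 1.2)), 50.0)
  expect_equal(porta_index(1:5), 0.0)
  expect_true(is.na(porta_index(rep(1, 5))))
  # sign-flipping the difference sequence maps PI -> 100 - PI
  set.seed(42)
  for (rep in 1:50) {
    d <- rnorm(sample(3:40, 1))
    d <- d[d != 0]
    iv <- cumsum(c(5, d))
    expect_equal(porta_index(iv) + porta_index(cumsum(c(5, -d))), 100)
  }
})

test_that("Guzik's index shares squared distance between sides", {
  expect_equal(guzik_index(cumsum(c(2, 1, -1))), 50.0)
  expect_equal(guzik_index(c(5, 4, 3, 2)), 0.0)
  expect_true(is.na(guzik_index(rep(1, 5))))
  set.seed(43)
  for (rep in 1:50) {
    d <- rnorm(sample(3:40, 1))
    d <- d[d != 0]
    expect_equal(guzik_index(cumsum(c(9, d))) + guzik_index(cumsum(c(9, -d))),
                 100, tolerance = 1e-9)
  }
})

test_that("asymmetry indices stay in [0, 100] and center at 50 for iid series", {
  set.seed(44)
  iv <- rexp(10000, rate = 1)
  pi_ <- porta_index(iv); gi <- guzik_index(iv)
  expect_true(pi_ >= 0 && pi_ <= 100)
  expect_true(gi >= 0 && gi <= 100)
  expect_equal(pi_, 50, tolerance = 2)
  expect_equal(gi, 50, tolerance = 2)
})

test_that("report aggregates counts, windows and durations correctly", {
  ev <- mk_events(seq(2, 118, length.out = 12))
  rep_ <- compute_report(ev, 120)
  expect_equal(rep_$events_per_min, 6.0)
  expect_equal(sum(rep_$per_minute_counts), 12)

  one <- compute_report(mk_events(5, dur = 0.030), 60)
  expect_equal(one$duration_histogram$count[3], 1L)
  expect_equal(one$duration_histogram$percent[3], 100)
  expect_equal(sum(one$duration_histogram$count), 1L)

  expect_error(compute_report(mk_events(1), 0), "positive")
  expect_error(compute_report(mk_events(100), 60), "outside")
})

test_that("report conservation laws hold on random event sets", {
  set.seed(45)
  for (rep in 1:30) {
    n <- sample(3:60, 1)
    starts <- sort(runif(n, 0, 570))
    starts <- starts[c(TRUE, diff(starts) > 0.2)]
    ev <- mk_events(starts, dur = sample(1:15, 1) / 100)
    rp <- compute_report(ev, 600)
    expect_equal(sum(rp$duration_histogram$count), nrow(ev))
    expect_equal(sum(rp$duration_histogram$percent), 100, tolerance = 1e-9)
    expect_equal(sum(rp$per_minute_counts),
                 sum(ev$start < 60 * floor(600 / 60)))
    expect_equal(nrow(rp$three_min_stats), floor(10 / 3))
  }
})

test_that("an event-free tail under one minute changes no statistic", {
  ev <- mk_events(sort(runif(25, 0, 170)))
  a <- compute_report(ev, 180)
  b <- compute_report(ev, 180 + 45)
  for (fld in c("n_events", "events_per_min", "per_minute_counts",
                "three_min_stats", "duration_histogram", "rmssd_s",
                "sd_intervals_s", "porta_index_pct", "guzik_index_pct")) {
    expect_identical(a[[fld]], b[[fld]])
  }
})
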