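test_that("architectures reproduce the published parameter counts", {
  crnn <- build_model(model_spec("crnn"))
  cdnn <- build_model(model_spec("cdnn"))
  # closed-form sums: conv (3*3*1+1)*30 + (4*2*30+1)*60, biGRU
  # 2*3*(600*80 + 80*80 + 2*80), dense 2*80+1
  expect_identical(count_params(crnn), 342281L)
  # (60+1)*120 + (9*120+1)*100 + (100+1)
  expect_identical(count_params(cdnn), 115521L)
  expect_equal(floor(count_params(crnn) / 1000) * 1000, 342000)
  expect_equal(floor(count_params(cdnn) / 1000) * 1000, 115000)
})

test_that("baseline thresholds frame means and is monotone in the cutoff", {
  blocks <- array(0, dim = c(3, 15, 4))
  blocks[2, , ] <- 0.08
  ft <- structure(list(blocks = blocks, frame_ms = 10, standardized = TRUE,
                       offset_s = 0), class = "bs_frame_tensor")
  pred <- baseline_classify(ft, baseline_config(0.07))
  expect_equal(pred$decisions, c(0L, 1L, 0L))

  ft$standardized <- FALSE
  expect_error(baseline_classify(ft), "standardized")

  # lowering the cutoff only ever adds positives (nested decision sets)
  ds <- make_tiny_dataset(duration_s = 10, seed = 5)
  ft <- structure(list(blocks = ds$items[[1]]$x, frame_ms = 10,
                       standardized = TRUE, offset_s = 0),
                  class = "bs_frame_tensor")
  cutoffs <- c(0.20, 0.10, 0.07, 0.05)
  decs <- lapply(cutoffs, function(cu)
    baseline_classify(ft, baseline_config(cu))$decisions)
  for (i in seq_len(length(decs) - 1))
    expect_true(all(decs[[i + 1]] >= decs[[i]]))
})

test_that("augmentation adds calibrated noise and keeps originals", {
  set.seed(6)
  ds <- lapply(1:17, function(i)
    list(x = array(rnorm(200 * 15 * 4), dim = c(200, 15, 4)),
         y = rbinom(200, 1, 0.15)))
  same <- augment(ds[1:2], sigma = 0, copies = 2, seed = 1)
  expect_length(same, 6L)
  expect_identical(same[[3]]$x, ds[[1]]$x)

  out <- augment(ds, sigma = 0.05, copies = 5, seed = 2)
  expect_length(out, (5 + 1) * 17L)
  expect_identical(out[[1]]$x, ds[[1]]$x)
  expect_identical(out[[18]]$y, ds[[1]]$y)
  diffs <- unlist(lapply(seq_along(ds), function(i)
    out[[17 + i]]$x - ds[[i]]$x))
  expect_gt(length(diffs), 1e6 / 5)
  expect_equal(sd(diffs), 0.05, tolerance = 0.001)
})

test_that("analytic gradients match finite differences on tiny models", {
  ns <- asNamespace("bsound")
  set.seed(7)
  for (kind in c("cdnn", "crnn")) {
    spec <- model_spec(kind, seq_len = 10L, n_bins = 7L, cols = 4L,
                       conv1_filters = 3L, conv2_filters = 4L, gru_units = 5L,
                       dense1 = 6L, context = 5L, dense2 = 7L, dropout = 0)
    model <- build_model(spec, seed = 3)
    B <- 2L; T <- spec$seq_len
    X <- matrix(rnorm(B * T * spec$n_bins * spec$cols), B * T)
    y <- rbinom(B * T, 1, 0.3)
    ci <- if (kind == "crnn")
      ns$.conv_indices(spec$n_bins, spec$cols, spec$conv1_filters)
    loss_fn <- function(P) {
      fw <- ns$.forward_model(list(spec = spec, params = P), X, B, T, ci = ci)
      ns$.bce_loss(fw$prob, y)
    }
    fw <- ns$.forward_model(model, X, B, T, ci = ci)
    grads <- if (kind == "crnn")
      ns$.crnn_backward(model$params, fw, y, B, T, ci, spec)
    else ns$.cdnn_backward(model$params, fw, y, B, T, spec)
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      for (i in sample(length(p), min(5, length(p)))) {
        eps <- 1e-5
        P1 <- model$params; P1[[nm]][i] <- P1[[nm]][i] + eps
        P2 <- model$params; P2[[nm]][i] <- P2[[nm]][i] - eps
        num <- (loss_fn(P1) - loss_fn(P2)) / (2 * eps)
        ana <- grads[[nm]][i]
        expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-5)
      }
    }
  }
})

test_that("training runs, is seeded, and flags single-class labels", {
  ds <- make_tiny_dataset()
  for (kind in c("crnn", "cdnn")) {
    m <- build_model(model_spec(kind), seed = 1)
    m <- train_model(m, ds$items[1:2], ds$items[3:4],
                     cfg = train_config(epochs = 1, seed = 1))
    expect_true(is.finite(m$history$loss[1]))
    m2 <- train_model(build_model(model_spec(kind), seed = 1),
                      ds$items[1:2], ds$items[3:4],
                      cfg = train_config(epochs = 1, seed = 1))
    expect_identical(m$history, m2$history)
  }

  blank <- lapply(ds$items[1:2], function(it) { it$y[] <- 0L; it })
  expect_warning(
    train_model(build_model(model_spec("cdnn")), blank,
                cfg = train_config(epochs = 1)),
    "single-class")
})

test_that("prediction contracts: shape, range, interchangeability, sigmoid(0)", {
  ds <- make_tiny_dataset()
  item <- ds$items[[1]]
  for (kind in c("crnn", "cdnn")) {
    m <- build_model(model_spec(kind), seed = 2)
    p <- predict(m, list(x = item$x))
    expect_length(p$probabilities, 200L)
    expect_true(all(p$probabilities >= 0 & p$probabilities <= 1))
    expect_identical(p$decisions, as.integer(p$probabilities > 0.5))
    # zeroed output layer pins every probability at sigmoid(0) = 0.5
    if (kind == "crnn") {
      m$params$Wd[] <- 0; m$params$bd <- 0
    } else {
      m$params$W3[] <- 0; m$params$b3 <- 0
    }
    expect_equal(predict(m, list(x = item$x))$probabilities, rep(0.5, 200))
  }
})
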