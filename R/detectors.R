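#' Baseline threshold detector configuration
#'
#' The simplest detector: a frame is a bowel sound when the mean of its
#' standardized spectrogram block (the 0-1500 Hz content) exceeds a fixed
#' cut-off. The default cut-off 0.07 is the best-accuracy operating point
#' of the threshold baseline.
#'
#' @param cutoff Threshold on the standardized-decibel frame mean.
#' @return An object of class `bs_baseline`.
#' @export
baseline_config <- function(cutoff = 0.07) {
  stopifnot(is.finite(cutoff))
  structure(list(kind = "baseline", cutoff = cutoff), class = "bs_baseline")
}

#' Frame predictions container
#'
#' @param probabilities Per-frame scores. For the neural models these are
#'   sigmoid probabilities in `[0, 1]`; for the baseline they are
#'   standardized-dB frame means (unbounded).
#' @param threshold Decision threshold; `decisions = probabilities > threshold`.
#' @param offset_s Time of frame 0 relative to the recording start.
#' @param frame_ms Frame width in milliseconds.
#' @return An object of class `bs_predictions`.
#' @export
bs_predictions <- function(probabilities, threshold = 0.5, offset_s = 0,
                           frame_ms = 10) {
  structure(
    list(probabilities = as.numeric(probabilities),
         threshold = threshold,
         decisions = as.integer(probabilities > threshold),
         offset_s = offset_s, frame_ms = frame_ms),
    class = "bs_predictions"
  )
}

#' @export
print.bs_predictions <- function(x, ...) {
  cat(sprintf("<bs_predictions: %d frames, %d positive at threshold %g>\n",
              length(x$probabilities), sum(x$decisions), x$threshold))
  invisible(x)
}

#' Classify frames with the mean-amplitude baseline
#'
#' Each frame's score is the mean over its `n_bins x cols_per_frame`
#' standardized spectrogram block; the decision is `score > cutoff`.
#' Requires standardized input: the cut-off is calibrated in standardized
#' decibel units.
#'
#' @param frames A [frame_tensor()] built from a standardized spectrogram.
#' @param cfg A [baseline_config()].
#' @return A [bs_predictions()] whose `probabilities` field holds the raw
#'   frame means.
#' @export
baseline_classify <- function(frames, cfg = baseline_config()) {
  if (!isTRUE(frames$standardized))
    stop("baseline_classify requires a standardized frame tensor")
  scores <- apply(frames$blocks, 1L, mean)
  bs_predictions(scores, threshold = cfg$cutoff, offset_s = frames$offset_s,
                 frame_ms = frames$frame_ms)
}

#' Neural frame-classifier architecture specification
#'
#' Two architectures share the convolutional feature idea on
#' `n_bins x cols` frame blocks of a 200-frame sequence:
#'
#' * `crnn` — per-frame 2-D convolutions (30 filters 3x3 then 60 filters
#'   4x2, valid padding, ReLU), flattened to 600 features, dropout, a
#'   bidirectional GRU with 80 units per direction (reset-after gates,
#'   ReLU candidate, sequence-returning), dropout, and a per-frame
#'   sigmoid unit. 342,281 trainable parameters at the defaults.
#' * `cdnn` — per-frame flatten (60) to a dense ReLU layer of 120 units,
#'   concatenation of the 9 adjacent frames' vectors (zero-padded at the
#'   sequence edges), dropout, dense ReLU 100, and a sigmoid unit.
#'   115,521 trainable parameters at the defaults.
#'
#' @param kind `"crnn"` or `"cdnn"`.
#' @param seq_len Frames per input sequence (200 for 2-s fragments).
#' @param n_bins Spectrogram bins per frame (15 at the default crop).
#' @param cols Spectrogram columns per frame (4 at the default hop).
#' @param conv1_filters,conv2_filters CRNN convolution widths.
#' @param gru_units CRNN GRU units per direction.
#' @param dense1 CDNN per-frame feature width.
#' @param context CDNN adjacent-frame context (odd).
#' @param dense2 CDNN post-context hidden width.
#' @param dropout Dropout probability applied after the feature stage and
#'   before the output stage during training.
#' @return An object of class `bs_model_spec`.
#' @export
model_spec <- function(kind = c("crnn", "cdnn"), seq_len = 200L,
                       n_bins = 15L, cols = 4L,
                       conv1_filters = 30L, conv2_filters = 60L,
                       gru_units = 80L, dense1 = 120L, context = 9L,
                       dense2 = 100L, dropout = 0.4) {
  kind <- match.arg(kind)
  stopifnot(seq_len >= 1, n_bins >= 1, cols >= 1, context %% 2 == 1,
            dropout >= 0, dropout < 1)
  structure(
    list(kind = kind, seq_len = as.integer(seq_len),
         n_bins = as.integer(n_bins), cols = as.integer(cols),
         conv1_filters = as.integer(conv1_filters),
         conv2_filters = as.integer(conv2_filters),
         gru_units = as.integer(gru_units), dense1 = as.integer(dense1),
         context = as.integer(context), dense2 = as.integer(dense2),
         dropout = dropout),
    class = "bs_model_spec"
  )
}

#' Build an untrained frame classifier
#'
#' Weights are initialized Glorot-uniform (biases zero) from `seed`;
#' construction validates that the convolution stack is consistent with
#' the block shape.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `bs_model` with fields `spec`, `params`
#'   (named weight arrays), and `norm` (standardization statistics, set
#'   by [train_model()]).
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  params <- with_seed(seed, {
    if (spec$kind == "crnn") {
      ci <- .conv_indices(spec$n_bins, spec$cols, spec$conv1_filters)
      feat <- ci$np2 * spec$conv2_filters
      H <- spec$gru_units
      gru_dir <- function() list(
        Wx = .glorot(feat, H, c(feat, 3L * H)),
        Wh = .glorot(H, H, c(H, 3L * H)),
        bx = numeric(3L * H), bh = numeric(3L * H))
      f <- gru_dir(); b <- gru_dir()
      list(W1 = .glorot(9L, spec$conv1_filters),
           b1 = numeric(spec$conv1_filters),
           W2 = .glorot(8L * spec$conv1_filters, spec$conv2_filters),
           b2 = numeric(spec$conv2_filters),
           Wxf = f$Wx, Whf = f$Wh, bxf = f$bx, bhf = f$bh,
           Wxb = b$Wx, Whb = b$Wh, bxb = b$bx, bhb = b$bh,
           Wd = .glorot(2L * H, 1L), bd = 0)
    } else {
      in_dim <- spec$n_bins * spec$cols
      ctx <- spec$context * spec$dense1
      list(W1 = .glorot(in_dim, spec$dense1), b1 = numeric(spec$dense1),
           W2 = .glorot(ctx, spec$dense2), b2 = numeric(spec$dense2),
           W3 = .glorot(spec$dense2, 1L), b3 = 0)
    }
  })
  structure(list(spec = spec, params = params, norm = NULL, history = NULL,
                 best_epoch = NA_integer_),
            class = "bs_model")
}

#' @export
print.bs_model <- function(x, ...) {
  cat(sprintf("<bs_model %s: %s trainable parameters%s>\n",
              toupper(x$spec$kind),
              format(count_params(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)"
              else sprintf(", best epoch %d", x$best_epoch)))
  invisible(x)
}

#' Trainable parameter count of a model
#' @param model A [build_model()] object.
#' @return Total number of weights and biases.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Training configuration
#'
#' Binary cross-entropy loss minimized with Adam at its default
#' parameters. The retained checkpoint is the best epoch by validation
#' accuracy.
#'
#' @param epochs Training epochs (default 100).
#' @param batch_size Sequences per minibatch.
#' @param lr,beta1,beta2,epsilon Adam parameters (defaults 0.001, 0.9,
#'   0.999, 1e-7).
#' @param augmentation_sigma Standard deviation of Gaussian spectrogram
#'   noise augmentation; `NULL` disables augmentation.
#' @param augmentation_copies Noisy replicas per training sequence.
#' @param threshold Decision threshold on the sigmoid output.
#' @param seed Integer seed governing shuffling, dropout and augmentation.
#' @param verbose Print per-epoch progress.
#' @return An object of class `bs_train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         augmentation_sigma = NULL, augmentation_copies = 5L,
                         threshold = 0.5, seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         augmentation_sigma = augmentation_sigma,
         augmentation_copies = as.integer(augmentation_copies),
         threshold = threshold, seed = as.integer(seed), verbose = verbose),
    class = "bs_train_config"
  )
}

#' Enlarge a training set with Gaussian spectrogram noise
#'
#' For each input sequence, `copies` replicas are created by adding
#' i.i.d. `N(0, sigma^2)` noise to the standardized spectrogram values;
#' labels are copied unchanged and the originals are retained, so the
#' output holds `(copies + 1)` times the input sequences.
#'
#' @param dataset List of sequence items `list(x = , y = )` as built by
#'   [build_dataset()].
#' @param sigma Noise standard deviation (`>= 0`).
#' @param copies Replicas per sequence.
#' @param seed Integer seed.
#' @return The enlarged dataset list (originals first).
#' @export
augment <- function(dataset, sigma, copies = 5L, seed = 1L) {
  stopifnot(sigma >= 0)
  if (copies < 1L) return(dataset)
  with_seed(seed, {
    replicas <- lapply(seq_len(copies), function(k) {
      lapply(dataset, function(item) {
        item$x <- item$x + stats::rnorm(length(item$x), 0, sigma)
        item
      })
    })
    c(dataset, unlist(replicas, recursive = FALSE))
  })
}

# Stack a dataset's sequences into the Nf x (n_bins*cols) frame matrix the
# network engine expects (sequence-major rows), with per-frame labels.
.stack_dataset <- function(dataset, spec) {
  T <- spec$seq_len
  in_dim <- spec$n_bins * spec$cols
  mats <- lapply(dataset, function(item) {
    x <- if (inherits(item$x, "bs_frame_tensor")) item$x$blocks else item$x
    d <- dim(x)
    if (d[1] != T || d[2] != spec$n_bins || d[3] != spec$cols)
      stop("sequence shape ", paste(d, collapse = "x"),
           " does not match model spec ", T, "x", spec$n_bins, "x", spec$cols)
    matrix(x, T, in_dim)
  })
  list(X = do.call(rbind, mats),
       Y = unlist(lapply(dataset, function(item) as.numeric(item$y))),
       B = length(dataset), T = T)
}

.forward_model <- function(model, X, B, T, masks = NULL, ci = NULL) {
  if (model$spec$kind == "crnn") {
    if (is.null(ci))
      ci <- .conv_indices(model$spec$n_bins, model$spec$cols,
                          model$spec$conv1_filters)
    .crnn_forward(model$params, X, B, T, ci, model$spec, masks)
  } else {
    .cdnn_forward(model$params, X, B, T, model$spec, masks)
  }
}

.eval_metrics <- function(model, val, threshold, ci = NULL) {
  sv <- .stack_dataset(val, model$spec)
  fw <- .forward_model(model, sv$X, sv$B, sv$T, ci = ci)
  res <- confusion(as.integer(fw$prob > threshold), sv$Y)
  list(metrics = res, loss = .bce_loss(fw$prob, sv$Y))
}

#' Train a frame classifier
#'
#' Minimizes per-frame binary cross-entropy with Adam on minibatches of
#' whole sequences. After each epoch the model is evaluated on the
#' validation set; the retained weights are those of the best epoch by
#' validation accuracy (earliest epoch on ties). With no validation set
#' the final epoch is retained. Training is deterministic given
#' `cfg$seed`.
#'
#' @param model An untrained (or warm) [build_model()] object.
#' @param train_set,validation_set Lists of sequence items
#'   `list(x = , y = )`; `validation_set` may be `NULL`.
#' @param cfg A [train_config()].
#' @param norm Optional `c(mean, sd)` standardization statistics to store
#'   with the model for later prediction on raw recordings.
#' @return The trained `bs_model` with `history` (per-epoch data frame)
#'   and `best_epoch` filled in.
#' @export
train_model <- function(model, train_set, validation_set = NULL,
                        cfg = train_config(), norm = NULL) {
  if (length(train_set) == 0L) stop("empty training set")
  spec <- model$spec
  if (!is.null(cfg$augmentation_sigma))
    train_set <- augment(train_set, cfg$augmentation_sigma,
                         cfg$augmentation_copies, seed = cfg$seed + 1L)
  st <- .stack_dataset(train_set, spec)
  if (length(unique(st$Y)) < 2L)
    warning("single-class training set; training proceeds but metrics may be degenerate")
  ci <- if (spec$kind == "crnn")
    .conv_indices(spec$n_bins, spec$cols, spec$conv1_filters) else NULL
  params <- model$params
  adam <- .adam_init(params)
  n_seq <- st$B; T <- spec$seq_len
  keep <- 1 - spec$dropout
  hist <- vector("list", cfg$epochs)
  best_acc <- -Inf; best_params <- params; best_epoch <- NA_integer_

  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_seq)
      ep_loss <- 0; n_batch <- 0L
      for (b0 in seq(1L, n_seq, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, n_seq)]
        rows <- as.vector(vapply(bi, function(b) (b - 1L) * T + seq_len(T),
                                 integer(T)))
        Xb <- st$X[rows, , drop = FALSE]
        Yb <- st$Y[rows]
        B <- length(bi)
        masks <- if (spec$dropout > 0) {
          dims <- if (spec$kind == "crnn")
            c(ci$np2 * spec$conv2_filters, 2L * spec$gru_units)
          else c(spec$context * spec$dense1, NA)
          m1 <- matrix((stats::runif(B * T * dims[1]) < keep) / keep, B * T)
          m2 <- if (!is.na(dims[2]))
            matrix((stats::runif(B * T * dims[2]) < keep) / keep, B * T)
          list(m1 = m1, m2 = m2)
        }
        tmp_model <- list(spec = spec, params = params)
        fw <- .forward_model(tmp_model, Xb, B, T, masks = masks, ci = ci)
        grads <- if (spec$kind == "crnn")
          .crnn_backward(params, fw, Yb, B, T, ci, spec, masks)
        else .cdnn_backward(params, fw, Yb, B, T, spec, masks)
        upd <- .adam_step(params, grads, adam, lr = cfg$lr, beta1 = cfg$beta1,
                          beta2 = cfg$beta2, eps = cfg$epsilon)
        params <- upd$params; adam <- upd$state
        ep_loss <- ep_loss + .bce_loss(fw$prob, Yb)
        n_batch <- n_batch + 1L
      }
      row <- data.frame(epoch = ep, loss = ep_loss / n_batch,
                        val_loss = NA_real_, val_accuracy = NA_real_,
                        val_precision = NA_real_, val_sensitivity = NA_real_,
                        val_specificity = NA_real_)
      if (!is.null(validation_set)) {
        tmp_model <- list(spec = spec, params = params)
        ev <- .eval_metrics(tmp_model, validation_set, cfg$threshold, ci = ci)
        row$val_loss <- ev$loss
        row$val_accuracy <- ev$metrics$accuracy
        row$val_precision <- ev$metrics$precision
        row$val_sensitivity <- ev$metrics$sensitivity
        row$val_specificity <- ev$metrics$specificity
        if (is.finite(row$val_accuracy) && row$val_accuracy > best_acc) {
          best_acc <- row$val_accuracy
          best_params <- params
          best_epoch <- ep
        }
      }
      hist[[ep]] <- row
      if (isTRUE(cfg$verbose))
        message(sprintf("epoch %3d  loss %.4f  val acc %s", ep, row$loss,
                        format(row$val_accuracy, digits = 4)))
    }
  })
  if (is.null(validation_set)) {
    best_params <- params
    best_epoch <- cfg$epochs
  }
  model$params <- best_params
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best_epoch
  if (!is.null(norm)) model$norm <- norm
  model
}

#' Predict frame probabilities for a fragment
#'
#' Runs the trained network (dropout disabled) on one frame tensor or a
#' list of them. Inputs must be standardized with the training-time
#' statistics.
#'
#' @param object A trained [build_model()] object.
#' @param frames A [frame_tensor()], a list of them, or a dataset item.
#' @param threshold Decision threshold on the sigmoid output.
#' @param ... Unused.
#' @return A [bs_predictions()] (or a list of them for list input).
#' @export
predict.bs_model <- function(object, frames, threshold = 0.5, ...) {
  if (is.list(frames) && !inherits(frames, "bs_frame_tensor") &&
      is.null(frames$x)) {
    return(lapply(frames, function(f)
      predict.bs_model(object, f, threshold = threshold)))
  }
  item <- if (inherits(frames, "bs_frame_tensor")) {
    if (!isTRUE(frames$standardized))
      stop("predict requires a standardized frame tensor")
    list(x = frames, y = rep(0L, dim(frames$blocks)[1]))
  } else list(x = frames$x, y = rep(0L, dim(frames$x)[1]))
  sv <- .stack_dataset(list(item), object$spec)
  fw <- .forward_model(object, sv$X, 1L, sv$T)
  off <- if (inherits(frames, "bs_frame_tensor")) frames$offset_s else 0
  fm <- if (inherits(frames, "bs_frame_tensor")) frames$frame_ms else 10
  bs_predictions(fw$prob, threshold = threshold, offset_s = off, frame_ms = fm)
}
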