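#' Frame-level confusion counts and metrics
#'
#' Tallies true/false positives/negatives between predicted and true frame
#' labels and derives the four headline percentages: accuracy, precision,
#' sensitivity (true-positive rate among sound frames) and specificity
#' (true-negative rate among noise frames). Ratios with a zero denominator
#' are reported as `NA` rather than 0, so degenerate folds cannot silently
#' corrupt summary tables.
#'
#' @param pred A [bs_predictions()] or a 0/1 vector of frame decisions.
#' @param truth A 0/1 vector of true frame labels of the same length.
#' @return An object of class `bs_eval`: list with counts `tp`, `fp`,
#'   `tn`, `fn` and percentages `accuracy`, `precision`, `sensitivity`,
#'   `specificity`.
#' @export
confusion <- function(pred, truth) {
  if (inherits(pred, "bs_predictions")) pred <- pred$decisions
  pred <- as.integer(pred > 0)
  truth <- as.integer(truth > 0)
  if (length(pred) != length(truth))
    stop("prediction and truth lengths differ (", length(pred), " vs ",
         length(truth), ")")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  tn <- sum(pred == 0L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = pct(tp + tn, tp + fp + tn + fn),
         precision = pct(tp, tp + fp),
         sensitivity = pct(tp, tp + fn),
         specificity = pct(tn, tn + fp)),
    class = "bs_eval"
  )
}

#' @export
print.bs_eval <- function(x, ...) {
  cat(sprintf(
    "<bs_eval: ACC %s%%  Prec %s%%  Sens %s%%  Spec %s%%  (tp %d fp %d tn %d fn %d)>\n",
    format(x$accuracy, digits = 4), format(x$precision, digits = 4),
    format(x$sensitivity, digits = 4), format(x$specificity, digits = 4),
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' k-fold cross-validation of a frame classifier
#'
#' Splits the dataset's sequences into `k` folds, trains on `k - 1` folds,
#' evaluates every epoch on the held-out fold and reports the best epoch's
#' metrics per fold (best by validation accuracy), plus their mean.
#'
#' @param dataset List of sequence items `list(x = , y = )` (one per 2-s
#'   fragment), e.g. from [build_dataset()].
#' @param spec A [model_spec()].
#' @param cfg A [train_config()].
#' @param k Number of folds.
#' @return List with `folds` (data frame: fold, best_epoch, counts and
#'   percentages) and `mean` (named numeric vector of the percentage
#'   columns averaged over folds).
#' @export
cross_validate <- function(dataset, spec = model_spec(), cfg = train_config(),
                           k = 5L) {
  n <- length(dataset)
  folds <- kfold_indices(n, k = k, seed = cfg$seed)
  rows <- lapply(seq_along(folds), function(f) {
    fold <- folds[[f]]
    model <- build_model(spec, seed = cfg$seed + f)
    model <- train_model(model, dataset[fold$train], dataset[fold$validation],
                         cfg = cfg)
    h <- model$history[model$best_epoch, ]
    ev <- .eval_metrics(model, dataset[fold$validation], cfg$threshold)
    data.frame(fold = f, best_epoch = model$best_epoch,
               tp = ev$metrics$tp, fp = ev$metrics$fp,
               tn = ev$metrics$tn, fn = ev$metrics$fn,
               accuracy = h$val_accuracy, precision = h$val_precision,
               sensitivity = h$val_sensitivity,
               specificity = h$val_specificity)
  })
  folds_df <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "precision", "sensitivity", "specificity")
  list(folds = folds_df,
       mean = colMeans(folds_df[, metric_cols], na.rm = TRUE))
}

#' Hyperparameter sweep mirroring the published ablation tables
#'
#' Re-runs cross-validation while varying exactly one axis, every other
#' parameter held at its base value:
#'
#' * `max_freq` — spectrogram crop frequency (Hz); the retained bin count
#'   (model input height) is derived from it.
#' * `fft` — window width L; the hop is recomputed as `floor(L / 4)` and
#'   the columns per frame as `max(1, floor(F / hop))`.
#' * `window` — `"hann"` vs `"hamming"`.
#' * `n_frames_context` — CDNN adjacent-frame context size.
#' * `sigma` — Gaussian augmentation noise level.
#'
#' @param axis One of `"max_freq"`, `"fft"`, `"window"`,
#'   `"n_frames_context"`, `"sigma"`.
#' @param values Values to sweep.
#' @param rec A [bs_recording()] supplying the audio.
#' @param ann Matching [bs_annotations()].
#' @param spec Base [model_spec()] (the CDNN is the usual sweep model).
#' @param cfg Base [train_config()].
#' @param params Base [stft_params()].
#' @param k Folds per value.
#' @return Data frame with one row per value: `value`, mean `accuracy`,
#'   `precision`, `sensitivity`, `specificity`, and `total_frames`
#'   (summed validation confusion counts, conserved across rows).
#' @export
sweep_axis <- function(axis = c("max_freq", "fft", "window",
                                "n_frames_context", "sigma"),
                       values, rec, ann, spec = model_spec("cdnn"),
                       cfg = train_config(), params = stft_params(),
                       k = 2L) {
  axis <- match.arg(axis)
  rows <- lapply(values, function(v) {
    p <- params; s <- spec; cf <- cfg
    if (axis == "max_freq") {
      p <- stft_params(window = p$window, size_L = p$size_L, hop = p$hop,
                       sample_rate = p$sample_rate, max_freq = as.numeric(v),
                       db_floor = p$db_floor)
    } else if (axis == "fft") {
      p <- stft_params(window = p$window, size_L = as.integer(v), hop = NULL,
                       sample_rate = p$sample_rate, max_freq = p$max_freq,
                       db_floor = p$db_floor)
    } else if (axis == "window") {
      p <- stft_params(window = as.character(v), size_L = p$size_L,
                       hop = p$hop, sample_rate = p$sample_rate,
                       max_freq = p$max_freq, db_floor = p$db_floor)
    } else if (axis == "n_frames_context") {
      s$context <- as.integer(v)
    } else if (axis == "sigma") {
      cf$augmentation_sigma <- if (as.numeric(v) > 0) as.numeric(v) else NULL
    }
    frame_ms <- 10
    Fsamp <- frame_ms * p$sample_rate / 1000
    cols <- max(1L, as.integer(floor(Fsamp / p$hop)))
    ds <- build_dataset(rec, ann, params = p, frame_ms = frame_ms,
                        cols_per_frame = cols)
    s$n_bins <- ds$n_bins
    s$cols <- cols
    cv <- cross_validate(ds$items, spec = s, cfg = cf, k = k)
    data.frame(value = as.character(v),
               accuracy = cv$mean[["accuracy"]],
               precision = cv$mean[["precision"]],
               sensitivity = cv$mean[["sensitivity"]],
               specificity = cv$mean[["specificity"]],
               total_frames = sum(cv$folds$tp + cv$folds$fp + cv$folds$tn +
                                    cv$folds$fn))
  })
  do.call(rbind, rows)
}
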