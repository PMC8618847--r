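#' Bowel-sound interval annotations
#'
#' Ground-truth sound intervals in seconds relative to the recording start.
#' Intervals are validated, sorted by start, and overlapping (or touching)
#' intervals are merged on construction.
#'
#' @param start,end Numeric vectors of interval bounds in seconds, with
#'   `start < end` elementwise.
#' @return An object of class `bs_annotations`: a data frame with columns
#'   `start` and `end`.
#' @export
bs_annotations <- function(start = numeric(), end = numeric()) {
  stopifnot(length(start) == length(end))
  bad <- which(!(end > start))
  if (length(bad) > 0L)
    stop("invalid annotation at row ", bad[1L], ": end (", end[bad[1L]],
         ") must exceed start (", start[bad[1L]], ")")
  o <- order(start, end)
  start <- as.numeric(start[o]); end <- as.numeric(end[o])
  # merge overlapping or touching intervals
  if (length(start) > 1L) {
    ms <- start[1L]; me <- end[1L]
    outs <- numeric(); oute <- numeric()
    for (i in 2L:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        outs <- c(outs, ms); oute <- c(oute, me)
        ms <- start[i]; me <- end[i]
      }
    }
    start <- c(outs, ms); end <- c(oute, me)
  }
  structure(data.frame(start = start, end = end),
            class = c("bs_annotations", "data.frame"))
}

#' Read interval annotations from CSV
#'
#' Expects a header with columns `start` and `end` (seconds); extra columns
#' are ignored. Rows with `end <= start` raise an error naming the row.
#'
#' @param path CSV path.
#' @return A [bs_annotations()] object (sorted, overlap-merged).
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("start", "end") %in% names(df)))
    stop("annotation CSV must have 'start' and 'end' columns: ", path)
  bs_annotations(df$start, df$end)
}

#' Write interval annotations to CSV
#' @param ann A [bs_annotations()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann)[, c("start", "end")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Binary frame labels from interval annotations
#'
#' Frame `m` (0-based) covers `[m D, (m+1) D)` with `D = frame_ms / 1000`.
#' It is labeled positive iff either (a) the total annotated-sound time
#' inside the frame is strictly greater than `D / 2`, or (b) some single
#' annotated sound has strictly more than half of its own duration inside
#' the frame. Condition (b) matters for sounds much shorter than a frame.
#'
#' @param ann A [bs_annotations()] object.
#' @param n_frames Number of frames to label.
#' @param frame_ms Frame width in milliseconds.
#' @return Integer vector of 0/1 labels of length `n_frames`.
#' @export
label_frames <- function(ann, n_frames, frame_ms = 10) {
  stopifnot(n_frames >= 0)
  n_frames <- as.integer(n_frames)
  D <- frame_ms / 1000
  labels <- integer(n_frames)
  if (n_frames == 0L || nrow(ann) == 0L) return(labels)
  # strict ">" comparisons carry a 1-ns guard so that an overlap of exactly
  # half a frame (or half a sound), up to floating-point rounding, stays
  # negative as the rule requires
  tol <- 1e-9
  cover <- numeric(n_frames)
  for (i in seq_len(nrow(ann))) {
    s <- ann$start[i]; e <- ann$end[i]
    dur <- e - s
    m_lo <- max(0L, as.integer(floor(s / D)))
    m_hi <- min(n_frames - 1L, as.integer(ceiling(e / D)))
    if (m_lo > m_hi) next
    for (m in m_lo:m_hi) {
      ov <- min(e, (m + 1) * D) - max(s, m * D)
      if (ov <= 0) next
      cover[m + 1L] <- cover[m + 1L] + ov
      if (ov > dur / 2 + tol) labels[m + 1L] <- 1L # condition (b)
    }
  }
  labels[cover > D / 2 + tol] <- 1L # condition (a)
  labels
}

# Evaluate an expression under a temporary RNG state; restores the caller's
# .Random.seed so package functions never perturb user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random train/test split by fragment
#'
#' Splits whole fragments (model input sequences), never individual frames,
#' so near-identical adjacent frames cannot leak between train and test.
#'
#' @param items List of fragment-level items (any type).
#' @param test_frac Fraction of fragments assigned to the test set.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with `train`, `test` (sublists of `items`) and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(items, test_frac = 0.15, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1)
  n <- length(items)
  if (n < 2L) stop("need at least 2 fragments to split")
  n_test <- max(1L, as.integer(round(test_frac * n)))
  test_idx <- sort(with_seed(seed, sample.int(n, n_test)))
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = items[train_idx], test = items[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

#' k-fold cross-validation indices over fragments
#'
#' @param n_fragments Number of fragments.
#' @param k Number of folds (validation folds partition the fragments;
#'   fold sizes differ by at most 1).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(train = , validation = )`.
#' @export
kfold_indices <- function(n_fragments, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (n_fragments < k) stop("need at least k fragments")
  perm <- with_seed(seed, sample.int(n_fragments))
  # assign shuffled fragments round-robin so fold sizes differ by <= 1
  fold_of <- integer(n_fragments)
  fold_of[perm] <- rep(seq_len(k), length.out = n_fragments)
  lapply(seq_len(k), function(f) {
    val <- which(fold_of == f)
    list(train = setdiff(seq_len(n_fragments), val), validation = val)
  })
}
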