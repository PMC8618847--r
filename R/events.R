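#' Merge per-frame decisions into discrete sound events
#'
#' Maximal runs of consecutive positive frames become one event: adjacent
#' positive frames are treated as the same longer sound. No minimum
#' duration is enforced and, by default, no gap bridging is applied; an
#' optional `bridge_frames` closes gaps of up to that many negative frames
#' between runs (default 0 = off).
#'
#' @param pred A `bs_predictions` object (see [baseline_classify()] /
#'   [predict.bs_model()]) or a logical/0-1 vector of frame decisions.
#' @param frame_ms Frame width in milliseconds.
#' @param offset_s Time of frame 0 relative to the recording start.
#' @param bridge_frames Merge runs separated by at most this many negative
#'   frames (0 disables; the gap frames are absorbed into the event).
#' @return A data frame of class `bs_events` with columns `start`, `end`,
#'   `n_frames`, `mean_probability` (rows sorted, disjoint).
#' @export
merge_frames <- function(pred, frame_ms = 10, offset_s = 0, bridge_frames = 0L) {
  if (inherits(pred, "bs_predictions")) {
    dec <- pred$decisions
    prob <- pred$probabilities
  } else {
    dec <- as.integer(pred)
    prob <- rep(NA_real_, length(dec))
  }
  D <- frame_ms / 1000
  r <- rle(dec > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values)
  if (length(pos) == 0L) return(.empty_events())
  s_idx <- starts[pos]; e_idx <- ends[pos]
  if (bridge_frames > 0L && length(pos) > 1L) {
    keep_s <- s_idx[1L]; out_s <- integer(); out_e <- integer()
    cur_e <- e_idx[1L]
    for (i in 2L:length(pos)) {
      if (s_idx[i] - cur_e - 1L <= bridge_frames) {
        cur_e <- e_idx[i]
      } else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
        keep_s <- s_idx[i]; cur_e <- e_idx[i]
      }
    }
    s_idx <- c(out_s, keep_s); e_idx <- c(out_e, cur_e)
  }
  ev <- data.frame(
    start = offset_s + (s_idx - 1L) * D,
    end = offset_s + e_idx * D,
    n_frames = e_idx - s_idx + 1L,
    mean_probability = vapply(seq_along(s_idx), function(i)
      mean(prob[s_idx[i]:e_idx[i]]), numeric(1))
  )
  structure(ev, class = c("bs_events", "data.frame"))
}

.empty_events <- function() {
  structure(data.frame(start = numeric(), end = numeric(),
                       n_frames = integer(), mean_probability = numeric()),
            class = c("bs_events", "data.frame"))
}

#' Rasterize events back to binary frame decisions
#'
#' Exact inverse of [merge_frames()] on its image; used for round-trip
#' checks and for re-scoring detections at frame level.
#'
#' @param events A `bs_events` data frame (times relative to frame 0).
#' @param n_frames Number of frames in the target vector.
#' @param frame_ms Frame width in milliseconds.
#' @return Integer 0/1 vector of length `n_frames`.
#' @export
events_to_frames <- function(events, n_frames, frame_ms = 10) {
  D <- frame_ms / 1000
  dec <- integer(n_frames)
  if (nrow(events) == 0L) return(dec)
  tol <- 1e-9
  if (any(events$start < -tol) || any(events$end > n_frames * D + tol))
    stop("event outside [0, n_frames * frame width]")
  for (i in seq_len(nrow(events))) {
    a <- as.integer(round(events$start[i] / D)) + 1L
    b <- as.integer(round(events$end[i] / D))
    dec[a:b] <- 1L
  }
  dec
}

#' Merge touching events across fragment boundaries
#'
#' Fragments are classified independently, so a sound spanning a boundary
#' appears as two touching events. This optional post-pass joins events
#' whose gap is below `tol_s`.
#'
#' @param events A `bs_events` data frame over absolute recording time.
#' @param tol_s Maximum gap (seconds) considered "touching".
#' @return A `bs_events` data frame.
#' @export
merge_touching_events <- function(events, tol_s = 1e-9) {
  if (nrow(events) <= 1L) return(events)
  events <- events[order(events$start), ]
  out <- events[1L, ]
  for (i in 2L:nrow(events)) {
    j <- nrow(out)
    if (events$start[i] - out$end[j] <= tol_s) {
      w1 <- out$n_frames[j]; w2 <- events$n_frames[i]
      out$mean_probability[j] <-
        (out$mean_probability[j] * w1 + events$mean_probability[i] * w2) / (w1 + w2)
      out$end[j] <- max(out$end[j], events$end[i])
      out$n_frames[j] <- w1 + w2
    } else {
      out <- rbind(out, events[i, ])
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("bs_events", "data.frame"))
}

#' Write detected events to CSV
#' @param events A `bs_events` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read detected events from CSV
#' @param path CSV with columns `start,end,n_frames,mean_probability`.
#' @return A `bs_events` data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  need <- c("start", "end")
  if (!all(need %in% names(df))) stop("events CSV must have start,end columns")
  if (is.null(df$n_frames)) df$n_frames <- NA_integer_
  if (is.null(df$mean_probability)) df$mean_probability <- NA_real_
  structure(df[order(df$start), c("start", "end", "n_frames", "mean_probability")],
            class = c("bs_events", "data.frame"))
}
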