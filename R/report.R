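#' Inter-event intervals
#'
#' Onset-to-onset intervals between successive detected sounds, the
#' convention of the heart-rate-variability statistics (RMSSD, Porta,
#' Guzik) applied here to bowel sounds.
#'
#' @param events A `bs_events` data frame (sorted by start).
#' @return Numeric vector of `n_events - 1` intervals in seconds (empty
#'   for fewer than 2 events).
#' @export
event_intervals <- function(events) {
  if (nrow(events) < 2L) return(numeric())
  diff(events$start)
}

#' Root mean square of successive interval differences (RMSSD)
#'
#' `sqrt(mean((I[i+1] - I[i])^2))` over successive inter-event intervals;
#' a short-term variability measure.
#'
#' @param intervals Numeric vector of inter-event intervals (seconds).
#' @return RMSSD in seconds, or `NA` when fewer than 2 intervals exist.
#' @export
rmssd <- function(intervals) {
  if (length(intervals) < 2L) return(NA_real_)
  sqrt(mean(diff(intervals)^2))
}

#' Porta's asymmetry index
#'
#' With `d[i] = I[i+1] - I[i]`, the percentage of negative differences
#' among the nonzero ones: `100 * #{d < 0} / #{d != 0}`. A symmetric
#' interval series gives 50%.
#'
#' @param intervals Numeric vector of inter-event intervals (seconds).
#' @return Percent in `[0, 100]`, or `NA` when undefined (fewer than 2
#'   intervals, or all differences zero).
#' @export
porta_index <- function(intervals) {
  if (length(intervals) < 2L) return(NA_real_)
  d <- diff(intervals)
  nz <- d[d != 0]
  if (length(nz) == 0L) return(NA_real_)
  100 * sum(nz < 0) / length(nz)
}

#' Guzik's asymmetry index
#'
#' The share of squared Poincare-plot distance from the identity line
#' contributed by positive interval differences:
#' `100 * sum(d[d > 0]^2) / sum(d[d != 0]^2)` (the constant `1/sqrt(2)`
#' distance factor cancels). A symmetric series gives 50%.
#'
#' @inheritParams porta_index
#' @return Percent in `[0, 100]`, or `NA` when undefined.
#' @export
guzik_index <- function(intervals) {
  if (length(intervals) < 2L) return(NA_real_)
  d <- diff(intervals)
  nz <- d[d != 0]
  if (length(nz) == 0L) return(NA_real_)
  100 * sum(nz[nz > 0]^2) / sum(nz^2)
}

#' Clinical statistics report for a recording's detected events
#'
#' Quantifies gastrointestinal acoustic activity: event counts overall and
#' per minute, per-3-minute summary statistics (mean, median, quartiles of
#' the per-minute counts), the event-duration histogram in 10-ms bins with
#' percentages, and interval statistics (RMSSD, standard deviation, Porta
#' and Guzik indices).
#'
#' Per-minute counts cover only complete minutes (a trailing partial
#' minute is excluded from the series but its events still count in the
#' totals), and the overall `events_per_min` rate is likewise normalized
#' by the complete minutes when the recording has at least one, so that a
#' sound-free trailing remainder cannot dilute the rate. Duration
#' histogram bin `b` counts events with duration in
#' `((b-1) * bin_ms, b * bin_ms]` milliseconds.
#'
#' @param events A `bs_events` data frame within `[0, recording_length_s]`.
#' @param recording_length_s Recording length in seconds (positive).
#' @param bin_ms Duration histogram bin width in milliseconds.
#' @param window_min Window length for the windowed per-minute statistics,
#'   in minutes.
#' @return An object of class `bs_stats_report` (a named list; see fields
#'   in the details). Undefined statistics are `NA`.
#' @export
compute_report <- function(events, recording_length_s, bin_ms = 10,
                           window_min = 3) {
  if (recording_length_s <= 0) stop("recording length must be positive")
  if (nrow(events) > 0 &&
      (min(events$start) < -1e-9 || max(events$end) > recording_length_s + 1e-9))
    stop("events outside [0, recording length]")
  n_events <- nrow(events)
  n_min <- floor(recording_length_s / 60)

  per_minute <- if (n_min > 0) {
    vapply(seq_len(n_min) - 1L, function(m)
      sum(events$start >= m * 60 & events$start < (m + 1) * 60), numeric(1))
  } else numeric(0)

  n_win <- if (n_min > 0) floor(n_min / window_min) else 0
  three_min <- if (n_win > 0) {
    do.call(rbind, lapply(seq_len(n_win), function(w) {
      counts <- per_minute[((w - 1) * window_min + 1):(w * window_min)]
      q <- stats::quantile(counts, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(window = w, mean = mean(counts), q1 = q[1], median = q[2],
                 q3 = q[3])
    }))
  } else data.frame(window = integer(), mean = numeric(), q1 = numeric(),
                    median = numeric(), q3 = numeric())

  if (n_events > 0) {
    dur_ms <- (events$end - events$start) * 1000
    bin <- pmax(1L, as.integer(ceiling(dur_ms / bin_ms - 1e-9)))
    counts <- tabulate(bin, nbins = max(bin))
    hist_df <- data.frame(duration_ms = seq_along(counts) * bin_ms,
                          count = counts,
                          percent = 100 * counts / n_events)
  } else {
    hist_df <- data.frame(duration_ms = numeric(), count = integer(),
                          percent = numeric())
  }

  iv <- event_intervals(events)
  structure(
    list(recording_length_s = recording_length_s,
         n_events = n_events,
         events_per_min = if (n_min > 0) n_events / n_min
                          else n_events / (recording_length_s / 60),
         per_minute_counts = per_minute,
         three_min_stats = three_min,
         duration_histogram = hist_df,
         rmssd_s = rmssd(iv),
         sd_intervals_s = if (length(iv) >= 2) stats::sd(iv) else NA_real_,
         porta_index_pct = porta_index(iv),
         guzik_index_pct = guzik_index(iv)),
    class = "bs_stats_report"
  )
}

#' @export
print.bs_stats_report <- function(x, ...) {
  cat("Bowel sound activity report\n")
  cat(sprintf("  recording length  : %.1f s\n", x$recording_length_s))
  cat(sprintf("  sounds detected   : %d (%.2f per minute)\n",
              x$n_events, x$events_per_min))
  if (length(x$per_minute_counts) > 0)
    cat("  per-minute counts :", paste(x$per_minute_counts, collapse = " "), "\n")
  if (nrow(x$duration_histogram) > 0) {
    nz <- x$duration_histogram[x$duration_histogram$count > 0, ]
    cat("  duration histogram:",
        paste(sprintf("%g ms: %d (%.1f%%)", nz$duration_ms, nz$count, nz$percent),
              collapse = ", "), "\n")
  }
  cat(sprintf("  RMSSD             : %s s\n", format(x$rmssd_s, digits = 4)))
  cat(sprintf("  SD of intervals   : %s s\n", format(x$sd_intervals_s, digits = 4)))
  cat(sprintf("  Porta's index     : %s %%\n", format(x$porta_index_pct, digits = 4)))
  cat(sprintf("  Guzik's index     : %s %%\n", format(x$guzik_index_pct, digits = 4)))
  invisible(x)
}

#' Serialize a statistics report to JSON
#' @param report A `bs_stats_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
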