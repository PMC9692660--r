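#' Filter gaze records by per-eye validity codes
#'
#' Retains exactly those acquisitions whose validity-code pair is (0,0) —
#' both eyes found with certainty — or (4,4) — both eyes lost, the signature
#' that opens a blink. Records with any code in 1-3 (uncertain / single-eye
#' assumptions) or with mismatched pairs are removed; order is preserved.
#'
#' @param records time-ordered gaze record `data.table`.
#' @return the retained subset, same columns and order.
#' @export
filter_validity <- function(records) {
  v <- cbind(records$validity_left, records$validity_right)
  bad <- which(!(v %in% 0:4) | !is.finite(v))
  if (length(bad) > 0L) {
    idx <- ((bad[1] - 1L) %% nrow(records)) + 1L
    stop("validity code outside 0-4 at record index ", idx)
  }
  keep <- (records$validity_left == 0L & records$validity_right == 0L) |
    (records$validity_left == 4L & records$validity_right == 4L)
  records[keep]
}

#' Segment blinks from a validity-filtered record sequence
#'
#' A maximal run of consecutive both-eyes validity-4 records followed by at
#' least one both-eyes validity-0 record is one blink. Runs of length >= 2
#' get `duration_ms = run_length * 1000 / sampling_rate_hz`; single-sample
#' runs are "fast" blinks whose duration cannot be computed (`duration_ms`
#' is `NA`, `is_fast` is `TRUE`) and are tallied separately. A trailing
#' validity-4 run at end of session yields no event (the return to validity
#' is never observed).
#'
#' @param records validity-filtered records (only (0,0)/(4,4) pairs).
#' @param sampling_rate_hz sampling frequency used to convert run lengths to
#'   durations.
#' @return list with `blinks` (`data.table`: `start_ms`, `end_ms`,
#'   `duration_ms`, `is_fast`) and `n_fast_blinks`.
#' @export
detect_blinks <- function(records, sampling_rate_hz) {
  if (sampling_rate_hz <= 0) stop_config("sampling_rate_hz", "must be > 0")
  if (any(records$validity_left %in% 1:3 | records$validity_right %in% 1:3)) {
    stop("detect_blinks expects validity-filtered input; codes 1-3 present")
  }
  empty <- data.table::data.table(
    start_ms = numeric(), end_ms = numeric(),
    duration_ms = numeric(), is_fast = logical()
  )
  if (nrow(records) == 0L) return(list(blinks = empty, n_fast_blinks = 0L))
  is4 <- records$validity_left == 4L & records$validity_right == 4L
  r <- rle(is4)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # runs of TRUE not at the end of the sequence are followed by a (0,0) run
  sel <- which(r$values & ends < length(is4))
  if (length(sel) == 0L) return(list(blinks = empty, n_fast_blinks = 0L))
  len <- r$lengths[sel]
  blinks <- data.table::data.table(
    start_ms = records$timestamp_ms[starts[sel]],
    end_ms = records$timestamp_ms[ends[sel]],
    duration_ms = ifelse(len >= 2L, len * 1000 / sampling_rate_hz, NA_real_),
    is_fast = len == 1L
  )
  list(blinks = blinks, n_fast_blinks = sum(blinks$is_fast))
}

span_dispersion <- function(x, y) {
  (max(x) - min(x)) + (max(y) - min(y))
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Operates on the both-eyes-found (0,0) records only, within each stretch
#' uninterrupted by a blink (a (4,4) run): windows never span an eyelid
#' closure, so fixations cannot overlap blinks in time. A window of
#' consecutive valid gaze points is grown while its dispersion
#' `(max(x)-min(x)) + (max(y)-min(y))` stays within `dispersion_threshold_px`;
#' a window spanning at least `min_duration_ms` is emitted as a fixation with
#' centroid at the mean gaze point, and the scan resumes after it. Windows
#' are therefore non-overlapping and time-ordered.
#'
#' @param records validity-filtered records.
#' @param sampling_rate_hz sampling frequency (documentation of provenance;
#'   durations are computed from timestamps).
#' @param dispersion_threshold_px maximum within-window dispersion, pixels.
#' @param min_duration_ms minimum fixation time span, milliseconds.
#' @return `data.table` with `start_ms`, `end_ms`, `duration_ms`,
#'   `centroid_x`, `centroid_y`.
#' @export
detect_fixations <- function(records, sampling_rate_hz = 50,
                             dispersion_threshold_px = 100,
                             min_duration_ms = 100) {
  if (dispersion_threshold_px <= 0) {
    stop_config("dispersion_threshold_px", "must be > 0")
  }
  if (min_duration_ms <= 0) stop_config("min_duration_ms", "must be > 0")
  is44 <- records$validity_left == 4L & records$validity_right == 4L
  ok <- records$validity_left == 0L & records$validity_right == 0L &
    is.finite(records$gaze_x) & is.finite(records$gaze_y)
  segment <- cumsum(is44)      # advances at every blink sample
  out <- list()
  for (seg in unique(segment[ok])) {
    pick <- ok & segment == seg
    t <- records$timestamp_ms[pick]
    x <- records$gaze_x[pick]
    y <- records$gaze_y[pick]
    n <- length(t)
    i <- 1L
    while (i <= n) {
      # smallest window starting at i that spans the minimum duration
      j <- i
      while (j <= n && t[j] - t[i] < min_duration_ms) j <- j + 1L
      if (j > n) break
      if (span_dispersion(x[i:j], y[i:j]) <= dispersion_threshold_px) {
        while (j < n &&
                 span_dispersion(x[i:(j + 1L)], y[i:(j + 1L)]) <=
                   dispersion_threshold_px) {
          j <- j + 1L
        }
        out[[length(out) + 1L]] <- c(
          start_ms = t[i], end_ms = t[j], duration_ms = t[j] - t[i],
          centroid_x = mean(x[i:j]), centroid_y = mean(y[i:j])
        )
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(
      start_ms = numeric(), end_ms = numeric(), duration_ms = numeric(),
      centroid_x = numeric(), centroid_y = numeric()
    ))
  }
  data.table::rbindlist(lapply(out, as.list))
}

#' Extract ocular events from one raw session
#'
#' Convenience wrapper: validity filtering, blink segmentation and I-DT
#' fixation detection in one call.
#'
#' @param records raw gaze records of a single session.
#' @param sampling_rate_hz sampling frequency.
#' @param dispersion_threshold_px,min_duration_ms I-DT parameters.
#' @return list of class `ocular_events`: `blinks`, `n_fast_blinks`,
#'   `fixations`, `retained_records`.
#' @export
extract_ocular_events <- function(records, sampling_rate_hz = 50,
                                  dispersion_threshold_px = 100,
                                  min_duration_ms = 100) {
  kept <- filter_validity(records)
  bl <- detect_blinks(kept, sampling_rate_hz)
  fx <- detect_fixations(kept, sampling_rate_hz,
                         dispersion_threshold_px, min_duration_ms)
  structure(
    list(blinks = bl$blinks, n_fast_blinks = bl$n_fast_blinks,
         fixations = fx, retained_records = kept),
    class = "ocular_events"
  )
}
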