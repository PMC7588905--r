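#' Per-minute summaries of delta records
#'
#' The per-minute evaluating data: a simple moving average of window 60 s.
#' The default (`align = "minute"`) is the tumbling form — records are
#' partitioned into non-overlapping `[t, t + 60)` windows aligned to the
#' wall-clock minute grid, one value per minute, matching clock-time chart
#' axes. `align = "sliding"` instead emits, for every record timestamp
#' `t`, the mean over `(t - 60, t]`.
#'
#' Minutes (or windows) containing no records are omitted, not zero-filled:
#' an absent person stores no frames, and a zero would conflate "still"
#' with "not there".
#'
#' @param records Delta records from [compute_deltas()], ordered by
#'   timestamp.
#' @param align `"minute"` (default) or `"sliding"`.
#' @return A tibble with columns `minute_start`, `mean_d_height`,
#'   `mean_d_width`, `mean_d_distance`, `n_records`. For the sliding
#'   variant `minute_start` is the window *end* timestamp.
#' @export
summarize_minutes <- function(records, align = c("minute", "sliding")) {
  align <- match.arg(align)
  if (nrow(records) == 0) {
    return(empty_minutes())
  }
  if (align == "minute") {
    minute_start <- floor(records$timestamp / 60) * 60
    grp <- new_tbl(
      minute_start = minute_start,
      d_height = records$d_height,
      d_width = records$d_width,
      d_distance = records$d_distance
    )
    out <- dplyr::summarise(
      dplyr::group_by(grp, .data$minute_start),
      mean_d_height = mean(.data$d_height),
      mean_d_width = mean(.data$d_width),
      mean_d_distance = mean(.data$d_distance),
      n_records = dplyr::n(),
      .groups = "drop"
    )
    return(dplyr::arrange(out, .data$minute_start))
  }
  # sliding: two-pointer window (t - 60, t] over the sorted records
  ts <- records$timestamp
  n <- length(ts)
  lo <- 1L
  means <- matrix(0, n, 3)
  counts <- integer(n)
  csum_h <- cumsum(records$d_height)
  csum_w <- cumsum(records$d_width)
  csum_d <- cumsum(records$d_distance)
  for (i in seq_len(n)) {
    while (ts[lo] <= ts[i] - 60) lo <- lo + 1L
    k <- i - lo + 1L
    base_h <- if (lo > 1) csum_h[lo - 1] else 0
    base_w <- if (lo > 1) csum_w[lo - 1] else 0
    base_d <- if (lo > 1) csum_d[lo - 1] else 0
    means[i, ] <- c(csum_h[i] - base_h, csum_w[i] - base_w, csum_d[i] - base_d) / k
    counts[i] <- k
  }
  new_tbl(
    minute_start = ts,
    mean_d_height = means[, 1],
    mean_d_width = means[, 2],
    mean_d_distance = means[, 3],
    n_records = counts
  )
}

empty_minutes <- function() {
  new_tbl(
    minute_start = double(), mean_d_height = double(),
    mean_d_width = double(), mean_d_distance = double(),
    n_records = integer()
  )
}

# Civil day of an epoch-second timestamp (timestamps carry local clock time).
civil_day <- function(timestamp) {
  as.Date(floor(timestamp / 86400), origin = "1970-01-01")
}

#' Per-day cumulative summaries
#'
#' For each calendar day with at least one valid frame: the per-channel
#' sums of all per-second deltas that day, the count of valid frames, and
#' the active hours — valid frames divided by 3600, the total time of
#' observed postural activity.
#'
#' @param stream The [pose_stream()] the records came from.
#' @param records Delta records from [compute_deltas()] under the same
#'   policy.
#' @param policy The [filter_policy()] used for both.
#' @return A tibble with columns `date`, `total_d_height`, `total_d_width`,
#'   `total_d_distance`, `active_hours`, `n_frames`. Days with no valid
#'   frames are absent.
#' @export
summarize_days <- function(stream, records, policy = filter_policy()) {
  valid_ts <- stream$timestamp[frame_passes(stream, policy)]
  if (length(valid_ts) == 0) {
    return(empty_days())
  }
  fr <- new_tbl(date = civil_day(valid_ts))
  frames_by_day <- dplyr::summarise(
    dplyr::group_by(fr, .data$date),
    n_frames = dplyr::n(), .groups = "drop"
  )
  if (nrow(records) > 0) {
    rec <- new_tbl(
      date = civil_day(records$timestamp),
      d_height = records$d_height,
      d_width = records$d_width,
      d_distance = records$d_distance
    )
    deltas_by_day <- dplyr::summarise(
      dplyr::group_by(rec, .data$date),
      total_d_height = sum(.data$d_height),
      total_d_width = sum(.data$d_width),
      total_d_distance = sum(.data$d_distance),
      .groups = "drop"
    )
  } else {
    deltas_by_day <- tibble::tibble(
      date = as.Date(character()), total_d_height = double(),
      total_d_width = double(), total_d_distance = double()
    )
  }
  out <- dplyr::left_join(frames_by_day, deltas_by_day, by = "date")
  out <- dplyr::mutate(
    out,
    total_d_height = ifelse(is.na(.data$total_d_height), 0, .data$total_d_height),
    total_d_width = ifelse(is.na(.data$total_d_width), 0, .data$total_d_width),
    total_d_distance = ifelse(is.na(.data$total_d_distance), 0, .data$total_d_distance),
    active_hours = .data$n_frames / 3600
  )
  dplyr::arrange(
    out[c(
      "date", "total_d_height", "total_d_width", "total_d_distance",
      "active_hours", "n_frames"
    )],
    .data$date
  )
}

empty_days <- function() {
  tibble::tibble(
    date = as.Date(character()), total_d_height = double(),
    total_d_width = double(), total_d_distance = double(),
    active_hours = double(), n_frames = integer()
  )
}

#' Presence intervals
#'
#' Segments the valid frames of a stream into maximal runs separated by
#' gaps longer than `min_gap` seconds. The intervals underlie waking-time,
#' break and sleep inference: a long gap means the person was absent (or
#' unobservable), a run means continuous presence.
#'
#' @param stream A [pose_stream()].
#' @param policy A [filter_policy()].
#' @param min_gap Gap length in seconds beyond which a run is split
#'   (default 300, i.e. five minutes).
#' @return A tibble with columns `start`, `end` (timestamps of the first
#'   and last frame of each run), `n_frames`, `duration` (`end - start`
#'   seconds).
#' @export
presence_intervals <- function(stream, policy = filter_policy(),
                               min_gap = 300) {
  ts <- stream$timestamp[frame_passes(stream, policy)]
  if (length(ts) == 0) {
    return(new_tbl(
      start = double(), end = double(), n_frames = integer(),
      duration = double()
    ))
  }
  brk <- which(diff(ts) > min_gap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(ts))
  new_tbl(
    start = ts[starts],
    end = ts[ends],
    n_frames = ends - starts + 1L,
    duration = ts[ends] - ts[starts]
  )
}

#' Write minute summaries to CSV
#'
#' @param minutes Output of [summarize_minutes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_minutes_csv <- function(minutes, path) {
  utils::write.csv(minutes, path, row.names = FALSE)
  invisible(path)
}

#' Write daily summaries to CSV
#'
#' @param days Output of [summarize_days()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_days_csv <- function(days, path) {
  utils::write.csv(days, path, row.names = FALSE)
  invisible(path)
}
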