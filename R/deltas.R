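#' Frame filtering policy
#'
#' Controls which frames take part in delta computation and in the daily
#' active-hours count.
#'
#' @param score_threshold Overall-pose confidence cutoff in `[0, 1]`; frames
#'   scoring below it are dropped. Default 0.5, the conventional
#'   pose-estimation threshold.
#' @param multi_person `"keep"` retains frames with more than one detected
#'   person (their deltas then reflect care-visit variation); `"exclude"`
#'   drops them, so only the unattended subject is recorded.
#' @param max_gap Maximum timestamp gap in seconds across which a delta is
#'   still computed (default 2). Larger gaps — absence, lights off — emit
#'   nothing rather than fabricating motion across the gap.
#' @param min_kp_score Per-keypoint confidence cutoff used when deriving the
#'   box; default 0 (all reported keypoints are included).
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(score_threshold = 0.5,
                          multi_person = c("keep", "exclude"),
                          max_gap = 2,
                          min_kp_score = 0) {
  multi_person <- match.arg(multi_person)
  if (score_threshold < 0 || score_threshold > 1) {
    stop("score_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (max_gap < 1) stop("max_gap must be >= 1 second", call. = FALSE)
  if (min_kp_score < 0 || min_kp_score > 1) {
    stop("min_kp_score must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      score_threshold = score_threshold, multi_person = multi_person,
      max_gap = max_gap, min_kp_score = min_kp_score
    ),
    class = "filter_policy"
  )
}

#' Which frames pass a filter policy?
#'
#' A frame is valid when its overall score reaches the threshold, the
#' multi-person rule admits it, and at least one keypoint passes
#' `min_kp_score` (so a box can be formed).
#'
#' @param stream A [pose_stream()].
#' @param policy A [filter_policy()].
#' @return Logical vector, one element per frame.
#' @export
frame_passes <- function(stream, policy = filter_policy()) {
  ok <- stream$score >= policy$score_threshold & stream$persons >= 1
  if (policy$multi_person == "exclude") {
    ok <- ok & stream$persons <= 1
  }
  if (policy$min_kp_score > 0) {
    has_kp <- vapply(
      stream$keypoints,
      function(kp) nrow(kp) > 0 && any(kp$score >= policy$min_kp_score),
      logical(1)
    )
    ok <- ok & has_kp
  }
  ok
}

stream_boxes <- function(stream, min_kp_score = 0) {
  n <- nrow(stream)
  m <- matrix(NA_real_, nrow = n, ncol = 4)
  colnames(m) <- c("x_min", "x_max", "y_min", "y_max")
  for (i in seq_len(n)) {
    kp <- stream$keypoints[[i]]
    keep <- kp$score >= min_kp_score
    x <- kp$x[keep]
    y <- kp$y[keep]
    m[i, ] <- c(min(x), max(x), min(y), max(y))
  }
  m
}

#' Per-second postural-change records from a pose stream
#'
#' Applies the filter policy, then emits one delta record for every pair of
#' surviving consecutive frames whose timestamp gap does not exceed
#' `policy$max_gap`. Each record carries the three change metrics of
#' [delta_metrics()] and is stamped with the later frame's timestamp.
#'
#' @param stream A [pose_stream()] ordered by timestamp.
#' @param policy A [filter_policy()].
#' @return A tibble with columns `timestamp`, `d_height`, `d_width`,
#'   `d_distance`, `gap`; zero rows when fewer than two frames survive.
#' @export
compute_deltas <- function(stream, policy = filter_policy()) {
  keep <- frame_passes(stream, policy)
  sub <- stream[keep, , drop = FALSE]
  n <- nrow(sub)
  if (n < 2) {
    return(empty_deltas())
  }
  b <- stream_boxes(sub, policy$min_kp_score)
  w <- b[, "x_max"] - b[, "x_min"]
  h <- b[, "y_max"] - b[, "y_min"]
  cx <- (b[, "x_min"] + b[, "x_max"]) / 2
  cy <- (b[, "y_min"] + b[, "y_max"]) / 2
  ts <- sub$timestamp
  gap <- diff(ts)
  ok <- gap <= policy$max_gap
  i2 <- which(ok) + 1L
  i1 <- i2 - 1L
  new_tbl(
    timestamp = ts[i2],
    d_height = abs(h[i2] - h[i1]),
    d_width = abs(w[i2] - w[i1]),
    d_distance = sqrt((cx[i2] - cx[i1])^2 + (cy[i2] - cy[i1])^2),
    gap = gap[ok]
  )
}

empty_deltas <- function() {
  new_tbl(
    timestamp = double(), d_height = double(), d_width = double(),
    d_distance = double(), gap = double()
  )
}

#' Default mapping from delta channels to monitored parameters
#'
#' Height changes track posture transitions (stand/sit conversions change
#' the box height), width changes track in-place limb and hand activity,
#' and center displacement tracks locomotion. The mapping is a bijection
#' and can be overridden wherever it is consumed.
#'
#' @return Named character vector mapping channel names to parameter names.
#' @export
default_channel_map <- function() {
  c(
    d_height = "pose_conversion",
    d_width = "body_movement",
    d_distance = "positional_change"
  )
}

#' Metric names
#'
#' The three monitored parameters, plus the `"none"` sentinel returned for
#' an all-zero record.
#'
#' @return Character vector of factor levels used by [label_dominant()].
#' @export
metric_names <- function() {
  c("pose_conversion", "body_movement", "positional_change")
}

#' Dominant parameter of each delta record
#'
#' Labels each record with the parameter whose delta channel is strictly
#' largest. Ties are broken by the fixed priority
#' positional_change > body_movement > pose_conversion; an all-zero record
#' receives the `"none"` sentinel (no postural change observed).
#'
#' Accepts either raw delta records (`d_height`/`d_width`/`d_distance`
#' columns) or minute summaries (`mean_d_*` columns), so per-second and
#' per-minute classification share one rule.
#'
#' @param records A tibble of delta records or minute summaries.
#' @param channel_map Bijection from the three channel names to the three
#'   parameter names; see [default_channel_map()].
#' @return Factor with levels `pose_conversion`, `body_movement`,
#'   `positional_change`, `none`, one element per row.
#' @export
label_dominant <- function(records, channel_map = default_channel_map()) {
  chans <- c("d_height", "d_width", "d_distance")
  if (!setequal(names(channel_map), chans) ||
    !setequal(unname(channel_map), metric_names())) {
    stop("channel_map must be a bijection from the three delta channels ",
      "to the three parameter names",
      call. = FALSE
    )
  }
  cols <- if (all(chans %in% names(records))) {
    chans
  } else if (all(paste0("mean_", chans) %in% names(records))) {
    paste0("mean_", chans)
  } else {
    stop("records must carry d_* or mean_d_* columns", call. = FALSE)
  }
  v <- cbind(
    records[[cols[1]]], records[[cols[2]]], records[[cols[3]]]
  )
  colnames(v) <- chans
  # tie priority over parameters, mapped back to channels
  priority <- c("positional_change", "body_movement", "pose_conversion")
  chan_order <- names(channel_map)[match(priority, channel_map)]
  lab <- rep("none", nrow(v))
  if (nrow(v) > 0) {
    top <- do.call(pmax, as.data.frame(v))
    for (ch in rev(chan_order)) {
      hit <- v[, ch] == top & top > 0
      lab[hit] <- channel_map[[ch]]
    }
    # rev() above assigns lowest priority first; highest priority wins ties
  }
  factor(lab, levels = c(metric_names(), "none"))
}
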