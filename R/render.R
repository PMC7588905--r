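#' Standard 17-keypoint skeleton connectivity
#'
#' @return Tibble with columns `from`, `to` (part names), the conventional
#'   edge list used to draw pose maps.
#' @export
skeleton_edges <- function() {
  tibble::tribble(
    ~from, ~to,
    "nose", "leftEye",
    "nose", "rightEye",
    "leftEye", "leftEar",
    "rightEye", "rightEar",
    "leftShoulder", "rightShoulder",
    "leftShoulder", "leftElbow",
    "leftElbow", "leftWrist",
    "rightShoulder", "rightElbow",
    "rightElbow", "rightWrist",
    "leftShoulder", "leftHip",
    "rightShoulder", "rightHip",
    "leftHip", "rightHip",
    "leftHip", "leftKnee",
    "leftKnee", "leftAnkle",
    "rightHip", "rightKnee",
    "rightKnee", "rightAnkle"
  )
}

#' Draw a pose map
#'
#' Renders one frame the way the live canvas view does: keypoint markers,
#' the standard skeleton edges (for the parts present), and the pose
#' bounding box, on an image-convention canvas (origin top-left, y
#' downward) of the stream resolution.
#'
#' @param frame A single-row [pose_stream()] slice with keypoints.
#' @param resolution `c(width, height)` in pixels.
#' @param min_kp_score Keypoint confidence cutoff for the box overlay.
#' @return A ggplot object.
#' @export
render_pose_map <- function(frame, resolution = c(320, 240),
                            min_kp_score = 0) {
  if (nrow(frame) != 1) {
    stop("render_pose_map draws exactly one frame", call. = FALSE)
  }
  kp <- frame$keypoints[[1]]
  if (is.null(kp) || nrow(kp) == 0) {
    stop("frame has no keypoints to draw", call. = FALSE)
  }
  box <- bbox_from_keypoints(kp, min_kp_score)
  edges <- skeleton_edges()
  edges <- edges[edges$from %in% kp$part & edges$to %in% kp$part, ]
  seg <- tibble::tibble(
    x = kp$x[match(edges$from, kp$part)],
    y = kp$y[match(edges$from, kp$part)],
    xend = kp$x[match(edges$to, kp$part)],
    yend = kp$y[match(edges$to, kp$part)]
  )
  box_df <- tibble::tibble(
    x_min = box$x_min, x_max = box$x_max,
    y_min = box$y_min, y_max = box$y_max
  )
  ggplot2::ggplot(kp, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_rect(
      data = box_df,
      ggplot2::aes(
        xmin = .data$x_min, xmax = .data$x_max,
        ymin = .data$y_min, ymax = .data$y_max
      ),
      inherit.aes = FALSE, fill = NA, colour = "red", linewidth = 0.4
    ) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$x, y = .data$y,
        xend = .data$xend, yend = .data$yend
      ),
      inherit.aes = FALSE, colour = "steelblue", linewidth = 0.6
    ) +
    ggplot2::geom_point(size = 1.4, colour = "black") +
    ggplot2::scale_y_reverse(limits = c(resolution[2], 0), expand = c(0, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, resolution[1]), expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("t = %.0f  (score %.2f)", frame$timestamp, frame$score),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Per-minute activity chart
#'
#' One line per monitored parameter over clock time — the minute-level
#' evaluating-data chart for a single day (or any span of minutes).
#'
#' @param minutes Output of [summarize_minutes()].
#' @param channel_map Channel-to-parameter mapping for the legend; see
#'   [default_channel_map()].
#' @return A ggplot object.
#' @export
chart_minutes <- function(minutes, channel_map = default_channel_map()) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(minutes),
    cols = c("mean_d_height", "mean_d_width", "mean_d_distance"),
    names_to = "channel", values_to = "value"
  )
  long$parameter <- factor(
    channel_map[sub("^mean_", "", long$channel)],
    levels = metric_names()
  )
  long$time <- as.POSIXct(long$minute_start,
    origin = "1970-01-01", tz = "UTC"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time, y = .data$value, colour = .data$parameter
  )) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "time", y = "mean change per minute (px)", colour = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Daily combination chart
#'
#' Bars for each day's cumulative parameter totals (left axis, pixels)
#' with the total active hours overlaid as a line on a secondary right
#' axis — the day-level rollup view.
#'
#' @param days Output of [summarize_days()].
#' @param channel_map Channel-to-parameter mapping for the legend.
#' @return A ggplot object.
#' @export
chart_daily <- function(days, channel_map = default_channel_map()) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(days),
    cols = c("total_d_height", "total_d_width", "total_d_distance"),
    names_to = "channel", values_to = "total"
  )
  long$parameter <- factor(
    channel_map[sub("^total_", "", long$channel)],
    levels = metric_names()
  )
  ratio <- max(long$total, 1) / max(days$active_hours, 1e-9)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$total, fill = .data$parameter),
      position = "dodge"
    ) +
    ggplot2::geom_line(
      data = tibble::as_tibble(days),
      ggplot2::aes(y = .data$active_hours * ratio, group = 1),
      colour = "black", linewidth = 0.7
    ) +
    ggplot2::geom_point(
      data = tibble::as_tibble(days),
      ggplot2::aes(y = .data$active_hours * ratio),
      colour = "black", size = 1.6
    ) +
    ggplot2::scale_y_continuous(
      name = "cumulative change (px)",
      sec.axis = ggplot2::sec_axis(~ . / ratio, name = "active hours")
    ) +
    ggplot2::labs(x = "date", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
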