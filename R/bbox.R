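#' Axis-aligned bounding box
#'
#' @param x_min,x_max,y_min,y_max Box extents in pixels (image convention:
#'   y increases downward).
#' @return An object of class `bbox`.
#' @export
#' @examples
#' bbox(0, 10, 0, 20)
bbox <- function(x_min, x_max, y_min, y_max) {
  if (x_min > x_max || y_min > y_max) {
    stop("malformed bounding box: min exceeds max", call. = FALSE)
  }
  structure(
    list(
      x_min = as.double(x_min), x_max = as.double(x_max),
      y_min = as.double(y_min), y_max = as.double(y_max)
    ),
    class = "bbox"
  )
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf(
    "<bbox> x: [%g, %g]  y: [%g, %g]  (w = %g, h = %g)\n",
    x$x_min, x$x_max, x$y_min, x$y_max, bbox_width(x), bbox_height(x)
  ))
  invisible(x)
}

#' Box width, height and center
#'
#' @param box A [bbox()].
#' @return `bbox_width()` and `bbox_height()` return pixels;
#'   `bbox_center()` returns a named numeric `c(x, y)`.
#' @export
bbox_width <- function(box) box$x_max - box$x_min

#' @rdname bbox_width
#' @export
bbox_height <- function(box) box$y_max - box$y_min

#' @rdname bbox_width
#' @export
bbox_center <- function(box) {
  c(x = (box$x_min + box$x_max) / 2, y = (box$y_min + box$y_max) / 2)
}

#' Bounding box of a keypoint set
#'
#' Computes the min/max x and y over the keypoints whose confidence passes
#' `min_kp_score` — the pose bounding box whose shape and displacement the
#' downstream change metrics are built on.
#'
#' @param keypoints A keypoint tibble (columns `x`, `y`, `score`).
#' @param min_kp_score Per-keypoint confidence cutoff in `[0, 1]`; the
#'   default 0 includes every reported keypoint.
#' @return A [bbox()]. Errors if no keypoint passes the cutoff (the caller
#'   treats such a frame as invalid).
#' @export
#' @examples
#' kp <- keypoints(c("nose", "leftWrist"), x = c(3, 7), y = c(4, 1), score = 0.9)
#' bbox_from_keypoints(kp)
bbox_from_keypoints <- function(keypoints, min_kp_score = 0) {
  keep <- keypoints$score >= min_kp_score
  if (!any(keep)) {
    stop("empty pose: no keypoint reaches min_kp_score = ", min_kp_score,
      call. = FALSE
    )
  }
  x <- keypoints$x[keep]
  y <- keypoints$y[keep]
  bbox(min(x), max(x), min(y), max(y))
}

#' Per-pair bounding-box change metrics
#'
#' The three change metrics between two pose bounding boxes:
#' * `d_height` — absolute change in box height (tracks pose conversion,
#'   e.g. standing up / sitting down);
#' * `d_width` — absolute change in box width (tracks in-place body
#'   movement such as hand and limb activity);
#' * `d_distance` — Euclidean displacement of the box center (tracks
#'   positional change, i.e. locomotion).
#'
#' All three are absolute magnitudes, so the function is symmetric in its
#' arguments. The same formulas serve both consecutive frames of one stream
#' and predicted-versus-reference boxes of one image
#' (see [difference_triple()]).
#'
#' @param prev,curr Two well-formed [bbox()] objects.
#' @return Named numeric vector `c(d_height, d_width, d_distance)` in pixels.
#' @export
#' @examples
#' delta_metrics(bbox(0, 10, 0, 20), bbox(3, 13, 4, 24)) # pure translation
delta_metrics <- function(prev, curr) {
  ctr_p <- bbox_center(prev)
  ctr_c <- bbox_center(curr)
  c(
    d_height = abs(bbox_height(curr) - bbox_height(prev)),
    d_width = abs(bbox_width(curr) - bbox_width(prev)),
    d_distance = sqrt(sum((ctr_c - ctr_p)^2))
  )
}
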