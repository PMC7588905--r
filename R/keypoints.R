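#' The 17-part keypoint vocabulary
#'
#' Named anatomical landmarks reported by single-person pose-estimation
#' models of the PoseNet/COCO family, in their conventional order.
#'
#' @return Character vector of the 17 permitted part names.
#' @export
#' @examples
#' keypoint_parts()
keypoint_parts <- function() {
  c(
    "nose", "leftEye", "rightEye", "leftEar", "rightEar",
    "leftShoulder", "rightShoulder", "leftElbow", "rightElbow",
    "leftWrist", "rightWrist", "leftHip", "rightHip",
    "leftKnee", "rightKnee", "leftAnkle", "rightAnkle"
  )
}

# Fast tibble constructor for hot paths (no validation, no recycling).
new_tbl <- function(...) {
  cols <- list(...)
  n <- length(cols[[1L]])
  structure(cols,
    class = c("tbl_df", "tbl", "data.frame"),
    row.names = c(NA_integer_, -n)
  )
}

#' Build a keypoint table
#'
#' @param part Character vector of part names from [keypoint_parts()].
#' @param x,y Pixel coordinates. Image convention: origin at the top-left
#'   corner, `x` increases rightward, `y` increases downward.
#' @param score Per-keypoint confidence in `[0, 1]`.
#' @return A tibble with columns `part`, `x`, `y`, `score`.
#' @export
keypoints <- function(part, x, y, score = 1) {
  n <- length(part)
  kp <- new_tbl(
    part = as.character(part),
    x = as.double(rep_len(x, n)),
    y = as.double(rep_len(y, n)),
    score = as.double(rep_len(score, n))
  )
  validate_keypoints(kp)
  kp
}

validate_keypoints <- function(kp, where = "keypoints") {
  if (!is.data.frame(kp) || !all(c("part", "x", "y", "score") %in% names(kp))) {
    stop(where, ": keypoints must have columns part, x, y, score", call. = FALSE)
  }
  bad <- setdiff(kp$part, keypoint_parts())
  if (length(bad) > 0) {
    stop(where, ": unknown keypoint part(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(kp$part)) {
    stop(where, ": duplicated keypoint part(s): ",
      paste(unique(kp$part[duplicated(kp$part)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(kp$x)) || any(!is.finite(kp$y))) {
    stop(where, ": keypoint coordinates must be finite", call. = FALSE)
  }
  if (any(kp$score < 0 | kp$score > 1 | !is.finite(kp$score))) {
    stop(where, ": keypoint scores must lie in [0, 1]", call. = FALSE)
  }
  invisible(kp)
}

#' Build a pose-frame stream
#'
#' A pose stream is one row per observed second: the frame timestamp (integer
#' seconds since epoch, 1 s grid), the estimator's overall confidence, the
#' number of detected persons, and a nested keypoint table (17 rows when a
#' person is present, zero rows otherwise).
#'
#' @param timestamp Integer seconds since epoch, strictly increasing.
#' @param score Overall pose confidence in `[0, 1]`.
#' @param persons Detected person count (`>= 0`).
#' @param keypoints List of keypoint tibbles (see [keypoints()]), one per
#'   frame; must be empty exactly when `persons` is 0.
#' @return A tibble of class `pose_stream`.
#' @export
#' @examples
#' pose_stream(
#'   timestamp = 100, score = 0.9, persons = 1,
#'   keypoints = list(keypoints("nose", 160, 60, 0.95))
#' )
pose_stream <- function(timestamp = numeric(), score = numeric(),
                        persons = integer(), keypoints = list()) {
  n <- length(timestamp)
  out <- new_tbl(
    timestamp = as.double(timestamp),
    score = as.double(rep_len(score, n)),
    persons = as.integer(rep_len(persons, n)),
    keypoints = keypoints
  )
  class(out) <- c("pose_stream", class(out))
  validate_pose_stream(out)
  out
}

new_pose_stream <- function(timestamp, score, persons, keypoints) {
  out <- new_tbl(
    timestamp = timestamp, score = score,
    persons = persons, keypoints = keypoints
  )
  class(out) <- c("pose_stream", class(out))
  out
}

#' Validate a pose stream against its invariants
#'
#' Checks the frame-level invariants: integer timestamps on a 1 s grid,
#' strictly increasing order (duplicates and reversals are rejected, never
#' silently sorted), scores in `[0, 1]`, and `persons == 0` if and only if
#' the frame has no keypoints. Keypoint tables are validated per frame.
#'
#' @param stream A [pose_stream()] tibble.
#' @return The stream, invisibly; errors on the first violation.
#' @export
validate_pose_stream <- function(stream) {
  if (!is.data.frame(stream) ||
    !all(c("timestamp", "score", "persons", "keypoints") %in% names(stream))) {
    stop("pose stream must have columns timestamp, score, persons, keypoints",
      call. = FALSE
    )
  }
  ts <- stream$timestamp
  if (any(!is.finite(ts)) || any(ts != floor(ts))) {
    stop("timestamps must be integer seconds (sub-second input is rejected)",
      call. = FALSE
    )
  }
  if (length(ts) > 1) {
    d <- diff(ts)
    if (any(d == 0)) {
      stop("duplicate timestamp at ", ts[which(d == 0)[1] + 1], call. = FALSE)
    }
    if (any(d < 0)) {
      stop("timestamps must be strictly increasing (violation at ",
        ts[which(d < 0)[1] + 1], ")",
        call. = FALSE
      )
    }
  }
  if (any(stream$score < 0 | stream$score > 1 | !is.finite(stream$score))) {
    stop("overall scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(stream$persons < 0)) {
    stop("persons must be >= 0", call. = FALSE)
  }
  for (i in seq_len(nrow(stream))) {
    kp <- stream$keypoints[[i]]
    n_kp <- if (is.null(kp)) 0L else nrow(kp)
    if (stream$persons[i] == 0 && n_kp != 0) {
      stop("frame at ", ts[i], ": persons = 0 but keypoints present",
        call. = FALSE
      )
    }
    if (stream$persons[i] >= 1) {
      if (n_kp != 17) {
        stop("frame at ", ts[i], ": expected 17 keypoints, got ", n_kp,
          call. = FALSE
        )
      }
      validate_keypoints(kp, where = paste0("frame at ", ts[i]))
    }
  }
  invisible(stream)
}
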