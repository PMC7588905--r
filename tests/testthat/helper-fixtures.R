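# Shared fixture builders. Everything is generated in code; nothing binary.

# A deterministic full 17-part keypoint set centred at (x0, y0).
kp17 <- function(x0 = 160, y0 = 120, spread = 30, score = 0.9) {
  parts <- keypoint_parts()
  n <- length(parts)
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  keypoints(
    part = parts,
    x = x0 + spread * cos(ang),
    y = y0 + spread * sin(ang),
    score = score
  )
}

# Shift every keypoint of a set by (dx, dy).
kp_shift <- function(kp, dx = 0, dy = 0) {
  kp$x <- kp$x + dx
  kp$y <- kp$y + dy
  kp
}

# A stream of full frames at the given timestamps; positions can be shifted
# per frame via dx/dy vectors.
make_stream <- function(ts, scores = 0.9, persons = 1L,
                        dx = 0, dy = 0, kp_score = 0.9) {
  n <- length(ts)
  scores <- rep_len(scores, n)
  persons <- rep_len(as.integer(persons), n)
  dx <- rep_len(dx, n)
  dy <- rep_len(dy, n)
  kps <- lapply(seq_len(n), function(i) {
    if (persons[i] == 0L) {
      keypoints(character(), numeric(), numeric(), numeric())
    } else {
      kp_shift(kp17(score = kp_score), dx[i], dy[i])
    }
  })
  pose_stream(ts, scores, persons, kps)
}

# Independent brute-force bounding-box oracle: explicit loop over points.
oracle_bbox <- function(kp, min_kp_score = 0) {
  x_min <- Inf
  x_max <- -Inf
  y_min <- Inf
  y_max <- -Inf
  for (i in seq_len(nrow(kp))) {
    if (kp$score[i] >= min_kp_score) {
      if (kp$x[i] < x_min) x_min <- kp$x[i]
      if (kp$x[i] > x_max) x_max <- kp$x[i]
      if (kp$y[i] < y_min) y_min <- kp$y[i]
      if (kp$y[i] > y_max) y_max <- kp$y[i]
    }
  }
  c(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max)
}

# Random keypoint set of 1..17 points on the 320 x 240 scene.
random_kp <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:17, 1)
  keypoints(
    part = sample(keypoint_parts(), n),
    x = runif(n, 0, 320),
    y = runif(n, 0, 240),
    score = runif(n)
  )
}

# The 3-frame score-filter trace fixture: scores (0.9, 0.3, 0.9) at t = 0,1,2.
filter_trace_stream <- function() {
  make_stream(ts = c(0, 1, 2), scores = c(0.9, 0.3, 0.9))
}

as_delta_matrix <- function(deltas) {
  as.matrix(deltas[c("d_height", "d_width", "d_distance")])
}
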