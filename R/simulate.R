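#' One activity segment of a simulation schedule
#'
#' @param start,end Segment bounds in integer seconds; frames are emitted
#'   for `start, ..., end - 1`. Segments must not overlap.
#' @param activity One of `"stand"`, `"sit"`, `"walk"`, `"lie"`,
#'   `"hand_activity"`, `"absent"`, `"visitor"`.
#' @param ... Activity parameters: `speed` (px/s) and `heading` (degrees,
#'   0 = rightward, 90 = downward) for `walk`; `amplitude` (px) and
#'   `period` (s) for `hand_activity`; `base` (the subject's own activity)
#'   for `visitor`; `anchor` (`c(x, y)` of the figure's floor midpoint)
#'   for any activity.
#' @return A one-row schedule tibble.
#' @export
#' @examples
#' sim_segment(0, 600, "walk", speed = 5)
sim_segment <- function(start, end, activity, ...) {
  activity <- match.arg(activity, sim_activities())
  if (start >= end) stop("segment start must precede end", call. = FALSE)
  if (start != floor(start) || end != floor(end)) {
    stop("segment bounds must be integer seconds", call. = FALSE)
  }
  tibble::tibble(
    start = as.double(start), end = as.double(end),
    activity = activity, params = list(list(...))
  )
}

sim_activities <- function() {
  c("stand", "sit", "walk", "lie", "hand_activity", "absent", "visitor")
}

#' Simulation configuration
#'
#' Describes a single-person scene watched by a fixed camera: one frame of
#' 17 keypoints per scheduled second, with additive coordinate jitter and
#' sampled confidence scores. Defaults emulate the monitored single-room
#' setting: a 320 x 240 px image of a 4 m x 3 m room sampled once per
#' second with a 0.5 pose-score threshold downstream.
#'
#' @param schedule Schedule tibble built from [sim_segment()] rows
#'   (ordered, non-overlapping; gaps between segments emit nothing).
#' @param resolution `c(width, height)` in pixels, default `c(320, 240)`.
#' @param noise_sd Per-coordinate Gaussian jitter SD in pixels (default 0).
#' @param score_model List with `mean` and `kappa`: overall and
#'   per-keypoint confidences are drawn from
#'   `Beta(mean * kappa, (1 - mean) * kappa)`. Default mean 0.85,
#'   kappa 40 — well-lit single-person estimates that occasionally dip,
#'   exercising the 0.5 threshold path. `kappa = Inf` is the degenerate
#'   limit: every score is exactly `mean` (useful when a property under
#'   test should not depend on confidence sampling).
#' @param seed Integer RNG seed; the whole stream is reproducible from it.
#' @param ramp Seconds over which a change of activity is linearly
#'   interpolated (default 3), so posture-transition spikes are finite.
#' @param coord_scale Multiplies every coordinate-valued quantity
#'   (template geometry, anchors, speeds, jitter and the frame bounds)
#'   after noise is drawn, so the same seed yields an exactly scaled scene.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(schedule,
                       resolution = c(320, 240),
                       noise_sd = 0,
                       score_model = list(mean = 0.85, kappa = 40),
                       seed = 1,
                       ramp = 3,
                       coord_scale = 1) {
  stopifnot(
    length(resolution) == 2, all(resolution > 0),
    noise_sd >= 0, ramp >= 0, coord_scale > 0
  )
  schedule <- dplyr::arrange(schedule, .data$start)
  if (nrow(schedule) > 1) {
    if (any(schedule$start[-1] < schedule$end[-nrow(schedule)])) {
      stop("schedule segments overlap", call. = FALSE)
    }
  }
  structure(
    list(
      schedule = schedule, resolution = as.double(resolution),
      noise_sd = noise_sd, score_model = score_model,
      seed = as.integer(seed), ramp = ramp, coord_scale = coord_scale
    ),
    class = "sim_config"
  )
}

#' Read a simulation config from JSON
#'
#' The document mirrors [sim_config()]:
#' `{"resolution": [320, 240], "noise_sd": 2, "seed": 7, "ramp": 3,
#'   "schedule": [{"start": 0, "end": 600, "activity": "stand"}, ...]}`
#' with optional activity parameters inside each segment object.
#'
#' @param path Path to the JSON file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schedule) || length(doc$schedule) == 0) {
    stop("config must contain a non-empty schedule", call. = FALSE)
  }
  segs <- lapply(doc$schedule, function(s) {
    extra <- s[setdiff(names(s), c("start", "end", "activity"))]
    extra <- lapply(extra, function(v) if (length(v) > 1) unlist(v) else v)
    do.call(sim_segment, c(list(s$start, s$end, s$activity), extra))
  })
  args <- list(schedule = dplyr::bind_rows(segs))
  if (!is.null(doc$resolution)) args$resolution <- unlist(doc$resolution)
  for (f in c("noise_sd", "seed", "ramp", "coord_scale")) {
    if (!is.null(doc[[f]])) args[[f]] <- doc[[f]]
  }
  if (!is.null(doc$score_model)) args$score_model <- doc$score_model
  do.call(sim_config, args)
}

# Stylized articulated figure. Offsets in px relative to the floor midpoint
# between the feet; y is negative upward (image convention). Standing
# figure is 150 px tall (a person prominent in the frame) and 50 px wide;
# sitting compresses height to 60%; lying is wide and short.
template_offsets <- function(activity, phase = 0, params = list()) {
  parts <- keypoint_parts()
  stand <- matrix(c(
    0, -147, # nose
    -3, -150, 3, -150, # eyes
    -6, -148, 6, -148, # ears
    -20, -130, 20, -130, # shoulders
    -23, -105, 23, -105, # elbows
    -25, -82, 25, -82, # wrists
    -15, -75, 15, -75, # hips
    -12, -38, 12, -38, # knees
    -10, 0, 10, 0 # ankles
  ), ncol = 2, byrow = TRUE)
  sit <- matrix(c(
    0, -87,
    -3, -90, 3, -90,
    -6, -88, 6, -88,
    -20, -72, 20, -72,
    -23, -55, 23, -55,
    -25, -42, 25, -42,
    -15, -40, 15, -40,
    -18, -20, 18, -20,
    -10, 0, 10, 0
  ), ncol = 2, byrow = TRUE)
  lie <- matrix(c(
    -72, -30,
    -74, -32, -70, -32,
    -75, -28, -69, -28,
    -52, -30, -52, -10,
    -30, -32, -30, -8,
    -8, -30, -8, -10,
    5, -28, 5, -12,
    38, -30, 38, -10,
    75, -32, 75, -8
  ), ncol = 2, byrow = TRUE)
  rownames(stand) <- rownames(sit) <- rownames(lie) <- parts
  switch(activity,
    stand = stand,
    walk = stand, # rigid figure; locomotion is anchor translation
    sit = sit,
    lie = lie,
    hand_activity = {
      amp <- params$amplitude %||% 12
      period <- params$period %||% 2
      osc <- (1 + cos(2 * pi * phase)) / 2 # 1 at phase 0, 0 at phase 0.5
      out <- stand
      out["leftWrist", 1] <- -(25 + amp * osc)
      out["rightWrist", 1] <- 25 + amp * osc
      out["leftElbow", 1] <- -(23 + amp * osc / 2)
      out["rightElbow", 1] <- 23 + amp * osc / 2
      out
    },
    visitor = template_offsets(params$base %||% "sit", phase, params),
    stop("no skeleton template for activity '", activity, "'", call. = FALSE)
  )
}

#' Skeleton template for an activity
#'
#' The deterministic 17-keypoint offset table of the stylized figure used
#' by the simulator, relative to the figure's floor anchor (midpoint
#' between the feet), before placement, interpolation and noise. Standing
#' and walking figures are tall and narrow, sitting is 60% of standing
#' height at identical width, lying is wide and short, and hand activity
#' oscillates the wrist and elbow offsets with `phase`.
#'
#' @param activity Activity name (see [sim_segment()]); `absent` has no
#'   template.
#' @param phase Oscillation phase in `[0, 1]` (used by `hand_activity`).
#' @param params Activity parameters (`amplitude`, `period`, `base`).
#' @return Tibble with columns `part`, `x_offset`, `y_offset` (pixels,
#'   `y_offset` negative upward).
#' @export
skeleton_template <- function(activity, phase = 0, params = list()) {
  m <- template_offsets(activity, phase, params)
  tibble::tibble(
    part = rownames(m), x_offset = m[, 1], y_offset = m[, 2]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# triangle-wave fold of p into [lo, hi]
pingpong <- function(p, lo, hi) {
  r <- hi - lo
  if (r <= 0) {
    return(rep(lo, length(p)))
  }
  q <- (p - lo) %% (2 * r)
  ifelse(q <= r, lo + q, hi - (q - r))
}

#' Simulate a pose-frame stream with ground truth
#'
#' Emits one frame per scheduled second for non-absent segments; absent
#' segments (and schedule gaps) emit nothing, mirroring a pipeline in
#' which an empty detection is never stored. Activity changes between
#' adjacent segments are linearly interpolated over `config$ramp` seconds.
#' Gaussian coordinate jitter and Beta-distributed confidence scores are
#' added afterwards; `visitor` segments report `persons = 2` while
#' retaining the subject's keypoints as the single estimated pose, as a
#' single-person estimator does when a caregiver enters the scene.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#' * `frames` — a [pose_stream()];
#' * `labels` — ground truth, one row per scheduled second: `second`,
#'   `activity`, `segment` (schedule row index), `persons`, `emitted`,
#'   `transition` (`TRUE` for seconds whose pose is affected by the
#'   interpolation ramp);
#' * `config` — the input configuration.
#' @export
simulate_stream <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sched <- config$schedule
  res <- config$resolution
  scale <- config$coord_scale
  ramp <- config$ramp
  sm <- config$score_model
  const_score <- is.infinite(sm$kappa)
  a_sh <- sm$mean * sm$kappa
  b_sh <- (1 - sm$mean) * sm$kappa
  default_anchor <- c(res[1] / 2, res[2] * 0.875)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  )
  set.seed(config$seed)

  total <- sum(sched$end - sched$start)
  ts <- double(total)
  score <- double(total)
  persons <- integer(total)
  kps <- vector("list", total)
  lab_second <- double(total)
  lab_activity <- character(total)
  lab_segment <- integer(total)
  lab_persons <- integer(total)
  lab_emitted <- logical(total)
  lab_transition <- logical(total)

  parts <- keypoint_parts()
  nf <- 0L # emitted frames
  li <- 0L # label rows
  blend_from <- NULL # pose (base scale) of the previous emitted second
  prev_t <- NA_real_

  for (k in seq_len(nrow(sched))) {
    act <- sched$activity[k]
    prm <- sched$params[[k]]
    seg_start <- sched$start[k]
    seg_end <- sched$end[k]
    anchor0 <- prm$anchor %||% default_anchor
    # does this segment blend out of the previous one?
    seg_blend <- if (act != "absent" && !is.na(prev_t) &&
      prev_t == seg_start - 1 && !is.null(blend_from)) {
      blend_from
    } else {
      NULL
    }
    for (t in seq(seg_start, seg_end - 1)) {
      u <- t - seg_start
      li <- li + 1L
      lab_second[li] <- t
      lab_activity[li] <- act
      lab_segment[li] <- k
      if (act == "absent") {
        lab_persons[li] <- 0L
        lab_emitted[li] <- FALSE
        blend_from <- NULL
        prev_t <- NA_real_
        next
      }
      if (act == "walk") {
        speed <- prm$speed %||% 8
        heading <- (prm$heading %||% 0) * pi / 180
        px <- anchor0[1] + speed * u * cos(heading)
        py <- anchor0[2] + speed * u * sin(heading)
        anchor <- c(
          pingpong(px, 40, res[1] - 40),
          pingpong(py, res[2] * 0.66, res[2] - 8)
        )
      } else {
        anchor <- anchor0
      }
      period <- prm$period %||% 2
      phase <- (u %% period) / period
      tmpl <- template_offsets(act, phase, prm)
      target <- cbind(
        unname(tmpl[, 1]) + anchor[1],
        unname(tmpl[, 2]) + anchor[2]
      )
      blended <- FALSE
      if (!is.null(seg_blend) && ramp > 0 && u < ramp) {
        w <- u / ramp
        target <- (1 - w) * seg_blend + w * target
        blended <- TRUE
      }
      z <- matrix(stats::rnorm(34), ncol = 2)
      coords <- (target + z * config$noise_sd) * scale
      coords[, 1] <- pmin(pmax(coords[, 1], 0), res[1] * scale)
      coords[, 2] <- pmin(pmax(coords[, 2], 0), res[2] * scale)
      if (const_score) {
        overall <- sm$mean
        kp_scores <- rep(sm$mean, 17)
      } else {
        overall <- stats::rbeta(1, a_sh, b_sh)
        kp_scores <- stats::rbeta(17, a_sh, b_sh)
      }

      nf <- nf + 1L
      ts[nf] <- t
      score[nf] <- overall
      persons[nf] <- if (act == "visitor") 2L else 1L
      kps[[nf]] <- new_tbl(
        part = parts, x = coords[, 1], y = coords[, 2], score = kp_scores
      )
      lab_persons[li] <- persons[nf]
      lab_emitted[li] <- TRUE
      # the ramp perturbs deltas at seconds u = 0..ramp of a blended entry
      lab_transition[li] <- blended || (!is.null(seg_blend) && u <= ramp && ramp > 0)
      blend_from <- target
      prev_t <- t
    }
  }
  frames <- new_pose_stream(
    ts[seq_len(nf)], score[seq_len(nf)], persons[seq_len(nf)],
    kps[seq_len(nf)]
  )
  labels <- new_tbl(
    second = lab_second[seq_len(li)],
    activity = lab_activity[seq_len(li)],
    segment = lab_segment[seq_len(li)],
    persons = lab_persons[seq_len(li)],
    emitted = lab_emitted[seq_len(li)],
    transition = lab_transition[seq_len(li)]
  )
  list(frames = frames, labels = labels, config = config)
}

#' Write ground-truth labels to CSV
#'
#' @param labels The `labels` element of a [simulate_stream()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' Expected per-minute dominant channels of a simulation
#'
#' Derives, from the ground-truth labels, the minutes whose dominant
#' parameter is unambiguous: every second of the minute (plus the second
#' before it, which pairs into the minute's first delta) was emitted from
#' one and the same segment, the segment's activity drives a single
#' channel deterministically (`walk` drives positional change,
#' `hand_activity` drives body movement), and no second is on an
#' interpolation ramp. Static activities (stand, sit, lie) produce an
#' all-zero signal at zero noise, so no dominant channel is defined for
#' them; visitor and transition minutes are mixtures. Such minutes are
#' excluded rather than guessed.
#'
#' @param sim Result of [simulate_stream()].
#' @return Tibble with columns `minute_start`, `activity`, `expected`
#'   (factor as in [label_dominant()]), one row per unambiguous minute.
#' @export
expected_minute_labels <- function(sim) {
  lab <- sim$labels
  driven <- c(walk = "positional_change", hand_activity = "body_movement")
  lab_by_second <- lab[order(lab$second), ]
  minute <- floor(lab_by_second$second / 60) * 60
  out <- list()
  for (m in unique(minute)) {
    idx <- which(minute == m)
    if (length(idx) < 60) next # minute not fully scheduled
    rows <- lab_by_second[idx, ]
    act <- rows$activity[1]
    if (!act %in% names(driven)) next
    prev <- lab_by_second[lab_by_second$second == m - 1, ]
    if (nrow(prev) != 1) next
    same_seg <- all(rows$segment == rows$segment[1]) &&
      prev$segment == rows$segment[1]
    if (!same_seg) next
    if (!all(rows$emitted) || !prev$emitted) next
    if (any(rows$transition) || prev$transition) next
    out[[length(out) + 1]] <- tibble::tibble(
      minute_start = m, activity = act, expected = driven[[act]]
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      minute_start = double(), activity = character(),
      expected = factor(character(), levels = c(metric_names(), "none"))
    ))
  }
  res <- dplyr::bind_rows(out)
  res$expected <- factor(res$expected, levels = c(metric_names(), "none"))
  res
}

#' A cyclic demonstration schedule
#'
#' Blocks of standing, walking, sitting and hand activity repeated for the
#' requested duration — the scripted mix used throughout the package's
#' examples and self-tests.
#'
#' @param duration Total schedule length in seconds (default 7200, two
#'   hours).
#' @param block Block length in seconds (default 300).
#' @param start First scheduled second (default 0).
#' @param pattern Character vector of activities to cycle through.
#' @return A schedule tibble for [sim_config()].
#' @export
demo_schedule <- function(duration = 7200, block = 300, start = 0,
                          pattern = c("stand", "walk", "sit", "hand_activity")) {
  starts <- seq(start, start + duration - 1, by = block)
  segs <- lapply(seq_along(starts), function(i) {
    sim_segment(
      starts[i], min(starts[i] + block, start + duration),
      pattern[(i - 1) %% length(pattern) + 1]
    )
  })
  dplyr::bind_rows(segs)
}
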