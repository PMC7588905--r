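tmpl_box <- function(activity, phase = 0, params = list()) {
  t <- skeleton_template(activity, phase, params)
  c(w = diff(range(t$x_offset)), h = diff(range(t$y_offset)))
}

test_that("skeleton templates have the intended silhouettes", {
  for (ph in c(0, 0.3, 0.7)) {
    st <- tmpl_box("stand", ph)
    expect_gt(st[["h"]], st[["w"]])
    li <- tmpl_box("lie", ph)
    expect_gt(li[["w"]], li[["h"]])
  }
  si <- tmpl_box("sit")
  st <- tmpl_box("stand")
  expect_equal(si[["h"]] / st[["h"]], 0.6)
  expect_identical(si[["w"]], st[["w"]]) # posture change is pure height

  # hand activity differs from itself across phase only at wrists/elbows
  a <- skeleton_template("hand_activity", phase = 0)
  b <- skeleton_template("hand_activity", phase = 0.5)
  moved <- a$part[a$x_offset != b$x_offset | a$y_offset != b$y_offset]
  expect_setequal(moved, c("leftWrist", "rightWrist", "leftElbow", "rightElbow"))
  expect_error(skeleton_template("absent"), "no skeleton template")
})

test_that("a static scene yields frames with exactly zero deltas", {
  cfg <- sim_config(sim_segment(0, 600, "stand"), noise_sd = 0, seed = 1)
  sim <- simulate_stream(cfg)
  expect_identical(nrow(sim$frames), 600L)
  d <- compute_deltas(sim$frames)
  expect_identical(nrow(d), 599L)
  expect_true(all(as_delta_matrix(d) == 0))
})

test_that("noise-free walking gives the constant-velocity closed form", {
  cfg <- sim_config(sim_segment(0, 60, "walk", speed = 5), noise_sd = 0, seed = 1)
  d <- compute_deltas(simulate_stream(cfg)$frames)
  expect_equal(d$d_distance, rep(5, 59), tolerance = 1e-12)
  expect_true(all(d$d_height == 0))
  expect_true(all(d$d_width == 0))
})

test_that("streams are reproducible from the seed and differ across seeds", {
  cfg <- sim_config(demo_schedule(600), noise_sd = 2, seed = 77)
  s1 <- simulate_stream(cfg)
  s2 <- simulate_stream(cfg)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$labels, s2$labels)
  s3 <- simulate_stream(sim_config(demo_schedule(600), noise_sd = 2, seed = 78))
  expect_false(identical(s1$frames, s3$frames))
  # the NDJSON files are byte-identical too
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_pose_stream(s1$frames, f1)
  write_pose_stream(s2$frames, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("absent segments emit nothing and visitor segments report two persons", {
  sched <- dplyr::bind_rows(
    sim_segment(0, 60, "sit"),
    sim_segment(60, 120, "absent"),
    sim_segment(120, 180, "visitor")
  )
  sim <- simulate_stream(sim_config(sched, noise_sd = 0, seed = 2))
  expect_identical(nrow(sim$frames), 120L)
  expect_false(any(sim$frames$timestamp %in% 60:119))
  expect_identical(nrow(sim$labels), 180L)
  expect_true(all(!sim$labels$emitted[sim$labels$activity == "absent"]))
  vis <- sim$frames$persons[sim$frames$timestamp >= 120]
  expect_true(all(vis == 2L))
  # visitor frames retain a single 17-keypoint pose for the subject
  expect_true(all(vapply(sim$frames$keypoints, nrow, integer(1)) == 17L))
  # and are excluded upstream under the exclude policy
  valid <- frame_passes(sim$frames, filter_policy(multi_person = "exclude"))
  expect_true(all(sim$frames$timestamp[valid] < 60))
})

test_that("noise-free per-second labels match the scheduled activity channels", {
  sched <- dplyr::bind_rows(
    sim_segment(0, 120, "stand"),
    sim_segment(120, 240, "sit"),
    sim_segment(240, 300, "walk", speed = 6),
    sim_segment(300, 360, "hand_activity")
  )
  sim <- simulate_stream(sim_config(sched, noise_sd = 0, seed = 4))
  d <- compute_deltas(sim$frames)
  lab <- label_dominant(d)
  labels <- sim$labels
  is_transition <- labels$transition[match(d$timestamp, labels$second)]
  act <- labels$activity[match(d$timestamp, labels$second)]

  # stand <-> sit ramp seconds with actual motion register as pose
  # conversion (the first transition second still holds the previous pose)
  ramp <- labels$second[labels$transition & labels$activity == "sit"]
  moving <- d$timestamp %in% ramp & rowSums(as_delta_matrix(d)) > 0
  expect_gte(sum(moving), 3)
  expect_true(all(lab[moving] == "pose_conversion"))

  # non-transition seconds: walk -> positional change, hand -> body movement,
  # static seconds -> the all-zero sentinel; zero misclassifications
  steady <- !is_transition
  expect_true(all(lab[steady & act == "walk"] == "positional_change"))
  expect_true(all(lab[steady & act == "hand_activity"] == "body_movement"))
  expect_true(all(lab[steady & act %in% c("stand", "sit")] == "none"))
})

test_that("simulated active hours equal scheduled presence exactly", {
  sched <- dplyr::bind_rows(
    sim_segment(0, 3600, "sit"),
    sim_segment(3600, 7200, "absent")
  )
  cfg <- sim_config(sched,
    noise_sd = 2, seed = 12,
    score_model = list(mean = 0.85, kappa = Inf)
  )
  sim <- simulate_stream(cfg)
  days <- summarize_days(sim$frames, compute_deltas(sim$frames))
  expect_identical(days$active_hours, 1)
})

test_that("schedule validation rejects overlaps and bad segments", {
  expect_error(
    sim_config(dplyr::bind_rows(
      sim_segment(0, 100, "stand"), sim_segment(50, 150, "sit")
    )),
    "overlap"
  )
  expect_error(sim_segment(10, 10, "stand"), "precede")
  expect_error(sim_segment(0, 10, "juggle"), "arg")
  expect_error(sim_segment(0.5, 10, "stand"), "integer")
})

test_that("JSON configs load into equivalent simulations", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "resolution": [320, 240], "noise_sd": 1.5, "seed": 21, "ramp": 3,
    "schedule": [
      {"start": 0, "end": 120, "activity": "stand"},
      {"start": 120, "end": 240, "activity": "walk", "speed": 5, "heading": 0},
      {"start": 240, "end": 300, "activity": "absent"}
    ]
  }', path)
  cfg <- read_sim_config(path)
  expect_identical(cfg$noise_sd, 1.5)
  expect_identical(cfg$seed, 21L)
  expect_identical(cfg$schedule$activity, c("stand", "walk", "absent"))
  expect_identical(cfg$schedule$params[[2]]$speed, 5L)
  sim <- simulate_stream(cfg)
  expect_identical(nrow(sim$frames), 240L)
  # equivalent to the in-code construction
  sched <- dplyr::bind_rows(
    sim_segment(0, 120, "stand"),
    sim_segment(120, 240, "walk", speed = 5, heading = 0),
    sim_segment(240, 300, "absent")
  )
  cfg2 <- sim_config(sched, noise_sd = 1.5, seed = 21)
  sim2 <- simulate_stream(cfg2)
  expect_equal(sim$frames$keypoints[[200]]$x, sim2$frames$keypoints[[200]]$x)
})
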