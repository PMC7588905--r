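test_that("bbox_from_keypoints matches the brute-force min/max oracle", {
  # degenerate single point
  kp <- keypoints("nose", 5, 7, 0.9)
  b <- bbox_from_keypoints(kp)
  expect_identical(c(b$x_min, b$x_max, b$y_min, b$y_max), c(5, 5, 7, 7))
  expect_identical(bbox_width(b), 0)
  expect_identical(bbox_height(b), 0)

  # worked example {(3,4), (7,1), (5,9)}
  kp <- keypoints(c("nose", "leftEye", "rightEye"),
    x = c(3, 7, 5), y = c(4, 1, 9), score = 0.9
  )
  b <- bbox_from_keypoints(kp)
  expect_identical(c(b$x_min, b$x_max, b$y_min, b$y_max), c(3, 7, 1, 9))

  # score filtering drops the low-confidence point
  kp <- keypoints(c("nose", "leftEye"), x = c(3, 7), y = c(4, 1), score = c(0.9, 0.1))
  b <- bbox_from_keypoints(kp, min_kp_score = 0.5)
  expect_identical(c(b$x_min, b$x_max, b$y_min, b$y_max), c(3, 3, 4, 4))
  expect_error(bbox_from_keypoints(kp, min_kp_score = 0.95), "empty pose")

  # property: equality with an independent scan on random sets
  withr::local_seed(11)
  for (i in 1:200) {
    kp <- random_kp()
    thr <- sample(c(0, runif(1, 0, 0.8)), 1)
    if (!any(kp$score >= thr)) next
    b <- bbox_from_keypoints(kp, thr)
    expect_identical(
      c(x_min = b$x_min, x_max = b$x_max, y_min = b$y_min, y_max = b$y_max),
      oracle_bbox(kp, thr)
    )
  }
})

test_that("delta_metrics reproduces the closed-form examples", {
  a <- bbox(0, 10, 0, 20)
  expect_identical(
    delta_metrics(a, a),
    c(d_height = 0, d_width = 0, d_distance = 0)
  )
  # pure translation by (3, 4): a 3-4-5 right triangle
  b <- bbox(3, 13, 4, 24)
  expect_equal(delta_metrics(a, b), c(d_height = 0, d_width = 0, d_distance = 5))
  # mixed change: heights 20 -> 15, widths 10 -> 14, centers (5,10) -> (7,7.5)
  cc <- bbox(0, 14, 0, 15)
  expect_equal(
    delta_metrics(a, cc),
    c(d_height = 5, d_width = 4, d_distance = sqrt(2^2 + 2.5^2)),
    tolerance = 1e-12
  )
})

test_that("delta_metrics is symmetric and center distances obey the triangle inequality", {
  withr::local_seed(7)
  rand_box <- function() {
    x <- sort(runif(2, 0, 320))
    y <- sort(runif(2, 0, 240))
    bbox(x[1], x[2], y[1], y[2])
  }
  for (i in 1:100) {
    a <- rand_box()
    b <- rand_box()
    cc <- rand_box()
    expect_identical(delta_metrics(a, b), delta_metrics(b, a))
    dab <- delta_metrics(a, b)[["d_distance"]]
    dbc <- delta_metrics(b, cc)[["d_distance"]]
    dac <- delta_metrics(a, cc)[["d_distance"]]
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("compute_deltas applies score threshold, gap limit and pairing rules", {
  # fewer than two frames -> nothing
  expect_identical(nrow(compute_deltas(make_stream(ts = 5))), 0L)

  # two identical frames 1 s apart -> a single zero record
  d <- compute_deltas(make_stream(ts = c(0, 1)))
  expect_identical(nrow(d), 1L)
  expect_identical(unname(as_delta_matrix(d)[1, ]), c(0, 0, 0))
  expect_identical(d$gap, 1)

  # trace fixture: middle frame fails the 0.5 threshold, survivors pair at gap 2
  d <- compute_deltas(filter_trace_stream(), filter_policy(max_gap = 2))
  expect_identical(nrow(d), 1L)
  expect_identical(d$gap, 2)
  expect_identical(d$timestamp, 2)

  # tightening max_gap to 1 suppresses the pair
  d <- compute_deltas(filter_trace_stream(), filter_policy(max_gap = 1))
  expect_identical(nrow(d), 0L)

  # fully valid 1 s stream of n frames -> exactly n - 1 records
  n <- 50L
  d <- compute_deltas(make_stream(seq_len(n), dx = seq_len(n)))
  expect_identical(nrow(d), n - 1L)
})

test_that("multi-person frames are dropped only in exclude mode", {
  s <- make_stream(ts = 0:3, persons = c(1L, 2L, 1L, 1L))
  keep <- compute_deltas(s, filter_policy(multi_person = "keep"))
  excl <- compute_deltas(s, filter_policy(multi_person = "exclude"))
  expect_identical(nrow(keep), 3L)
  # t=1 dropped: pairs (0,2) at gap 2 and (2,3) at gap 1
  expect_identical(nrow(excl), 2L)
  expect_identical(excl$gap, c(2, 1))
})

test_that("raising the score threshold never increases the record count", {
  withr::local_seed(23)
  for (rep in 1:20) {
    n <- 40
    s <- make_stream(seq_len(n),
      scores = runif(n),
      dx = cumsum(runif(n, -3, 3))
    )
    counts <- vapply(
      c(0, 0.25, 0.5, 0.75, 0.9),
      function(thr) nrow(compute_deltas(s, filter_policy(score_threshold = thr))),
      integer(1)
    )
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("label_dominant follows the channel mapping and tie priority", {
  rec <- tibble::tibble(
    d_height = c(10, 0, 5, 2, 2),
    d_width = c(1, 0, 5, 9, 2),
    d_distance = c(1, 0, 5, 2, 2)
  )
  lab <- label_dominant(rec)
  expect_identical(
    as.character(lab),
    c(
      "pose_conversion", "none", "positional_change",
      "body_movement", "positional_change"
    )
  )
  # remapping swaps the parameter, tie priority stays on parameters
  swapped <- c(
    d_height = "positional_change", d_width = "body_movement",
    d_distance = "pose_conversion"
  )
  lab2 <- label_dominant(rec, channel_map = swapped)
  expect_identical(as.character(lab2)[1], "positional_change")
  expect_identical(as.character(lab2)[3], "positional_change") # tie: d_height wins now
  expect_error(
    label_dominant(rec, channel_map = c(d_height = "pose_conversion")),
    "bijection"
  )
})
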