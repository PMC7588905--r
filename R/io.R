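#' Read a pose stream from NDJSON
#'
#' Parses a newline-delimited JSON file holding one pose frame per line in
#' the PoseNet-style dialect
#' `{"timestamp": t, "persons": p, "score": s,
#'   "keypoints": [{"part": "...", "score": s, "position": {"x": x, "y": y}}, ...]}`.
#' Every frame is validated against the stream invariants; a frame that
#' fails validation is rejected with its line number, and out-of-order or
#' duplicated timestamps raise an error rather than being silently sorted.
#'
#' @param path Path to an NDJSON file. An empty file yields an empty stream.
#' @return A [pose_stream()] tibble ordered by timestamp.
#' @export
read_pose_stream <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) {
    return(pose_stream())
  }
  timestamp <- double(n)
  score <- double(n)
  persons <- integer(n)
  kps <- vector("list", n)
  for (i in seq_len(n)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        stop("line ", i, ": malformed JSON: ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    frame <- tryCatch(
      parse_frame(obj),
      error = function(e) {
        stop("line ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    timestamp[i] <- frame$timestamp
    score[i] <- frame$score
    persons[i] <- frame$persons
    kps[[i]] <- frame$keypoints
  }
  out <- new_pose_stream(timestamp, score, persons, kps)
  validate_pose_stream(out)
  out
}

parse_frame <- function(obj) {
  for (f in c("timestamp", "persons", "score", "keypoints")) {
    if (is.null(obj[[f]])) stop("missing field '", f, "'")
  }
  kp_list <- obj$keypoints
  m <- length(kp_list)
  if (m > 0) {
    part <- character(m)
    x <- double(m)
    y <- double(m)
    ks <- double(m)
    for (j in seq_len(m)) {
      k <- kp_list[[j]]
      if (is.null(k$part) || is.null(k$position$x) || is.null(k$position$y)) {
        stop("keypoint ", j, " lacks part/position fields")
      }
      part[j] <- k$part
      x[j] <- as.double(k$position$x)
      y[j] <- as.double(k$position$y)
      ks[j] <- if (is.null(k$score)) 1 else as.double(k$score)
    }
    kp <- new_tbl(part = part, x = x, y = y, score = ks)
    validate_keypoints(kp)
  } else {
    kp <- empty_keypoints()
  }
  p <- as.integer(obj$persons)
  if (p == 0) stop("persons = 0 frames are never serialized")
  list(
    timestamp = as.double(obj$timestamp),
    score = as.double(obj$score),
    persons = p,
    keypoints = kp
  )
}

empty_keypoints <- function() {
  new_tbl(part = character(), x = double(), y = double(), score = double())
}

#' Write a pose stream to NDJSON
#'
#' Serializes one frame per line in the dialect read by
#' [read_pose_stream()]. Doubles are written with 17 significant digits so
#' that `read_pose_stream(write_pose_stream(s))` reproduces `s` field-exactly.
#' Frames with `persons == 0` are rejected: an absent person produces no
#' stored frame, so such frames exist only transiently in memory.
#'
#' @param stream A valid [pose_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose_stream <- function(stream, path) {
  validate_pose_stream(stream)
  if (any(stream$persons == 0)) {
    stop("persons = 0 frames are transient and are never serialized",
      call. = FALSE
    )
  }
  n <- nrow(stream)
  lines <- character(n)
  for (i in seq_len(n)) {
    kp <- stream$keypoints[[i]]
    kp_objs <- lapply(seq_len(nrow(kp)), function(j) {
      list(
        part = kp$part[j],
        score = kp$score[j],
        position = list(x = kp$x[j], y = kp$y[j])
      )
    })
    lines[i] <- jsonlite::toJSON(
      list(
        timestamp = stream$timestamp[i],
        persons = stream$persons[i],
        score = stream$score[i],
        keypoints = kp_objs
      ),
      auto_unbox = TRUE, digits = I(17)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read reference bounding-box extents
#'
#' Loads a reference keypoint set for the agreement protocol. Two formats
#' are accepted:
#' * CSV with header `image_id,x_min,x_max,y_min,y_max` — extents taken
#'   verbatim;
#' * a JSON array of records, each with an `image_id` and either the four
#'   extent fields or a `keypoints` list (`part`/`position` objects as in the
#'   NDJSON dialect), in which case the extent is computed with
#'   [bbox_from_keypoints()].
#'
#' @param path Path to the CSV or JSON file.
#' @param format `"auto"` (by file extension), `"csv"` or `"json"`.
#' @return A tibble with columns `image_id`, `x_min`, `x_max`, `y_min`,
#'   `y_max`; empty input yields an empty tibble.
#' @export
read_references <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  refs <- if (format == "csv") read_references_csv(path) else read_references_json(path)
  bad <- refs$x_min > refs$x_max | refs$y_min > refs$y_max
  if (any(bad)) {
    stop("malformed extent for image_id ", refs$image_id[which(bad)[1]],
      " (min exceeds max)",
      call. = FALSE
    )
  }
  refs
}

read_references_csv <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first))) {
    return(empty_references())
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x_min", "x_max", "y_min", "y_max")
  if (!all(need %in% names(df))) {
    stop("reference CSV must have header ", paste(need, collapse = ","),
      call. = FALSE
    )
  }
  df <- df[need]
  df$image_id <- as.character(df$image_id)
  df[-1] <- lapply(df[-1], as.double)
  tibble::as_tibble(df)
}

read_references_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0) {
    return(empty_references())
  }
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$image_id)) {
      stop("reference record ", i, ": missing image_id", call. = FALSE)
    }
    has_extent <- !is.null(r$x_min) && !is.null(r$x_max) &&
      !is.null(r$y_min) && !is.null(r$y_max)
    if (has_extent) {
      ext <- c(
        x_min = as.double(r$x_min), x_max = as.double(r$x_max),
        y_min = as.double(r$y_min), y_max = as.double(r$y_max)
      )
    } else if (!is.null(r$keypoints) && length(r$keypoints) > 0) {
      m <- length(r$keypoints)
      x <- double(m)
      y <- double(m)
      for (j in seq_len(m)) {
        p <- r$keypoints[[j]]$position
        if (is.null(p$x) || is.null(p$y)) {
          stop("reference record ", i, ": keypoint ", j, " lacks position",
            call. = FALSE
          )
        }
        x[j] <- as.double(p$x)
        y[j] <- as.double(p$y)
      }
      b <- bbox_from_keypoints(new_tbl(
        part = rep(NA_character_, m), x = x, y = y, score = rep(1, m)
      ))
      ext <- c(
        x_min = b$x_min, x_max = b$x_max,
        y_min = b$y_min, y_max = b$y_max
      )
    } else {
      stop("reference record ", i, " (image_id ", r$image_id,
        "): needs either keypoints or the four extent values",
        call. = FALSE
      )
    }
    tibble::tibble(
      image_id = as.character(r$image_id),
      x_min = ext[["x_min"]], x_max = ext[["x_max"]],
      y_min = ext[["y_min"]], y_max = ext[["y_max"]]
    )
  })
  dplyr::bind_rows(rows)
}

empty_references <- function() {
  tibble::tibble(
    image_id = character(), x_min = double(), x_max = double(),
    y_min = double(), y_max = double()
  )
}

#' Write delta records to CSV
#'
#' @param deltas A delta-record tibble from [compute_deltas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deltas_csv <- function(deltas, path) {
  utils::write.csv(
    deltas[c("timestamp", "d_height", "d_width", "d_distance", "gap")],
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Read delta records from CSV
#'
#' @param path Path to a CSV written by [write_deltas_csv()].
#' @return A delta-record tibble.
#' @export
read_deltas_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "d_height", "d_width", "d_distance", "gap")
  if (!all(need %in% names(df))) {
    stop("delta CSV must have header ", paste(need, collapse = ","),
      call. = FALSE
    )
  }
  df <- df[need]
  df[] <- lapply(df, as.double)
  tibble::as_tibble(df)
}
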