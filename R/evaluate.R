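#' Difference values between a predicted and a reference box
#'
#' Applies the bounding-box change formulas across sources for one image:
#' the difference value K per channel is `|height(pred) - height(ref)|`,
#' `|width(pred) - width(ref)|`, and the Euclidean distance between the two
#' box centers. Identical to [delta_metrics()] by construction — the
#' agreement protocol reuses the monitoring algorithm unchanged.
#'
#' @param pred,ref Well-formed [bbox()] objects for the same image.
#' @return Named numeric `c(k_height, k_width, k_distance)`, all `>= 0`.
#' @export
#' @examples
#' difference_triple(bbox(0, 12, 0, 30), bbox(0, 10, 0, 20))
difference_triple <- function(pred, ref) {
  d <- delta_metrics(ref, pred)
  c(k_height = d[["d_height"]], k_width = d[["d_width"]], k_distance = d[["d_distance"]])
}

#' Predicted-versus-reference agreement triples
#'
#' Joins two extent tables by `image_id` and computes the difference
#' triple for every image. Any id present in one table but not the other
#' is an error — silent dropping would bias the percentages.
#'
#' The default `mode = "paired"` compares the predicted and reference box
#' of the *same* image. `mode = "sequential"` instead treats each source as
#' an ordered sequence, applies the change metrics to consecutive image
#' pairs within each source, and reports per channel the absolute
#' difference of the two sources' pair metrics (an alternative reading of
#' the protocol, kept for completeness).
#'
#' @param pred,ref Extent tables as returned by [read_references()].
#' @param mode `"paired"` (default) or `"sequential"`.
#' @return A tibble with columns `image_id`, `k_height`, `k_width`,
#'   `k_distance`.
#' @export
evaluate_agreement <- function(pred, ref, mode = c("paired", "sequential")) {
  mode <- match.arg(mode)
  missing_in_ref <- setdiff(pred$image_id, ref$image_id)
  missing_in_pred <- setdiff(ref$image_id, pred$image_id)
  if (length(missing_in_ref) > 0 || length(missing_in_pred) > 0) {
    stop(
      "unmatched image_id(s): ",
      paste(utils::head(c(missing_in_ref, missing_in_pred), 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(pred) == 0) {
    return(new_tbl(
      image_id = character(), k_height = double(), k_width = double(),
      k_distance = double()
    ))
  }
  ref <- ref[match(pred$image_id, ref$image_id), , drop = FALSE]
  geom <- function(tb) {
    list(
      w = tb$x_max - tb$x_min,
      h = tb$y_max - tb$y_min,
      cx = (tb$x_min + tb$x_max) / 2,
      cy = (tb$y_min + tb$y_max) / 2
    )
  }
  p <- geom(pred)
  r <- geom(ref)
  if (mode == "paired") {
    return(new_tbl(
      image_id = as.character(pred$image_id),
      k_height = abs(p$h - r$h),
      k_width = abs(p$w - r$w),
      k_distance = sqrt((p$cx - r$cx)^2 + (p$cy - r$cy)^2)
    ))
  }
  if (nrow(pred) < 2) {
    stop("sequential mode needs at least two images", call. = FALSE)
  }
  pair_metrics <- function(g) {
    i2 <- seq(2, length(g$w))
    i1 <- i2 - 1
    list(
      dh = abs(g$h[i2] - g$h[i1]),
      dw = abs(g$w[i2] - g$w[i1]),
      dd = sqrt((g$cx[i2] - g$cx[i1])^2 + (g$cy[i2] - g$cy[i1])^2)
    )
  }
  pm <- pair_metrics(p)
  rm_ <- pair_metrics(r)
  new_tbl(
    image_id = as.character(pred$image_id[-1]),
    k_height = abs(pm$dh - rm_$dh),
    k_width = abs(pm$dw - rm_$dw),
    k_distance = abs(pm$dd - rm_$dd)
  )
}

#' Bin difference values into agreement percentages
#'
#' Assigns every image's difference value K, per channel, to one of three
#' ranges — `K <= e1`, `e1 < K <= e2`, `K > e2` (upper edges closed) — and
#' reports the percentage of total images in each range. Default edges are
#' 10 and 30 pixels.
#'
#' @param triples Output of [evaluate_agreement()] (columns `k_height`,
#'   `k_width`, `k_distance`).
#' @param edges Numeric length-2, `edges[1] < edges[2]`.
#' @return A tibble of class `bin_report` with columns `channel`, `bin`,
#'   `count`, `percentage`, plus attributes `n_images` and `edges`.
#'   Percentages are exact; the print method rounds to two decimals.
#' @export
bin_report <- function(triples, edges = c(10, 30)) {
  if (length(edges) != 2 || edges[1] >= edges[2]) {
    stop("edges must be two increasing values", call. = FALSE)
  }
  n <- nrow(triples)
  if (n == 0) {
    stop("bin_report needs at least one triple (percentages undefined)",
      call. = FALSE
    )
  }
  bin_labels <- c(
    sprintf("K <= %g", edges[1]),
    sprintf("%g < K <= %g", edges[1], edges[2]),
    sprintf("K > %g", edges[2])
  )
  chans <- c(k_height = "d_height", k_width = "d_width", k_distance = "d_distance")
  rows <- lapply(names(chans), function(col) {
    k <- triples[[col]]
    idx <- ifelse(k <= edges[1], 1L, ifelse(k <= edges[2], 2L, 3L))
    counts <- tabulate(idx, nbins = 3L)
    tibble::tibble(
      channel = chans[[col]],
      bin = bin_labels,
      count = counts,
      percentage = 100 * counts / n
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_images") <- n
  attr(out, "edges") <- edges
  class(out) <- c("bin_report", class(out))
  out
}

#' @export
print.bin_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(x)[c("channel", "bin", "percentage")],
    names_from = "channel", values_from = "percentage"
  )
  cat(
    "Agreement by difference range (", attr(x, "n_images"),
    " images)\n\n",
    sep = ""
  )
  hdr <- sprintf(
    "%-14s %10s %10s %10s", "Difference (K)",
    "dHeight", "dWidth", "dDistance"
  )
  cat(hdr, "\n")
  for (i in seq_len(nrow(wide))) {
    cat(sprintf(
      "%-14s %9.2f%% %9.2f%% %9.2f%%\n",
      wide$bin[i], wide$d_height[i], wide$d_width[i], wide$d_distance[i]
    ))
  }
  invisible(x)
}

#' Write a bin report to CSV
#'
#' @param report A [bin_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_report_csv <- function(report, path) {
  df <- tibble::as_tibble(report)
  df$percentage <- round(df$percentage, 2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
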