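# Anchor generation and IoU-based label assignment, the first stage of a
# region-proposal pipeline.  Anchors are tiled densely over a feature grid;
# each grid cell maps to an image location at the cell center times the
# stride, and carries one anchor per aspect ratio at constant area.

#' Generate a dense anchor grid
#'
#' Tiles `rows * cols * length(ratios)` anchors over a feature grid.  Grid
#' cell `(i, j)` (0-based, row-major) maps to the image point
#' `((j + 0.5) * stride, (i + 0.5) * stride)`; each anchor is centered
#' there.  For aspect ratio `r` the anchor has `w * h = base_size^2` and
#' `h / w = r` (area-preserving aspect ratios, the usual region-proposal
#' convention for the `(0.5, 1, 2)` triple).  Anchors extending beyond the
#' image are kept as-is unless `clip` is given.
#'
#' @param grid_shape integer `(rows, cols)` of the feature grid.
#' @param stride pixels per grid cell (> 0).
#' @param base_size anchor side length in pixels at ratio 1 (> 0).
#' @param ratios positive aspect ratios `h / w`; default `c(0.5, 1, 2)`.
#' @param image_id identifier stamped on the anchor boxes.
#' @param slice_index slice stamped on the anchor boxes.
#' @param clip optional `(height, width)` of the image in pixels; when
#'   given, anchor boxes are clipped to `[0, width) x [0, height)`.
#' @return an object of class `anchor_set`: a list with elements `boxes`
#'   (box data frame with extra columns `cell_row`, `cell_col`, `ratio`),
#'   `grid_shape`, `stride`, `base_size`, `ratios`.  Anchor order is
#'   deterministic: row-major over cells, then ratio order within a cell.
#' @examples
#' a <- generate_anchors(c(2, 3), stride = 16, base_size = 16)
#' nrow(a$boxes)  # 18
#' @export
generate_anchors <- function(grid_shape, stride, base_size,
                             ratios = c(0.5, 1, 2),
                             image_id = "img", slice_index = 0L,
                             clip = NULL) {
  if (length(grid_shape) != 2 || any(grid_shape < 1)) {
    stop_invalid("grid_shape must be (rows, cols) with positive entries")
  }
  if (length(ratios) == 0) stop_invalid("ratios must be nonempty")
  if (any(ratios <= 0)) stop_invalid("all ratios must be positive")
  if (stride <= 0 || base_size <= 0) {
    stop_invalid("stride and base_size must be positive")
  }
  rows <- as.integer(grid_shape[1])
  cols <- as.integer(grid_shape[2])
  nr <- length(ratios)
  # Row-major cell order, ratios innermost.
  cell_row <- rep(rep(seq_len(rows) - 1L, each = cols), each = nr)
  cell_col <- rep(rep(seq_len(cols) - 1L, times = rows), each = nr)
  ratio <- rep(ratios, times = rows * cols)
  cx <- (cell_col + 0.5) * stride
  cy <- (cell_row + 0.5) * stride
  w <- base_size / sqrt(ratio)
  h <- base_size * sqrt(ratio)
  x <- cx - w / 2
  y <- cy - h / 2
  if (!is.null(clip)) {
    x1 <- clamp(x + w, 0, clip[2]); y1 <- clamp(y + h, 0, clip[1])
    x <- clamp(x, 0, clip[2]); y <- clamp(y, 0, clip[1])
    w <- x1 - x; h <- y1 - y
    keep <- w > 0 & h > 0
    x <- x[keep]; y <- y[keep]; w <- w[keep]; h <- h[keep]
    cell_row <- cell_row[keep]; cell_col <- cell_col[keep]; ratio <- ratio[keep]
  }
  df <- data.frame(
    image_id = as.character(image_id), slice_index = as.integer(slice_index),
    x = x, y = y, w = w, h = h,
    cell_row = cell_row, cell_col = cell_col, ratio = ratio,
    stringsAsFactors = FALSE
  )
  structure(
    list(boxes = df, grid_shape = c(rows, cols), stride = stride,
         base_size = base_size, ratios = ratios),
    class = "anchor_set"
  )
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf(
    "Anchor set: %d anchors (%d x %d grid, stride %g, base %g, ratios %s)\n",
    nrow(x$boxes), x$grid_shape[1], x$grid_shape[2], x$stride, x$base_size,
    paste(x$ratios, collapse = ", ")
  ))
  invisible(x)
}

#' Assign ternary anchor labels from an IoU matrix
#'
#' An anchor is labeled positive when its best IoU against any ground-truth
#' box reaches `hi_thresh`, negative when its best IoU is at most
#' `lo_thresh` (or when there are no ground truths at all), and ignored in
#' between.  Ignored anchors contribute to neither loss term downstream.
#'
#' @param ious `n_anchors x n_gt` IoU matrix from [iou_matrix()]; zero
#'   columns means no ground truth and every anchor becomes negative.
#' @param hi_thresh IoU at or above which an anchor is positive.
#' @param lo_thresh IoU at or below which an anchor is negative; must
#'   satisfy `0 <= lo_thresh < hi_thresh <= 1`.
#' @param force_best if `TRUE`, the highest-IoU anchor for each ground
#'   truth is additionally marked positive regardless of threshold (a
#'   common region-proposal extra; off by default).
#' @return an object of class `anchor_labels`: an integer vector with
#'   values `1` (positive), `0` (negative), `NA` (ignored), carrying
#'   attributes `hi_thresh` and `lo_thresh`.
#' @examples
#' m <- matrix(c(0.9, 0.1, 0.5), ncol = 1)
#' assign_labels(m)  # positive, negative, ignored
#' @export
assign_labels <- function(ious, hi_thresh = 0.7, lo_thresh = 0.3,
                          force_best = FALSE) {
  if (!is.matrix(ious)) stop_invalid("ious must be a matrix")
  if (!(lo_thresh >= 0 && lo_thresh < hi_thresh && hi_thresh <= 1)) {
    stop_invalid("thresholds must satisfy 0 <= lo_thresh < hi_thresh <= 1")
  }
  n <- nrow(ious)
  if (ncol(ious) == 0) {
    lab <- rep(0L, n)
  } else {
    mx <- apply(ious, 1, max)
    lab <- rep(NA_integer_, n)
    lab[mx >= hi_thresh] <- 1L
    lab[mx <= lo_thresh] <- 0L
    if (force_best) {
      best <- apply(ious, 2, which.max)
      lab[best] <- 1L
    }
  }
  structure(lab, hi_thresh = hi_thresh, lo_thresh = lo_thresh,
            class = "anchor_labels")
}

#' @export
print.anchor_labels <- function(x, ...) {
  cat(sprintf(
    "Anchor labels: %d positive, %d negative, %d ignored (hi %.2f, lo %.2f)\n",
    sum(x == 1L, na.rm = TRUE), sum(x == 0L, na.rm = TRUE), sum(is.na(x)),
    attr(x, "hi_thresh"), attr(x, "lo_thresh")
  ))
  invisible(x)
}

#' Export anchor labels as the binary vector y
#'
#' Positives map to 1; negatives and ignored anchors map to 0.  Together
#' with [negate_labels()] this realizes the pair of indicator vectors used
#' by the loss: ignored anchors are zero in both and so contribute to
#' neither loss term.
#'
#' @param labels an `anchor_labels` object (or a plain 0/1/NA vector).
#' @return numeric 0/1 vector, one entry per anchor.
#' @export
as_y <- function(labels) {
  y <- as.integer(unclass(labels))
  out <- ifelse(!is.na(y) & y == 1L, 1, 0)
  as.numeric(out)
}

#' Negation of the anchor label vector
#'
#' Applies the 1-minus-label operation over decided anchors: negatives map
#' to 1, positives to 0.  Ignored anchors map to 0, so they are excluded
#' from the negative loss term just as they are from the positive one.
#'
#' @inheritParams as_y
#' @return numeric 0/1 vector `y_neg` with `y_neg[i] = 1 - y[i]` on
#'   non-ignored anchors and 0 at ignored positions.
#' @examples
#' y <- structure(c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 1L), class = "anchor_labels")
#' negate_labels(y)  # 1 1 1 0 0 0 1 0
#' @export
negate_labels <- function(labels) {
  y <- as.integer(unclass(labels))
  out <- ifelse(!is.na(y) & y == 0L, 1, 0)
  as.numeric(out)
}
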