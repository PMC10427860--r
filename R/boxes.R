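# Axis-aligned boxes.  A box is a row of a data frame with columns
# x, y, w, h and optionally image_id and slice_index.  Coordinates are
# 0-based pixels with the upper-left-corner convention; a box occupies the
# half-open region [x, x + w) x [y, y + h), so area is w * h exactly.

BOX_COLS <- c("x", "y", "w", "h")

#' Construct a box data frame
#'
#' Boxes follow the `(x, y, w, h)` upper-left-corner convention in 0-based
#' pixel coordinates; each box occupies the half-open rectangle
#' `[x, x + w) x [y, y + h)` so its area is exactly `w * h`.
#'
#' @param x,y numeric vectors, upper-left corner coordinates (0-based pixels).
#' @param w,h numeric vectors of widths and heights in pixels; must be `> 0`.
#' @param image_id character or numeric identifier(s), recycled.
#' @param slice_index integer slice indices (0-based), recycled.
#' @return a `data.frame` with columns `image_id`, `slice_index`, `x`, `y`,
#'   `w`, `h`; `empty_boxes()` returns the zero-row frame.
#' @examples
#' boxes(x = 0, y = 0, w = 16, h = 16)
#' @export
boxes <- function(x, y, w, h, image_id = "img", slice_index = 0L) {
  n <- length(x)
  if (length(y) != n || length(w) != n || length(h) != n) {
    stop_invalid("x, y, w, h must have equal length")
  }
  df <- data.frame(
    image_id = rep_len(as.character(image_id), n),
    slice_index = rep_len(as.integer(slice_index), n),
    x = as.numeric(x), y = as.numeric(y),
    w = as.numeric(w), h = as.numeric(h),
    stringsAsFactors = FALSE
  )
  validate_boxes(df)
  df
}

validate_boxes <- function(df, what = "boxes") {
  if (!is.data.frame(df) || !all(BOX_COLS %in% names(df))) {
    stop_invalid(what, " must be a data frame with columns x, y, w, h")
  }
  if (nrow(df) > 0 && (any(df$w <= 0) || any(df$h <= 0))) {
    stop_invalid(what, ": box widths and heights must be positive")
  }
  invisible(df)
}

#' @rdname boxes
#' @export
empty_boxes <- function() {
  data.frame(
    image_id = character(0), slice_index = integer(0),
    x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Intersection over union of two boxes
#'
#' Areas are continuous (half-open boxes), so touching boxes have zero
#' intersection.  The result is symmetric, lies in `[0, 1]`, equals 1 for
#' identical boxes and 0 for disjoint ones.
#'
#' @param a,b single boxes: one-row data frames (or lists) with `x`, `y`,
#'   `w`, `h`.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(boxes(0, 0, 2, 2), boxes(1, 1, 2, 2))  # 1/7
#' @export
iou <- function(a, b) {
  drop(iou_matrix(as.data.frame(a)[1, , drop = FALSE],
                  as.data.frame(b)[1, , drop = FALSE]))
}

#' IoU matrix between anchors and ground-truth boxes
#'
#' @param anchors box data frame (or an `anchor_set`) with `n` rows.
#' @param gts box data frame with `m` rows; may be empty.
#' @return an `n x m` numeric matrix; entry `(i, j)` is
#'   `iou(anchors[i, ], gts[j, ])`.  With zero ground truths an `n x 0`
#'   matrix is returned.
#' @export
iou_matrix <- function(anchors, gts) {
  if (inherits(anchors, "anchor_set")) anchors <- anchors$boxes
  validate_boxes(anchors, "anchors")
  if (nrow(anchors) == 0) stop_invalid("anchors must be nonempty")
  if (is.null(gts) || nrow(gts) == 0) {
    return(matrix(numeric(0), nrow = nrow(anchors), ncol = 0))
  }
  validate_boxes(gts, "gts")
  ax0 <- anchors$x; ay0 <- anchors$y
  ax1 <- ax0 + anchors$w; ay1 <- ay0 + anchors$h
  bx0 <- gts$x; by0 <- gts$y
  bx1 <- bx0 + gts$w; by1 <- by0 + gts$h
  iw <- pmax(0, outer(ax1, bx1, pmin) - outer(ax0, bx0, pmax))
  ih <- pmax(0, outer(ay1, by1, pmin) - outer(ay0, by0, pmax))
  inter <- iw * ih
  areas_a <- anchors$w * anchors$h
  areas_b <- gts$w * gts$h
  union <- outer(areas_a, areas_b, `+`) - inter
  inter / union
}

#' Read and write box annotation files
#'
#' The CSV dialect has header `image_id,slice_index,x,y,w,h` (0-based
#' pixels), optionally followed by extra columns such as `hidden` or
#' `score`; the JSON dialect is an array of objects with the same fields.
#' Reading back a written file reproduces the boxes bit-exactly.
#'
#' @param df box data frame.
#' @param path file path.
#' @return `read_boxes_csv()` / `read_boxes_json()` return the box data
#'   frame; writers return `path` invisibly.
#' @export
write_boxes_csv <- function(df, path) {
  validate_boxes(df)
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      # 17 significant digits make the decimal text round-trip to the same
      # double, so read_boxes_csv(write_boxes_csv(df)) is bit-exact.
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_boxes_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("box file not found: ", path)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop_invalid("malformed box CSV ", path, ": ", conditionMessage(e))
  )
  missing <- setdiff(BOX_COLS, names(df))
  if (length(missing)) {
    stop_invalid("box CSV ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(df$w <= 0 | df$h <= 0)
  if (length(bad)) {
    stop_invalid("box CSV ", path, ", line ", bad[1] + 1L,
                 ": nonpositive width or height")
  }
  if ("image_id" %in% names(df)) df$image_id <- as.character(df$image_id)
  df
}

#' @rdname write_boxes_csv
#' @export
write_boxes_json <- function(df, path) {
  validate_boxes(df)
  # I(17): 17 significant digits, enough for doubles to round-trip exactly.
  jsonlite::write_json(df, path, dataframe = "rows", digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_boxes_json <- function(path) {
  if (!file.exists(path)) stop_invalid("box file not found: ", path)
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0) return(empty_boxes())
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(BOX_COLS, names(df))
  if (length(missing)) {
    stop_invalid("box JSON ", path, " lacks field(s): ", paste(missing, collapse = ", "))
  }
  if ("image_id" %in% names(df)) df$image_id <- as.character(df$image_id)
  validate_boxes(df)
  df
}
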