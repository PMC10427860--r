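# Independent scalar oracles used across the suite.  These are written as
# plain loops over box pairs / loss terms, independent of the vectorized
# package implementations they check.

# Scalar IoU of two (x, y, w, h) boxes.
oracle_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Brute-force ternary labels: per-anchor max IoU, then threshold compare.
oracle_labels <- function(anchor_df, gt_df, hi, lo) {
  n <- nrow(anchor_df)
  out <- integer(n)
  for (i in seq_len(n)) {
    best <- 0
    if (nrow(gt_df) > 0) {
      for (j in seq_len(nrow(gt_df))) {
        v <- oracle_iou(as.numeric(anchor_df[i, c("x", "y", "w", "h")]),
                        as.numeric(gt_df[j, c("x", "y", "w", "h")]))
        if (v > best) best <- v
      }
    }
    out[i] <- if (nrow(gt_df) == 0) 0L
      else if (best >= hi) 1L
      else if (best <= lo) 0L
      else NA_integer_
  }
  out
}

# Scalar-loop binary cross-entropy with clipping, split into the positive
# and negative parts.
oracle_cross_entropy <- function(y, p, eps = 1e-7) {
  lp <- 0; ln <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    lp <- lp - y[i] * log(pi)
    ln <- ln - (1 - y[i]) * log(1 - pi)
  }
  list(pos = lp, neg = ln, total = lp + ln)
}

# Random axis-aligned boxes inside a canvas.
random_boxes <- function(n, canvas = 64, min_side = 2, max_side = 20) {
  w <- runif(n, min_side, max_side)
  h <- runif(n, min_side, max_side)
  boxes(x = runif(n, 0, canvas - w), y = runif(n, 0, canvas - h),
        w = w, h = h)
}
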