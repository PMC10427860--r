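test_that("a single-cell grid at ratio 1 yields the identity anchor", {
  a <- generate_anchors(c(1, 1), stride = 16, base_size = 16, ratios = 1.0)
  expect_equal(nrow(a$boxes), 1L)
  expect_equal(as.numeric(a$boxes[1, c("x", "y", "w", "h")]), c(0, 0, 16, 16))
})

test_that("anchor count and order follow row-major cells then ratios", {
  a <- generate_anchors(c(2, 3), stride = 16, base_size = 16,
                        ratios = c(0.5, 1, 2))
  expect_equal(nrow(a$boxes), 2 * 3 * 3)
  # First three anchors share cell (0, 0) across the three ratios.
  expect_equal(a$boxes$cell_row[1:3], rep(0L, 3))
  expect_equal(a$boxes$cell_col[1:3], rep(0L, 3))
  expect_equal(a$boxes$ratio[1:3], c(0.5, 1, 2))
  # Fourth anchor advances to cell (0, 1); cells fill a row before the next.
  expect_equal(a$boxes$cell_col[4], 1L)
  expect_equal(a$boxes$cell_row[10], 1L)
})

test_that("aspect ratios preserve anchor area", {
  a <- generate_anchors(c(1, 1), stride = 16, base_size = 16, ratios = 0.5)
  b <- a$boxes[1, ]
  expect_equal(b$w, 16 * sqrt(2), tolerance = 1e-12)
  expect_equal(b$h, 16 / sqrt(2), tolerance = 1e-12)
  expect_equal(b$w * b$h, 256, tolerance = 1e-9)
  expect_equal(b$h / b$w, 0.5, tolerance = 1e-12)
  # Anchors are centered on the mapped cell center.
  expect_equal(b$x + b$w / 2, 8)
  expect_equal(b$y + b$h / 2, 8)
})

test_that("invalid anchor-grid arguments are rejected", {
  expect_error(generate_anchors(c(1, 1), 16, 16, numeric(0)), "ratios")
  expect_error(generate_anchors(c(1, 1), 16, 16, c(1, -2)), "positive")
  expect_error(generate_anchors(c(1, 1), 0, 16, 1), "positive")
  expect_error(generate_anchors(c(1, 1), 16, -1, 1), "positive")
})

test_that("iou matches hand-computed and oracle values", {
  expect_equal(iou(boxes(0, 0, 2, 2), boxes(0, 0, 2, 2)), 1.0)
  expect_equal(iou(boxes(0, 0, 2, 2), boxes(10, 10, 2, 2)), 0.0)
  expect_equal(iou(boxes(0, 0, 2, 2), boxes(1, 1, 2, 2)), 1 / 7)
  # Touching half-open boxes do not intersect.
  expect_equal(iou(boxes(0, 0, 2, 2), boxes(2, 0, 2, 2)), 0.0)
})

test_that("iou is symmetric, bounded, and 1 on identity", {
  set.seed(42)
  a <- random_boxes(50)
  b <- random_boxes(50)
  for (i in seq_len(50)) {
    v1 <- iou(a[i, ], b[i, ])
    v2 <- iou(b[i, ], a[i, ])
    expect_identical(v1, v2)
    expect_gte(v1, 0)
    expect_lte(v1, 1)
    expect_equal(iou(a[i, ], a[i, ]), 1.0)
  }
})

test_that("iou_matrix agrees elementwise with scalar calls", {
  set.seed(7)
  a <- random_boxes(5)
  g <- random_boxes(3)
  m <- iou_matrix(a, g)
  expect_equal(dim(m), c(5L, 3L))
  for (i in 1:5) for (j in 1:3) {
    expect_equal(m[i, j],
                 oracle_iou(as.numeric(a[i, c("x", "y", "w", "h")]),
                            as.numeric(g[j, c("x", "y", "w", "h")])),
                 tolerance = 1e-12)
  }
})

test_that("iou_matrix with zero ground truths gives an n x 0 matrix and all negatives", {
  a <- random_boxes(4)
  m <- iou_matrix(a, empty_boxes())
  expect_equal(dim(m), c(4L, 0L))
  lab <- assign_labels(m)
  expect_true(all(unclass(lab) == 0L))
})

test_that("assign_labels applies the 0.7 / 0.3 thresholds", {
  m <- matrix(c(0.9, 0.1, 0.5), ncol = 1)
  lab <- assign_labels(m, hi_thresh = 0.7, lo_thresh = 0.3)
  expect_identical(as.integer(unclass(lab)), c(1L, 0L, NA_integer_))
  expect_true(all(unclass(assign_labels(matrix(0, 5, 2))) == 0L))
  expect_error(assign_labels(m, hi_thresh = 0.3, lo_thresh = 0.7), "thresholds")
})

test_that("assign_labels agrees with a brute-force oracle on random layouts", {
  set.seed(11)
  for (rep in seq_len(25)) {
    a <- random_boxes(40)
    g <- random_boxes(sample(0:3, 1))
    lab <- assign_labels(iou_matrix(a, g))
    expect_identical(as.integer(unclass(lab)), oracle_labels(a, g, 0.7, 0.3))
  }
})

test_that("label conservation and threshold monotonicity hold", {
  set.seed(13)
  for (rep in seq_len(20)) {
    a <- random_boxes(60)
    g <- random_boxes(3)
    m <- iou_matrix(a, g)
    lab <- assign_labels(m)
    n_pos <- sum(unclass(lab) == 1L, na.rm = TRUE)
    n_neg <- sum(unclass(lab) == 0L, na.rm = TRUE)
    n_ign <- sum(is.na(unclass(lab)))
    expect_equal(n_pos + n_neg + n_ign, nrow(a))
    # Raising lo_thresh never decreases the negative count.
    lab2 <- assign_labels(m, lo_thresh = 0.5)
    expect_gte(sum(unclass(lab2) == 0L, na.rm = TRUE), n_neg)
    # Raising hi_thresh never increases the positive count.
    lab3 <- assign_labels(m, hi_thresh = 0.9)
    expect_lte(sum(unclass(lab3) == 1L, na.rm = TRUE), n_pos)
  }
})

test_that("force_best marks the best anchor per ground truth positive", {
  m <- matrix(c(0.4, 0.2, 0.1), ncol = 1)
  expect_true(all(is.na(unclass(assign_labels(m))[1])))
  lab <- assign_labels(m, force_best = TRUE)
  expect_identical(unclass(lab)[1], 1L)
})

test_that("negate_labels reproduces the printed y -> y_neg correspondence", {
  y <- structure(c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 1L), class = "anchor_labels")
  expect_equal(as_y(y), c(0, 0, 0, 1, 1, 1, 0, 1))
  expect_equal(negate_labels(y), c(1, 1, 1, 0, 0, 0, 1, 0))
})

test_that("negation maps all-positive to all-zero and zeroes ignored anchors", {
  all_pos <- structure(rep(1L, 5), class = "anchor_labels")
  expect_equal(negate_labels(all_pos), rep(0, 5))
  with_ign <- structure(c(1L, NA, 0L, NA), class = "anchor_labels")
  yn <- negate_labels(with_ign)
  expect_equal(yn, c(0, 0, 1, 0))
  # Ignored anchors contribute to neither loss term: y and y_neg are both 0
  # there, so any probability at those positions is loss-free under the mask.
  y <- as_y(with_ign)
  p <- c(0.9, 0.5, 0.1, 0.5)
  lb <- masked_loss(y, p, lambda_ = 1, mask = yn)
  expect_equal(lb$l_ns, -log(1 - 0.1), tolerance = 1e-12)
})

test_that("anchor clipping truncates boundary anchors to the image", {
  a <- generate_anchors(c(2, 2), stride = 16, base_size = 24,
                        ratios = c(1), clip = c(32, 32))
  b <- a$boxes
  expect_true(all(b$x >= 0 & b$y >= 0))
  expect_true(all(b$x + b$w <= 32 & b$y + b$h <= 32))
})
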