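test_that("greedy matching resolves the basic cases", {
  gt <- boxes(10, 10, 8, 8, image_id = "a")
  hit <- boxes(10, 10, 8, 8, image_id = "a"); hit$score <- 0.9
  m <- match_detections(hit, gt)
  expect_true(m$dets$tp)
  expect_true(m$gt_hit)
  # Two overlapping detections on one lesion: higher score wins, other is FP.
  two <- rbind(hit, hit); two$score <- c(0.6, 0.9)
  m2 <- match_detections(two, gt)
  expect_equal(m2$dets$score, c(0.9, 0.6))
  expect_equal(m2$dets$tp, c(TRUE, FALSE))
  # No ground truth: everything is a false positive.
  m3 <- match_detections(hit, empty_boxes())
  expect_false(any(m3$dets$tp))
})

test_that("a perfect detector reaches sensitivity 1 at FPPI 0", {
  gts <- rbind(boxes(5, 5, 6, 6, image_id = "a"),
               boxes(20, 20, 6, 6, image_id = "b"))
  dets <- gts
  dets$score <- c(0.9, 0.8)
  cv <- froc_curve(dets, gts, n_images = 2)
  s <- sensitivity_at_fppi(cv)
  expect_equal(unname(s), rep(1, 6))
  expect_equal(max(cv$points$sensitivity[cv$points$fppi == 0]), 1)
})

test_that("the two-image worked example traces the expected curve", {
  gts <- rbind(boxes(5, 5, 6, 6, image_id = "a"),
               boxes(20, 20, 6, 6, image_id = "b"))
  tp1 <- gts[1, ]; tp1$score <- 0.9
  fp <- boxes(40, 40, 6, 6, image_id = "a"); fp$score <- 0.8
  tp2 <- gts[2, ]; tp2$score <- 0.7
  dets <- rbind(tp1, fp, tp2)
  cv <- froc_curve(dets, gts, n_images = 2)
  # Threshold sweep: 0.9 -> (fppi 0, sens .5); 0.8 -> (0.5, .5);
  # 0.7 -> (0.5, 1).  The curve keeps the best sensitivity per FPPI.
  s <- sensitivity_at_fppi(cv, c(0.25, 0.5, 1, 2, 4))
  expect_equal(unname(s), c(0.5, 1, 1, 1, 1))
  expect_equal(cv$n_lesions, 2L)
  # Input order does not matter.
  cv2 <- froc_curve(dets[c(3, 1, 2), ], gts, n_images = 2)
  expect_equal(cv2$points, cv$points)
})

test_that("FROC sensitivity is non-decreasing in FPPI and ends at the matchable fraction", {
  set.seed(31)
  gts <- empty_boxes(); dets <- empty_boxes(); dets$score <- numeric(0)
  for (img in paste0("im", 1:6)) {
    g <- random_boxes(2, canvas = 100)
    g$image_id <- img
    gts <- rbind(gts, g)
    d <- random_boxes(8, canvas = 100)
    d$image_id <- img
    d$score <- runif(8)
    # Guarantee a few true hits.
    d[1:2, c("x", "y", "w", "h")] <- g[1:2, c("x", "y", "w", "h")]
    dets <- rbind(dets, d)
  }
  cv <- froc_curve(dets, gts, n_images = 6)
  expect_true(all(diff(cv$points$sensitivity) >= 0))
  expect_true(all(diff(cv$points$fppi) > 0))
  total_tp <- sum(vapply(paste0("im", 1:6), function(img) {
    sum(match_detections(dets[dets$image_id == img, ],
                         gts[gts$image_id == img, ])$dets$tp)
  }, numeric(1)))
  expect_equal(max(cv$points$sensitivity), total_tp / nrow(gts))
})

test_that("step-function read-out uses the largest achieved FPPI below target", {
  cv <- structure(list(points = data.frame(threshold = 0.5, fppi = 1,
                                           sensitivity = 0.8),
                       n_images = 1L, n_lesions = 5L),
                  class = "froc_curve")
  s <- sensitivity_at_fppi(cv, c(0.5, 1, 2))
  expect_equal(unname(s), c(0, 0.8, 0.8))
})

test_that("average sensitivity over the four canonical FPPI points is the mean", {
  expect_equal(average_sensitivity(c(1, 1, 1, 1)), 1)
  expect_equal(average_sensitivity(c(0, 0, 0, 0)), 0)
  # A published row: 60.44 70.60 75.83 85.32 averages to 73.05 (rounded).
  avg <- average_sensitivity(c(0.6044, 0.7060, 0.7583, 0.8532))
  expect_lt(abs(avg - 0.7305), 0.00005 + 1e-12)
  expect_error(average_sensitivity(c(0.5, 0.6)), "four")
})

test_that("froc_curve refuses an empty ground truth", {
  d <- boxes(1, 1, 2, 2); d$score <- 0.5
  expect_error(froc_curve(d, empty_boxes()), "lesion")
})

test_that("froc_report tabulates percent sensitivities and writes files", {
  gts <- boxes(5, 5, 6, 6, image_id = "a")
  dets <- gts; dets$score <- 0.9
  cv <- froc_curve(dets, gts, n_images = 1)
  js <- tempfile(fileext = ".json"); tx <- tempfile(fileext = ".txt")
  row <- froc_report(cv, json_path = js, txt_path = tx)
  expect_equal(unname(unlist(row)), rep(100, 7))
  expect_equal(jsonlite::fromJSON(js)$avg, 100)
  expect_match(readLines(tx)[1], "Avg")
})

test_that("non-maximum suppression keeps the highest-scoring of overlapping boxes", {
  d <- rbind(boxes(0, 0, 10, 10), boxes(1, 1, 10, 10), boxes(30, 30, 10, 10))
  d$score <- c(0.5, 0.9, 0.4)
  kept <- nms(d, iou_thresh = 0.5)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$score, c(0.9, 0.4))
})
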