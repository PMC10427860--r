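# FROC evaluation: sensitivity at fixed false positives per image (FPPI).
# Detections are matched greedily to ground truth in descending score
# order; sweeping the score threshold traces the FROC curve, which is then
# read out at canonical FPPI operating points and averaged over
# FPPI in {0.5, 1, 2, 4}.

#' Greedy detection-to-ground-truth matching
#'
#' Detections are visited in descending score order (ties broken by stable
#' input order).  A detection is a true positive when its best-IoU not-yet
#' -matched ground-truth box reaches `iou_thresh`; otherwise it is a false
#' positive.  Each ground truth is matched at most once, so duplicate
#' detections of the same lesion count as false positives.
#'
#' @param dets data frame of detections: box columns plus `score`.
#' @param gts box data frame of ground truths (may be empty).
#' @param iou_thresh IoU at or above which a detection may claim a ground
#'   truth; default 0.5.
#' @return a list with `dets` (the detections sorted by descending score,
#'   with a logical `tp` column) and `gt_hit` (logical per ground truth).
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  if (nrow(dets) > 0) validate_boxes(dets, "dets")
  if (!"score" %in% names(dets)) stop_invalid("dets must have a score column")
  if (nrow(gts) > 0) validate_boxes(gts, "gts")
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  n_gt <- nrow(gts)
  gt_hit <- rep(FALSE, n_gt)
  tp <- rep(FALSE, nrow(dets))
  if (nrow(dets) > 0 && n_gt > 0) {
    m <- iou_matrix(dets, gts)
    for (i in seq_len(nrow(dets))) {
      open <- which(!gt_hit)
      if (length(open) == 0) break
      j <- open[which.max(m[i, open])]
      if (m[i, j] >= iou_thresh) {
        tp[i] <- TRUE
        gt_hit[j] <- TRUE
      }
    }
  }
  dets$tp <- tp
  rownames(dets) <- NULL
  list(dets = dets, gt_hit = gt_hit)
}

#' FROC curve over a test set
#'
#' Matches detections to the full ground truth per image, then sweeps a
#' global score threshold.  At each threshold the operating point is
#' `fppi = total false positives / n_images` and `sensitivity = matched
#' ground truths / n_lesions`.  When several thresholds share an FPPI
#' value, the best (largest) sensitivity at that FPPI is kept, so the
#' curve is a non-decreasing step function of FPPI.
#'
#' @param dets detections over the whole test set (box columns, `score`,
#'   `image_id`).
#' @param gts full-truth boxes over the whole test set; must be nonempty.
#' @param n_images number of images in the test set; defaults to the
#'   number of distinct `image_id`s in `gts` and `dets` combined (pass it
#'   explicitly when some images have neither lesions nor detections).
#' @param iou_thresh matching threshold, as in [match_detections()].
#' @return an object of class `froc_curve`: a list with `points` (data
#'   frame `threshold`, `fppi`, `sensitivity`), `n_images`, `n_lesions`.
#' @export
froc_curve <- function(dets, gts, n_images = NULL, iou_thresh = 0.5) {
  if (is.null(gts) || nrow(gts) == 0) {
    stop_invalid("FROC needs at least one ground-truth lesion")
  }
  if (is.null(n_images)) {
    n_images <- length(unique(c(as.character(gts$image_id),
                                as.character(dets$image_id))))
  }
  if (n_images < 1) stop_invalid("n_images must be >= 1")
  n_lesions <- nrow(gts)
  matched <- data.frame(score = numeric(0), tp = logical(0))
  for (id in unique(as.character(gts$image_id))) {
    sub_d <- dets[as.character(dets$image_id) == id, , drop = FALSE]
    sub_g <- gts[as.character(gts$image_id) == id, , drop = FALSE]
    if (nrow(sub_d) == 0) next
    mm <- match_detections(sub_d, sub_g, iou_thresh)
    matched <- rbind(matched, data.frame(score = mm$dets$score,
                                         tp = mm$dets$tp))
  }
  # Detections on images without any ground truth are all false positives.
  extra <- dets[!(as.character(dets$image_id) %in%
                    as.character(gts$image_id)), , drop = FALSE]
  if (nrow(extra) > 0) {
    matched <- rbind(matched, data.frame(score = extra$score,
                                         tp = rep(FALSE, nrow(extra))))
  }
  if (nrow(matched) == 0) {
    pts <- data.frame(threshold = Inf, fppi = 0, sensitivity = 0)
  } else {
    ord <- order(-matched$score)
    sc <- matched$score[ord]
    tp <- matched$tp[ord]
    cum_tp <- cumsum(tp)
    cum_fp <- cumsum(!tp)
    # One operating point per distinct score (all tied detections enter
    # together).
    last_of_score <- which(!duplicated(sc, fromLast = TRUE))
    pts <- data.frame(
      threshold = sc[last_of_score],
      fppi = cum_fp[last_of_score] / n_images,
      sensitivity = cum_tp[last_of_score] / n_lesions
    )
    pts <- rbind(data.frame(threshold = Inf, fppi = 0, sensitivity = 0), pts)
    # Keep the best sensitivity per FPPI value.
    best <- tapply(seq_len(nrow(pts)), pts$fppi,
                   function(i) i[which.max(pts$sensitivity[i])])
    pts <- pts[sort(unlist(best, use.names = FALSE)), , drop = FALSE]
    pts <- pts[order(pts$fppi), , drop = FALSE]
    rownames(pts) <- NULL
  }
  structure(list(points = pts, n_images = as.integer(n_images),
                 n_lesions = as.integer(n_lesions)),
            class = "froc_curve")
}

#' @export
print.froc_curve <- function(x, ...) {
  cat(sprintf("FROC curve: %d operating points, %d images, %d lesions\n",
              nrow(x$points), x$n_images, x$n_lesions))
  s <- sensitivity_at_fppi(x)
  cat("sensitivity @ FPPI ",
      paste(sprintf("%g: %.3f", c(0.5, 1, 2, 4, 8, 16), s), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.froc_curve <- function(x, ...) {
  plot(x$points$fppi, x$points$sensitivity, type = "s",
       xlab = "False positives per image (FPPI)", ylab = "Sensitivity",
       ylim = c(0, 1), ...)
  abline(v = c(0.5, 1, 2, 4), lty = 3, col = "grey60")
  invisible(x)
}

#' Read sensitivities off an FROC curve at FPPI targets
#'
#' Step-function evaluation with no interpolation: for each target the
#' sensitivity at the largest achieved FPPI not exceeding the target is
#' returned (0 when even the empty operating point exceeds it).
#'
#' @param curve a `froc_curve`.
#' @param fppi_targets FPPI operating points; default
#'   `c(0.5, 1, 2, 4, 8, 16)`.
#' @return numeric vector of sensitivities, named by target.
#' @export
sensitivity_at_fppi <- function(curve, fppi_targets = c(0.5, 1, 2, 4, 8, 16)) {
  stopifnot(inherits(curve, "froc_curve"))
  pts <- curve$points
  out <- vapply(fppi_targets, function(t) {
    ok <- pts$fppi <= t
    if (!any(ok)) 0 else pts$sensitivity[max(which(ok))]
  }, numeric(1))
  names(out) <- as.character(fppi_targets)
  out
}

#' Average sensitivity over FPPI 0.5, 1, 2 and 4
#'
#' The headline FROC summary: the arithmetic mean of the sensitivities at
#' the four canonical low-FPPI operating points.
#'
#' @param sens_at numeric vector of exactly four sensitivities, in the
#'   order FPPI = 0.5, 1, 2, 4.
#' @return their arithmetic mean.
#' @examples
#' average_sensitivity(c(0.6044, 0.7060, 0.7583, 0.8532))  # 0.730475
#' @export
average_sensitivity <- function(sens_at) {
  if (length(sens_at) != 4) {
    stop_invalid("average_sensitivity expects the four sensitivities at ",
                 "FPPI 0.5, 1, 2, 4")
  }
  mean(sens_at)
}

#' FROC evaluation report
#'
#' Tabulates sensitivity at the canonical FPPI points plus the average
#' over FPPI in `{0.5, 1, 2, 4}`, and optionally writes JSON and a
#' plain-text table.
#'
#' @param curve a `froc_curve`.
#' @param json_path,txt_path optional output paths.
#' @return a one-row data frame with columns `0.5`, `1`, `2`, `4`, `8`,
#'   `16`, `avg` (sensitivities in percent).
#' @export
froc_report <- function(curve, json_path = NULL, txt_path = NULL) {
  s <- sensitivity_at_fppi(curve)
  avg <- average_sensitivity(s[c("0.5", "1", "2", "4")])
  row <- as.data.frame(as.list(100 * c(s, avg = avg)), check.names = FALSE)
  names(row) <- c(names(s), "avg")
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(row), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(txt_path)) {
    hdr <- sprintf("%8s", c(names(s), "Avg. [0.5,1,2,4]"))
    val <- sprintf("%8.2f", unlist(row))
    writeLines(c(paste(hdr, collapse = " "), paste(val, collapse = " ")),
               txt_path)
  }
  row
}

#' Greedy non-maximum suppression
#'
#' Keeps detections in descending score order, discarding any whose IoU
#' with an already-kept detection reaches `iou_thresh`.
#'
#' @param dets detection data frame (box columns plus `score`).
#' @param iou_thresh suppression threshold; default 0.5.
#' @return the surviving detections, sorted by descending score.
#' @export
nms <- function(dets, iou_thresh = 0.5) {
  if (nrow(dets) <= 1) return(dets)
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  m <- iou_matrix(dets, dets)
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (i == 1 || all(m[i, which(keep)] < iou_thresh)) keep[i] <- TRUE
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
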