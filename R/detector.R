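# A small trainable proposal scorer.  The mechanism under study is the
# classification loss, which is architecture-agnostic, so the scorer is
# deliberately tiny: for each anchor it pools intensity features from the
# key slice and its neighbours (box mean, center-surround contrast, and
# through-plane persistence, computed with integral images) and maps them
# through a logistic head.  Training is plain stochastic gradient descent
# on the masked partial-label loss, one volume per step.

# Summed-area table: S[i+1, j+1] = sum of img[1..i, 1..j].
integral_image <- function(img) {
  s <- apply(img, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# Sum of img over 0-based half-open pixel rows r0..r1, cols c0..c1.
box_sums <- function(S, r0, r1, c0, c1) {
  S[cbind(r1 + 1, c1 + 1)] - S[cbind(r0 + 1, c1 + 1)] -
    S[cbind(r1 + 1, c0 + 1)] + S[cbind(r0 + 1, c0 + 1)]
}

# Per-anchor features on one volume's key slice.  Returns an
# n_anchors x 3 matrix: box mean, center-surround contrast, and the mean
# over the two adjacent slices (through-plane persistence).  All scaled
# by 1/255.
anchor_features <- function(volume, anchors) {
  d <- dim(volume$voxels)
  D <- d[1]; H <- d[2]; W <- d[3]
  key <- volume$key_slice
  slice <- volume$voxels[key + 1L, , ]
  nb_idx <- unique(clamp(c(key - 1L, key + 1L), 0L, D - 1L))
  nb <- Reduce(`+`, lapply(nb_idx, function(z) volume$voxels[z + 1L, , ])) /
    length(nb_idx)
  S <- integral_image(slice)
  Snb <- integral_image(nb)
  b <- anchors$boxes
  r0 <- clamp(floor(b$y), 0, H - 1); r1 <- clamp(ceiling(b$y + b$h), r0 + 1, H)
  c0 <- clamp(floor(b$x), 0, W - 1); c1 <- clamp(ceiling(b$x + b$w), c0 + 1, W)
  area <- (r1 - r0) * (c1 - c0)
  inner <- box_sums(S, r0, r1, c0, c1)
  f_mean <- inner / area
  # Surround ring: the box dilated by half its size on every side.
  er0 <- clamp(r0 - (r1 - r0) %/% 2, 0, H); er1 <- clamp(r1 + (r1 - r0) %/% 2, 0, H)
  ec0 <- clamp(c0 - (c1 - c0) %/% 2, 0, W); ec1 <- clamp(c1 + (c1 - c0) %/% 2, 0, W)
  earea <- (er1 - er0) * (ec1 - ec0)
  ring_area <- pmax(earea - area, 1)
  ring_mean <- (box_sums(S, er0, er1, ec0, ec1) - inner) / ring_area
  f_contrast <- f_mean - ring_mean
  f_nb <- box_sums(Snb, r0, r1, c0, c1) / area
  cbind(mean = f_mean, contrast = f_contrast, adjacent = f_nb) / 255
}

detector_anchors <- function(config, image_id = "img", slice_index = 0L) {
  generate_anchors(
    grid_shape = c(config$image_hw[1] %/% config$stride,
                   config$image_hw[2] %/% config$stride),
    stride = config$stride, base_size = config$base_size,
    ratios = config$ratios, image_id = image_id, slice_index = slice_index
  )
}

#' Fit a small lesion-proposal scorer under the partial-label loss
#'
#' Trains a logistic scorer over pooled anchor features by stochastic
#' gradient descent, one volume per step, using the masked
#' \eqn{\lambda}-weighted cross-entropy.  Anchor labels are assigned
#' against the *kept* (visible) boxes only, so hidden lesions are wrongly
#' negative -- the partial-label condition the loss is designed to
#' survive.  The negative mask is resampled at every step from a seed
#' derived from `(seed, epoch, step)`; the whole fit is a pure function
#' of `(dataset, config, seed)`.
#'
#' @param dataset a `pl_dataset` (from [make_dataset()] or
#'   [read_dataset()]) or a dataset directory path.
#' @param config an [experiment_config()].
#' @param seed integer training seed.
#' @return an object of class `pl_detector` with components `weights`
#'   (feature weights), `bias`, `trace` (per-step loss breakdown data
#'   frame), `config`, `seed`.  Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals`.
#' @seealso [predict.pl_detector()], [evaluate_detector()]
#' @export
train_detector <- function(dataset, config = experiment_config(), seed = 1L) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  stopifnot(inherits(dataset, "pl_dataset"))
  train_ids <- names(dataset$split)[dataset$split == "train"]
  if (length(train_ids) == 0) stop_invalid("dataset has no training volumes")
  kept <- dataset_boxes(dataset, "kept")
  lambda_eff <- if (config$use_factor) config$lambda_ else 1
  keep_eff <- if (config$use_mask) config$keep_fraction else 1
  # Anchor geometry is shared by every volume; features and labels are
  # fixed per volume, so compute them once.
  anchors <- detector_anchors(config)
  feats <- list(); labs <- list()
  for (id in train_ids) {
    v <- dataset$volumes[[id]]
    feats[[id]] <- anchor_features(v, anchors)
    g <- kept[kept$image_id == id, , drop = FALSE]
    labs[[id]] <- assign_labels(iou_matrix(anchors, g),
                                hi_thresh = config$hi_thresh,
                                lo_thresh = config$lo_thresh)
  }
  n_feat <- ncol(feats[[1]])
  # Standard neutral initialization: zero weights, zero bias.
  w <- numeric(n_feat)
  bias <- 0
  lr <- config$learning_rate
  trace <- vector("list", config$epochs * length(train_ids))
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    for (k in seq_along(train_ids)) {
      step <- step + 1L
      id <- train_ids[k]
      f <- feats[[id]]
      lab <- labs[[id]]
      y <- as_y(lab)
      mask <- sample_negative_mask(lab, keep_eff,
                                   seed = derive_seed(seed, ep, k))
      p <- plogis(drop(f %*% w) + bias)
      lb <- masked_loss(y, p, lambda_ = lambda_eff, mask = mask,
                        normalize = config$normalize)
      if (!is.finite(lb$l_m)) {
        stop_invalid(sprintf(
          "non-finite loss at step %d (volume %s): l_ps=%g l_ns=%g",
          step, id, lb$l_ps, lb$l_ns))
      }
      # d l_m / d logit:  -y (1 - p)  +  lambda * M * (1 - y) * p,
      # with the same per-term normalization as the loss itself.
      g_pos <- -(y * (1 - p))
      g_neg <- lambda_eff * unclass(mask) * (1 - y) * p
      if (config$normalize) {
        g_pos <- g_pos / max(lb$n_pos, 1)
        g_neg <- g_neg / max(lb$n_neg_kept, 1)
      }
      gz <- g_pos + g_neg
      w <- w - lr * drop(crossprod(f, gz))
      bias <- bias - lr * sum(gz)
      trace[[step]] <- data.frame(step = step, epoch = ep, volume = id,
                                  l_ps = lb$l_ps, l_ns = lb$l_ns,
                                  l_m = lb$l_m, n_pos = lb$n_pos,
                                  n_neg_kept = lb$n_neg_kept)
    }
  }
  names(w) <- colnames(feats[[1]])
  structure(
    list(weights = w, bias = bias, trace = do.call(rbind, trace),
         config = config, seed = as.integer(seed),
         n_train = length(train_ids)),
    class = "pl_detector"
  )
}

#' @export
print.pl_detector <- function(x, ...) {
  cat(sprintf(
    "Partial-label proposal scorer: %d features, trained %d steps on %d volumes\n",
    length(x$weights), nrow(x$trace), x$n_train))
  cat(sprintf("  lambda = %g (factor %s), keep_fraction = %g (mask %s)\n",
              x$config$lambda_, if (x$config$use_factor) "on" else "off",
              x$config$keep_fraction, if (x$config$use_mask) "on" else "off"))
  cat(sprintf("  final loss L_M = %.4f\n", x$trace$l_m[nrow(x$trace)]))
  invisible(x)
}

#' @export
coef.pl_detector <- function(object, ...) {
  c(bias = object$bias, object$weights)
}

#' @export
summary.pl_detector <- function(object, ...) {
  tr <- object$trace
  ep <- tapply(tr$l_m, tr$epoch, mean)
  out <- list(
    coefficients = coef(object),
    epochs = length(ep),
    loss_by_epoch = data.frame(epoch = as.integer(names(ep)),
                               mean_l_m = as.numeric(ep)),
    config = object$config
  )
  class(out) <- "summary.pl_detector"
  out
}

#' @export
print.summary.pl_detector <- function(x, ...) {
  cat("Partial-label proposal scorer\n\nCoefficients:\n")
  print(x$coefficients)
  cat("\nMean masked loss by epoch:\n")
  print(x$loss_by_epoch, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pl_detector <- function(x, ...) {
  tr <- x$trace
  plot(tr$step, tr$l_m, type = "l", xlab = "training step",
       ylab = "masked loss L_M", ...)
  lines(tr$step, tr$l_ps, col = "steelblue")
  legend("topright", legend = c("L_M", "L_PS"),
         col = c("black", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Score anchors and emit detections
#'
#' Applies the fitted scorer to each requested volume: every anchor gets
#' an objectness probability, then greedy non-maximum suppression prunes
#' overlapping candidates and the `top_k` highest-scoring survivors per
#' image are returned as detections on the key slice.
#'
#' @param object a fitted `pl_detector`.
#' @param dataset a `pl_dataset` or a single `lesion_volume`.
#' @param split which dataset split to score (default `"test"`); ignored
#'   for a single volume.
#' @param nms_iou non-maximum-suppression IoU threshold.
#' @param top_k detections kept per image after suppression.
#' @param ... unused.
#' @return detection data frame: `image_id`, `slice_index`, `x`, `y`,
#'   `w`, `h`, `score`.
#' @export
predict.pl_detector <- function(object, dataset, split = "test",
                                nms_iou = 0.5, top_k = 30, ...) {
  if (inherits(dataset, "lesion_volume")) {
    vols <- list(vol = dataset)
  } else {
    stopifnot(inherits(dataset, "pl_dataset"))
    ids <- names(dataset$split)[dataset$split %in% split]
    vols <- dataset$volumes[ids]
  }
  out <- list()
  for (id in names(vols)) {
    v <- vols[[id]]
    anchors <- detector_anchors(object$config, image_id = id,
                                slice_index = v$key_slice)
    f <- anchor_features(v, anchors)
    p <- plogis(drop(f %*% object$weights) + object$bias)
    d <- anchors$boxes[, c("image_id", "slice_index", "x", "y", "w", "h")]
    d$score <- p
    d <- nms(d, iou_thresh = nms_iou)
    out[[id]] <- head(d, top_k)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-anchor residuals of the fitted scorer
#'
#' For diagnostic use: `y - p` over the anchors of one volume, where `y`
#' is the label against the chosen truth.
#'
#' @param object a fitted `pl_detector`.
#' @param volume a `lesion_volume`.
#' @param gts ground-truth boxes for that volume.
#' @param ... unused.
#' @return numeric vector, one residual per anchor (NA at ignored anchors).
#' @export
residuals.pl_detector <- function(object, volume, gts, ...) {
  anchors <- detector_anchors(object$config)
  f <- anchor_features(volume, anchors)
  p <- plogis(drop(f %*% object$weights) + object$bias)
  lab <- assign_labels(iou_matrix(anchors, gts),
                       hi_thresh = object$config$hi_thresh,
                       lo_thresh = object$config$lo_thresh)
  y <- as.integer(unclass(lab))
  ifelse(is.na(y), NA_real_, y - p)
}

#' Evaluate a fitted detector with FROC
#'
#' Scores the requested split and computes the FROC curve against the
#' FULL ground truth (kept plus hidden boxes): label dropout corrupts
#' training, never the evaluation oracle.
#'
#' @param object a fitted `pl_detector`.
#' @param dataset a `pl_dataset`.
#' @param split dataset split to evaluate (default `"test"`).
#' @param iou_thresh FROC matching threshold.
#' @return a list with `curve` (a `froc_curve`), `sens` (sensitivities at
#'   FPPI 0.5, 1, 2, 4, 8, 16) and `avg` (mean over FPPI 0.5-4).
#' @export
evaluate_detector <- function(object, dataset, split = "test",
                              iou_thresh = 0.5) {
  dets <- predict(object, dataset, split = split)
  gts <- dataset_boxes(dataset, "full", split = split)
  n_images <- sum(dataset$split %in% split)
  curve <- froc_curve(dets, gts, n_images = n_images, iou_thresh = iou_thresh)
  s <- sensitivity_at_fppi(curve)
  list(curve = curve, sens = s,
       avg = average_sensitivity(s[c("0.5", "1", "2", "4")]))
}
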