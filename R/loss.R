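# The partial-label classification loss.  Standard anchor cross-entropy
# penalizes every negative anchor; under partial annotation some "negative"
# anchors actually cover unlabeled lesions, so that penalty is wrong.  Two
# controls reduce it: a random binary mask M that silences a subset of the
# negative anchors, and a factor lambda that scales the whole negative term:
#
#   L_PS = -sum_i y_i log p_i
#   L_NS = -lambda * sum_i (1 - y_i) log(1 - p_i)
#   L_M  = -sum_i [ y_i log p_i + lambda * M_i (1 - y_i) log(1 - p_i) ]

#' Sample the negative-anchor mask
#'
#' Draws one standard-normal variate per negative anchor and keeps the
#' anchor (mask 1) when its variate falls below the `keep_fraction`
#' quantile of the standard normal, so each negative anchor survives
#' independently with probability `keep_fraction`.  Positive and ignored
#' anchors always get mask 0 (the loss multiplies the mask by `1 - y`, so
#' those positions never contribute anyway).  The draw is a pure function
#' of `(labels, keep_fraction, seed)`.
#'
#' @param labels an `anchor_labels` object from [assign_labels()].
#' @param keep_fraction fraction of negative anchors to keep, in `(0, 1]`;
#'   `1` keeps every negative anchor and reduces to the unmasked loss.
#' @param seed integer seed for the mask draw.
#' @return an object of class `negative_mask`: a 0/1 numeric vector over
#'   anchors with attributes `keep_fraction` and `seed`.
#' @export
sample_negative_mask <- function(labels, keep_fraction, seed = 1L) {
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1 ||
      keep_fraction <= 0 || keep_fraction > 1) {
    stop_invalid("keep_fraction must lie in (0, 1]")
  }
  lab <- as.integer(unclass(labels))
  neg <- which(!is.na(lab) & lab == 0L)
  m <- numeric(length(lab))
  if (length(neg) > 0) {
    z <- with_seed(seed, rnorm(length(neg)))
    m[neg] <- as.numeric(z < qnorm(keep_fraction))
  }
  structure(m, keep_fraction = keep_fraction, seed = as.integer(seed),
            class = "negative_mask")
}

clip_probs <- function(p, eps) clamp(p, eps, 1 - eps)

check_lengths <- function(y, p, mask = NULL) {
  if (length(y) != length(p)) {
    stop_invalid("y and p must have the same length (", length(y),
                 " vs ", length(p), ")")
  }
  if (!is.null(mask) && length(mask) != length(y)) {
    stop_invalid("mask length (", length(mask),
                 ") must match y and p (", length(y), ")")
  }
}

#' Positive-sample cross-entropy loss
#'
#' `L_PS = -sum_i y_i log p_i`.  Predicted probabilities are clipped into
#' `[eps, 1 - eps]` before the logarithm.
#'
#' @param y binary ground-truth vector over anchors (1 = positive).
#' @param p predicted probability vector, same length as `y`.
#' @param eps clipping bound for probabilities; default `1e-7`.
#' @return nonnegative scalar; 0 when there are no positives.
#' @export
positive_loss <- function(y, p, eps = 1e-7) {
  check_lengths(y, p)
  p <- clip_probs(p, eps)
  -sum(y * log(p))
}

#' Lambda-weighted negative-sample cross-entropy loss
#'
#' `L_NS = -lambda * sum_i (1 - y_i) log(1 - p_i)`.  The factor `lambda`
#' rebalances the loss mass of the (far more numerous, and under partial
#' annotation partly mislabeled) negative anchors against the positives;
#' the term is exactly linear in `lambda`.
#'
#' @inheritParams positive_loss
#' @param lambda_ nonnegative scale on the negative term.
#' @return nonnegative scalar; 0 when `lambda_ = 0`.
#' @export
negative_loss <- function(y, p, lambda_, eps = 1e-7) {
  check_lengths(y, p)
  if (!is.numeric(lambda_) || length(lambda_) != 1 || lambda_ < 0) {
    stop_invalid("lambda_ must be a single nonnegative number")
  }
  p <- clip_probs(p, eps)
  -lambda_ * sum((1 - y) * log(1 - p))
}

#' Masked partial-label loss
#'
#' The combined loss
#' `L_M = -sum_i [ y_i log p_i + lambda * M_i (1 - y_i) log(1 - p_i) ]`,
#' reported together with its positive and negative components.  With an
#' all-ones mask and `lambda_ = 1` it reduces to plain binary
#' cross-entropy over the decided anchors.
#'
#' @inheritParams negative_loss
#' @param mask a `negative_mask` (or plain 0/1 vector) over anchors.
#' @param normalize if `TRUE`, divide the positive term by `max(n_pos, 1)`
#'   and the negative term by `max(n_neg_kept, 1)` (per-term means instead
#'   of plain sums; useful for training stability).  Default `FALSE`:
#'   plain sums.
#' @return an object of class `loss_breakdown`: a list with `l_ps`,
#'   `l_ns`, `l_m` (`= l_ps + l_ns`), `n_pos`, `n_neg_kept`, `lambda_`.
#' @examples
#' masked_loss(c(1, 0, 0), c(0.8, 0.6, 0.1), lambda_ = 0.6, mask = c(0, 1, 0))
#' @export
masked_loss <- function(y, p, lambda_, mask, eps = 1e-7, normalize = FALSE) {
  check_lengths(y, p, mask)
  if (!is.numeric(lambda_) || length(lambda_) != 1 || lambda_ < 0) {
    stop_invalid("lambda_ must be a single nonnegative number")
  }
  m <- as.numeric(unclass(mask))
  p <- clip_probs(p, eps)
  n_pos <- sum(y == 1)
  n_neg_kept <- sum(m * (1 - y))
  l_ps <- -sum(y * log(p))
  l_ns <- -lambda_ * sum(m * (1 - y) * log(1 - p))
  if (normalize) {
    l_ps <- l_ps / max(n_pos, 1)
    l_ns <- l_ns / max(n_neg_kept, 1)
  }
  structure(
    list(l_ps = l_ps, l_ns = l_ns, l_m = l_ps + l_ns,
         n_pos = as.integer(n_pos), n_neg_kept = as.integer(round(n_neg_kept)),
         lambda_ = lambda_),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "Masked loss: L_M = %.6g (L_PS = %.6g, L_NS = %.6g; lambda = %g, %d pos, %d neg kept)\n",
    x$l_m, x$l_ps, x$l_ns, x$lambda_, x$n_pos, x$n_neg_kept
  ))
  invisible(x)
}

#' Serialize a loss breakdown to a flat JSON record
#'
#' One line of JSON per training step, suitable for structured logs.
#'
#' @param x a `loss_breakdown`.
#' @return a single JSON string.
#' @export
loss_record_json <- function(x) {
  stopifnot(inherits(x, "loss_breakdown"))
  as.character(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA))
}
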