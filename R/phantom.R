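# Synthetic partially-annotated CT phantoms.  Each phantom is a multi-slice
# grey-scale volume: a smooth low-frequency background field plus Gaussian
# noise, with 1-3 additive ellipsoidal lesion blobs on the key (central)
# slice.  The tight bounding box of each blob at half its peak contrast is
# emitted as ground truth, and a seeded dropout process hides a fraction of
# the boxes to emulate partial annotation.  The mechanism under study
# depends on the label structure, not on realistic lesion texture, so the
# blobs make no claim of anatomical appearance.

#' Linear HU-to-intensity windowing
#'
#' Rescales CT values from the Hounsfield-unit range `[-1024, 3071]`
#' linearly onto `[0, 255]`; values outside the input range are clamped
#' (real CT series contain padding values).  The map is monotone
#' non-decreasing, sends -1024 to 0 and 3071 to 255 exactly, and clamping
#' makes it a fixed point on already-windowed data in that output range.
#'
#' @param raw_hu numeric scalar or array of CT values in HU.
#' @return values in `[0, 255]`, same shape as the input.
#' @examples
#' hu_window(c(-1024, 1023.5, 3071))  # 0, 127.5, 255
#' @export
hu_window <- function(raw_hu) {
  clamp((raw_hu + 1024) / 4095, 0, 1) * 255
}

#' Phantom generation parameters
#'
#' @param shape volume dimensions `(D, H, W)`; default `c(7, 128, 128)`
#'   (seven axial slices; 128 px in-plane keeps generation fast, 512 is
#'   available for full-size phantoms).
#' @param lesions_per_slice integer range `(min, max)` of lesions on the
#'   key slice, drawn uniformly; default `c(1, 3)`.
#' @param lesion_radius_px range of lesion semi-axes in pixels; default
#'   `c(5, 9)`.
#' @param lesion_contrast range of peak lesion intensity above background,
#'   in windowed intensity units; default `c(40, 90)`.
#' @param background_noise_sd per-voxel Gaussian noise standard deviation;
#'   default `6`.
#' @param dropout_rate fraction of ground-truth boxes hidden by
#'   [drop_annotations()], in `[0, 1)`; default `0.5`.
#' @param spacing_mm voxel spacing `(z, y, x)` in millimetres; default
#'   `c(2, 0.8, 0.8)` (2 mm slice interval).
#' @param seed integer seed.
#' @return an object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(shape = c(7, 128, 128),
                         lesions_per_slice = c(1, 3),
                         lesion_radius_px = c(5, 9),
                         lesion_contrast = c(40, 90),
                         background_noise_sd = 6,
                         dropout_rate = 0.5,
                         spacing_mm = c(2, 0.8, 0.8),
                         seed = 1L) {
  if (length(shape) != 3 || any(shape < 1)) {
    stop_invalid("shape must be (D, H, W) with positive entries")
  }
  if (length(lesions_per_slice) != 2 || lesions_per_slice[1] < 0 ||
      lesions_per_slice[2] < lesions_per_slice[1]) {
    stop_invalid("lesions_per_slice must be a nonempty (min, max) range")
  }
  if (length(lesion_radius_px) != 2 || lesion_radius_px[1] <= 0 ||
      lesion_radius_px[2] < lesion_radius_px[1]) {
    stop_invalid("lesion_radius_px must be a positive (min, max) range")
  }
  if (lesion_radius_px[2] >= min(shape[2], shape[3]) / 2) {
    stop_invalid("lesion radius must be below half the image size")
  }
  if (length(lesion_contrast) != 2 || lesion_contrast[1] <= 0 ||
      lesion_contrast[2] < lesion_contrast[1]) {
    stop_invalid("lesion_contrast must be a positive (min, max) range")
  }
  if (background_noise_sd < 0) stop_invalid("background_noise_sd must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_invalid("dropout_rate must lie in [0, 1)")
  }
  structure(
    list(shape = as.integer(shape),
         lesions_per_slice = as.integer(lesions_per_slice),
         lesion_radius_px = as.numeric(lesion_radius_px),
         lesion_contrast = as.numeric(lesion_contrast),
         background_noise_sd = background_noise_sd,
         dropout_rate = dropout_rate,
         spacing_mm = as.numeric(spacing_mm),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

new_lesion_volume <- function(voxels, spacing_mm, key_slice) {
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 key_slice = as.integer(key_slice)),
            class = "lesion_volume")
}

#' @export
print.lesion_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "Lesion volume: %d x %d x %d (D x H x W), spacing %s mm, key slice %d\n",
    d[1], d[2], d[3], paste(x$spacing_mm, collapse = " x "), x$key_slice
  ))
  invisible(x)
}

#' Generate one synthetic lesion volume
#'
#' Builds a `D x H x W` volume of windowed intensities in `[0, 255]`: a
#' bilinearly upsampled coarse random field (the low-frequency anatomy
#' surrogate) plus i.i.d. Gaussian noise, with additive ellipsoidal
#' Gaussian lesion blobs centered on the key slice.  Each lesion's
#' ground-truth box is the tight bounding box of the region where the blob
#' reaches half its peak contrast on the key slice (semi-axis times
#' `sqrt(2 log 2)`).  Identical seed and spec give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param image_id identifier stamped on the returned boxes.
#' @param seed optional seed overriding `spec$seed`.
#' @return a list with `volume` (a `lesion_volume`) and `gts` (box data
#'   frame on the key slice).
#' @export
generate_volume <- function(spec, image_id = "vol", seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(seed)) seed <- spec$seed
  D <- spec$shape[1]; H <- spec$shape[2]; W <- spec$shape[3]
  key <- (D - 1L) %/% 2L
  with_seed(seed, {
    coarse <- matrix(rnorm(25, mean = 0, sd = 18), 5, 5)
    bg2d <- 90 + bilinear_upsample(coarse, H, W)
    vox <- array(rep(bg2d, D), dim = c(H, W, D))
    vox <- vox + array(rnorm(length(vox), sd = spec$background_noise_sd),
                       dim = dim(vox))
    n_les <- if (spec$lesions_per_slice[2] == 0) 0L else
      sample(seq(spec$lesions_per_slice[1], spec$lesions_per_slice[2]), 1L)
    gts <- empty_boxes()
    if (n_les > 0) {
      rmax <- spec$lesion_radius_px[2]
      margin <- rmax * sqrt(2 * log(2)) + 1
      for (k in seq_len(n_les)) {
        rx <- runif(1, spec$lesion_radius_px[1], spec$lesion_radius_px[2])
        ry <- runif(1, spec$lesion_radius_px[1], spec$lesion_radius_px[2])
        rz <- 1.2
        cx <- runif(1, margin, W - margin)
        cy <- runif(1, margin, H - margin)
        contrast <- runif(1, spec$lesion_contrast[1], spec$lesion_contrast[2])
        # Evaluate the blob on a local window only (cheap, exact to noise).
        hwx <- rx * sqrt(2 * log(2)); hwy <- ry * sqrt(2 * log(2))
        jx <- seq(max(0, floor(cx - 3 * rx)), min(W - 1, ceiling(cx + 3 * rx)))
        jy <- seq(max(0, floor(cy - 3 * ry)), min(H - 1, ceiling(cy + 3 * ry)))
        dx2 <- ((jx + 0.5 - cx) / rx)^2
        dy2 <- ((jy + 0.5 - cy) / ry)^2
        blob2d <- contrast * exp(-0.5 * outer(dy2, dx2, `+`))
        for (z in seq_len(D) - 1L) {
          fz <- exp(-0.5 * ((z - key) / rz)^2)
          vox[jy + 1, jx + 1, z + 1] <- vox[jy + 1, jx + 1, z + 1] + fz * blob2d
        }
        gts <- rbind(gts, boxes(
          x = max(0, cx - hwx), y = max(0, cy - hwy),
          w = min(W, cx + hwx) - max(0, cx - hwx),
          h = min(H, cy + hwy) - max(0, cy - hwy),
          image_id = image_id, slice_index = key
        ))
      }
    }
    vox <- clamp(vox, 0, 255)
    list(volume = new_lesion_volume(aperm(vox, c(3, 1, 2)), spec$spacing_mm, key),
         gts = gts)
  })
}

#' Hide a fraction of ground-truth annotations
#'
#' Emulates the partial-label condition: each box is independently hidden
#' with probability `dropout_rate`.  Hidden boxes are returned separately
#' so that training sees only the kept boxes while evaluation can still
#' score against the full truth.
#'
#' @param gts box data frame.
#' @param dropout_rate probability of hiding each box, in `[0, 1)`.
#' @param seed integer seed; the partition is a pure function of
#'   `(gts, dropout_rate, seed)`.
#' @return a list with disjoint box data frames `kept` and `hidden` whose
#'   union is `gts`.
#' @export
drop_annotations <- function(gts, dropout_rate, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_invalid("dropout_rate must lie in [0, 1)")
  }
  validate_boxes(gts, "gts")
  n <- nrow(gts)
  hide <- if (n == 0) logical(0) else with_seed(seed, runif(n) < dropout_rate)
  list(kept = gts[!hide, , drop = FALSE],
       hidden = gts[hide, , drop = FALSE])
}
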