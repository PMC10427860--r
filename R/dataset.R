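# Dataset assembly and on-disk layout.  A dataset couples phantom volumes
# with their kept (visible to training) and hidden (full-truth-only) boxes
# and a train/validation/test split.  On disk: one NIfTI file per volume,
# one CSV of boxes with a `hidden` column, and a JSON manifest.

#' Deterministic 70/15/15 split assignment
#'
#' Volumes are assigned in order: the first `floor(0.7 n)` to train, the
#' next `floor(0.15 n)` to validation, the remainder to test (exactly
#' 70/15/15 when `n` is a multiple of 20).
#'
#' @param n number of volumes.
#' @return character vector of `"train"`, `"val"`, `"test"`.
#' @export
split_assignment <- function(n) {
  n_train <- floor(0.70 * n)
  n_val <- floor(0.15 * n)
  rep(c("train", "val", "test"), c(n_train, n_val, n - n_train - n_val))
}

#' Generate a partially annotated phantom dataset in memory
#'
#' Draws `n_volumes` phantoms from `spec`, hides a fraction
#' `spec$dropout_rate` of the ground-truth boxes, and assigns the
#' 70/15/15 split.  Fully determined by `(spec, n_volumes, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param n_volumes number of volumes to generate.
#' @param seed integer seed; per-volume and dropout seeds are derived
#'   from it.
#' @return an object of class `pl_dataset`: a list with `volumes` (named
#'   list of `lesion_volume`), `boxes` (box data frame with a 0/1
#'   `hidden` column), `split` (named character vector), and `spec`.
#' @export
make_dataset <- function(spec, n_volumes, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), n_volumes >= 1)
  ids <- sprintf("vol_%03d", seq_len(n_volumes))
  volumes <- vector("list", n_volumes)
  names(volumes) <- ids
  all_boxes <- empty_boxes()
  for (i in seq_len(n_volumes)) {
    g <- generate_volume(spec, image_id = ids[i], seed = derive_seed(seed, 1, i))
    volumes[[i]] <- g$volume
    all_boxes <- rbind(all_boxes, g$gts)
  }
  dr <- drop_annotations(all_boxes, spec$dropout_rate,
                         seed = derive_seed(seed, 2))
  kept <- dr$kept; hidden <- dr$hidden
  if (nrow(kept)) kept$hidden <- 0L
  if (nrow(hidden)) hidden$hidden <- 1L
  boxes_df <- rbind(kept, hidden)
  if (nrow(boxes_df) == 0) boxes_df <- cbind(empty_boxes(), hidden = integer(0))
  boxes_df <- boxes_df[order(boxes_df$image_id, boxes_df$x, boxes_df$y), ,
                       drop = FALSE]
  rownames(boxes_df) <- NULL
  split <- split_assignment(n_volumes)
  names(split) <- ids
  structure(list(volumes = volumes, boxes = boxes_df, split = split,
                 spec = spec),
            class = "pl_dataset")
}

#' @export
print.pl_dataset <- function(x, ...) {
  cat(sprintf(
    "Partially annotated dataset: %d volumes (%d train / %d val / %d test), %d boxes (%d hidden)\n",
    length(x$volumes), sum(x$split == "train"), sum(x$split == "val"),
    sum(x$split == "test"), nrow(x$boxes), sum(x$boxes$hidden == 1L)
  ))
  invisible(x)
}

#' Extract box views from a dataset
#'
#' @param ds a `pl_dataset`.
#' @param truth `"kept"` (training view: only visible annotations),
#'   `"full"` (evaluation view: every true lesion) or `"hidden"`.
#' @param split optional subset: `"train"`, `"val"` or `"test"`.
#' @return box data frame.
#' @export
dataset_boxes <- function(ds, truth = c("kept", "full", "hidden"),
                          split = NULL) {
  truth <- match.arg(truth)
  b <- ds$boxes
  b <- switch(truth,
    kept = b[b$hidden == 0L, , drop = FALSE],
    hidden = b[b$hidden == 1L, , drop = FALSE],
    full = b
  )
  if (!is.null(split)) {
    ids <- names(ds$split)[ds$split %in% split]
    b <- b[b$image_id %in% ids, , drop = FALSE]
  }
  rownames(b) <- NULL
  b
}

#' Write and read a phantom dataset
#'
#' On disk a dataset is a directory holding `volumes/<id>.nii.gz` (double
#' precision, voxel spacing in the NIfTI header), `boxes.csv` in the
#' standard box dialect plus a `hidden` column, and `manifest.json`
#' listing the files, the split assignment, key slices, and the
#' generating spec.  `read_dataset(write_dataset(ds, dir))` reproduces
#' voxels, boxes and split exactly.
#'
#' @param ds a `pl_dataset`.
#' @param dir_path dataset directory (created if missing).
#' @return `write_dataset()` returns the manifest (invisibly);
#'   `read_dataset()` returns the `pl_dataset`.
#' @export
write_dataset <- function(ds, dir_path) {
  stopifnot(inherits(ds, "pl_dataset"))
  dir.create(file.path(dir_path, "volumes"), recursive = TRUE,
             showWarnings = FALSE)
  files <- character(length(ds$volumes))
  key_slices <- integer(length(ds$volumes))
  for (i in seq_along(ds$volumes)) {
    id <- names(ds$volumes)[i]
    v <- ds$volumes[[i]]
    rel <- file.path("volumes", paste0(id, ".nii.gz"))
    # NIfTI stores x fastest: permute (D, H, W) -> (W, H, D).
    arr <- aperm(v$voxels, c(3, 2, 1))
    attr(arr, "pixdim") <- rev(v$spacing_mm)
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"),
                       file.path(dir_path, rel), datatype = "double")
    files[i] <- rel
    key_slices[i] <- v$key_slice
  }
  write_boxes_csv(ds$boxes, file.path(dir_path, "boxes.csv"))
  manifest <- list(
    volumes = data.frame(id = names(ds$volumes), file = files,
                         split = unname(ds$split), key_slice = key_slices,
                         stringsAsFactors = FALSE),
    boxes_file = "boxes.csv",
    spec = unclass(ds$spec)
  )
  jsonlite::write_json(manifest, file.path(dir_path, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir_path) {
  mf_path <- file.path(dir_path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop_invalid("no manifest.json in ", dir_path)
  }
  manifest <- jsonlite::fromJSON(mf_path)
  spec <- do.call(phantom_spec, manifest$spec)
  vols <- manifest$volumes
  volumes <- vector("list", nrow(vols))
  names(volumes) <- vols$id
  for (i in seq_len(nrow(vols))) {
    f <- file.path(dir_path, vols$file[i])
    if (!file.exists(f)) stop_invalid("missing volume file: ", f)
    img <- RNifti::readNifti(f)
    spacing <- rev(RNifti::pixdim(img))
    arr <- aperm(as.array(img), c(3, 2, 1))
    attributes(arr) <- list(dim = dim(arr))
    volumes[[i]] <- new_lesion_volume(arr, spacing, vols$key_slice[i])
  }
  boxes_df <- read_boxes_csv(file.path(dir_path, manifest$boxes_file))
  if (!"hidden" %in% names(boxes_df)) boxes_df$hidden <- 0L
  split <- vols$split
  names(split) <- vols$id
  structure(list(volumes = volumes, boxes = boxes_df, split = split,
                 spec = spec, dir = dir_path),
            class = "pl_dataset")
}
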