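#' CT volume container
#'
#' A 3-D stack of axial slices indexed `(slice, row, col)`, optionally
#' carrying voxel spacing (mm) and a 4x4 affine orientation transform.
#' Intensities are Hounsfield units for real CT or arbitrary phantom units.
#'
#' @param data 3-D numeric array indexed `(slice, row, col)`.
#' @param spacing optional numeric vector of 3 positive voxel sizes (mm).
#' @param affine optional 4x4 orientation matrix.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = NULL, affine = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must have exactly 3 dimensions", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!is.null(spacing)) {
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
      stop("`spacing` must be 3 positive lengths", call. = FALSE)
    }
  }
  if (!is.null(affine) && !identical(dim(affine), c(4L, 4L))) {
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d slices of %d x %d, intensities [%.1f, %.1f]\n",
              d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' Label volume paired with a CT volume
#'
#' Non-negative integer class labels on the same voxel grid as a
#' [ct_volume()]. Any positive label is treated as tumor: multi-subtype
#' lesion labels are collapsed to the binary tumor/background problem the
#' segmentation network solves.
#'
#' @param data 3-D array of non-negative integers.
#' @param volume optional paired `ct_volume`; shapes are checked when given.
#' @return An object of class `label_volume` with binarized `data`.
#' @export
label_volume <- function(data, volume = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must have exactly 3 dimensions", call. = FALSE)
  }
  if (any(data < 0)) stop("labels must be non-negative", call. = FALSE)
  if (!is.null(volume) && !identical(dim(data), dim(volume$data))) {
    stop("label shape does not match paired volume", call. = FALSE)
  }
  bin <- array(as.integer(data > 0), dim = dim(data))
  structure(list(data = bin), class = "label_volume")
}

#' Intensity window specification
#'
#' Linear display window mapping the intensity interval
#' `[level - width/2, level + width/2]` onto `[0, 2^out_depth - 1]`,
#' clipping outside. The default (level 40, width 400) is the standard
#' abdominal soft-tissue window.
#'
#' @param level window center intensity.
#' @param width positive window width.
#' @param out_depth output bit depth, 8 or 16.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(level = 40, width = 400, out_depth = 8L) {
  if (!is.numeric(width) || width <= 0) stop("`width` must be > 0", call. = FALSE)
  if (!out_depth %in% c(8L, 16L)) stop("`out_depth` must be 8 or 16", call. = FALSE)
  structure(list(level = level, width = width, out_depth = as.integer(out_depth)),
            class = "window_spec")
}

#' Read a NIfTI volume
#'
#' Reads a `.nii` or `.nii.gz` file into a [ct_volume()], reordering the
#' NIfTI `(x, y, z)` voxel grid to `(slice, row, col)`.
#'
#' @param path path to a NIfTI file.
#' @return A `ct_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop("not a readable NIfTI file: ", path,
                         " (", conditionMessage(e), ")", call. = FALSE)
                  })
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  }
  pd <- attr(img, "pixdim")
  spacing <- if (!is.null(pd) && length(pd) >= 3 && all(pd[1:3] > 0)) {
    rev(pd[1:3])                              # (z, y, x) -> (slice, row, col)
  } else NULL
  affine <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  ct_volume(aperm(arr, c(3L, 2L, 1L)), spacing = spacing, affine = affine)
}

#' Write a volume as NIfTI
#'
#' Inverse of [read_volume()]: the `(slice, row, col)` array is stored on
#' the NIfTI `(x, y, z)` grid, so a write-then-read round trip is exact.
#'
#' @param volume a `ct_volume` or `label_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- aperm(volume$data, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  sp <- volume$spacing
  if (!is.null(sp)) {
    RNifti::pixdim(img) <- rev(sp)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Apply an intensity window
#'
#' Maps intensities through
#' `round(clip((x - (level - width/2)) / width, 0, 1) * (2^out_depth - 1))`.
#'
#' @param volume a `ct_volume`.
#' @param window a [window_spec()].
#' @return A `ct_volume` with integer-valued data in the output bit range.
#' @export
apply_window <- function(volume, window = window_spec()) {
  stopifnot(inherits(window, "window_spec"))
  lo <- window$level - window$width / 2
  top <- 2^window$out_depth - 1
  x <- (volume$data - lo) / window$width
  x <- pmin(pmax(x, 0), 1)
  out <- volume
  out$data <- array(round(x * top), dim = dim(volume$data))
  out
}

window_matrix <- function(m, window) {
  lo <- window$level - window$width / 2
  top <- 2^window$out_depth - 1
  round(pmin(pmax((m - lo) / window$width, 0), 1) * top)
}

#' Bounding box
#'
#' Axis-aligned pixel box, 0-based, half-open on the max edges:
#' a pixel at (row r, col c) (1-based array indices) is inside iff
#' `y_min <= r - 1 < y_max` and `x_min <= c - 1 < x_max`.
#'
#' @param x_min,y_min,x_max,y_max integer box edges.
#' @return A named numeric vector of class `bounding_box`.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  if (!(x_min < x_max && y_min < y_max) || x_min < 0 || y_min < 0) {
    stop("invalid box: need 0 <= min < max on both axes", call. = FALSE)
  }
  structure(c(x_min = as.integer(x_min), y_min = as.integer(y_min),
              x_max = as.integer(x_max), y_max = as.integer(y_max)),
            class = "bounding_box")
}

#' Tight boxes around mask components
#'
#' One tight [bounding_box()] per 8-connected foreground component, sorted
#' by `(y_min, x_min)`.
#'
#' @param mask 2-D binary (0/1) matrix.
#' @return A list of `bounding_box` objects (empty for an empty mask).
#' @export
mask_to_boxes <- function(mask) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) {
    stop("`mask` must be binary (0/1)", call. = FALSE)
  }
  lab <- cc_label8(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  n <- max(lab)
  if (n == 0L) return(list())
  boxes <- vector("list", n)
  for (k in seq_len(n)) {
    w <- which(lab == k, arr.ind = TRUE)
    boxes[[k]] <- bounding_box(x_min = min(w[, 2]) - 1L, y_min = min(w[, 1]) - 1L,
                               x_max = max(w[, 2]), y_max = max(w[, 1]))
  }
  ord <- order(vapply(boxes, `[[`, numeric(1), "y_min"),
               vapply(boxes, `[[`, numeric(1), "x_min"))
  boxes[ord]
}

#' Axial slice sample
#'
#' One axial slice: windowed image, binary tumor mask, tight component
#' boxes, and the tumor-present flag. The three fields are kept mutually
#' consistent (`has_tumor` iff the mask has foreground iff boxes exist).
#'
#' @param image 2-D numeric matrix in the windowed bit range.
#' @param mask 2-D binary matrix of the same shape (or `NULL` when no
#'   ground truth is available).
#' @param volume_id identifier of the source volume.
#' @param slice_index 1-based axial index of the slice.
#' @param boxes optional precomputed boxes; recomputed from `mask` if missing.
#' @return An object of class `slice_sample`.
#' @export
slice_sample <- function(image, mask = NULL, volume_id = "vol",
                         slice_index = 1L, boxes = NULL) {
  image <- as.matrix(image)
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(image), dim(mask))) {
      stop("image and mask shapes differ", call. = FALSE)
    }
    if (is.null(boxes)) boxes <- mask_to_boxes(mask)
  } else if (is.null(boxes)) {
    boxes <- list()
  }
  structure(list(image = image, mask = mask, boxes = boxes,
                 has_tumor = length(boxes) > 0L,
                 volume_id = volume_id,
                 slice_index = as.integer(slice_index)),
            class = "slice_sample")
}

#' @export
print.slice_sample <- function(x, ...) {
  cat(sprintf("<slice_sample> %s slice %d: %d x %d, %s (%d box%s)\n",
              x$volume_id, x$slice_index, nrow(x$image), ncol(x$image),
              if (x$has_tumor) "tumor" else "background",
              length(x$boxes), if (length(x$boxes) == 1) "" else "es"))
  invisible(x)
}

#' Extract windowed axial slices with masks and boxes
#'
#' Produces one [slice_sample()] per axial index. Only a minority of slices
#' typically carry tumor; the `has_tumor` flag follows the mask support.
#'
#' @param volume a `ct_volume`.
#' @param labels a paired `label_volume` of the same shape.
#' @param window a [window_spec()].
#' @param volume_id identifier stored on every sample.
#' @return A list of `slice_sample` objects, one per slice.
#' @export
extract_slices <- function(volume, labels, window = window_spec(),
                           volume_id = "vol") {
  if (!identical(dim(volume$data), dim(labels$data))) {
    stop("volume and label shapes differ", call. = FALSE)
  }
  n <- dim(volume$data)[1]
  lapply(seq_len(n), function(k) {
    slice_sample(image = window_matrix(volume$data[k, , ], window),
                 mask = labels$data[k, , ],
                 volume_id = volume_id, slice_index = k)
  })
}

#' Export a slice image (and its mask) to disk
#'
#' Writes the slice image as PNG or JPEG. The mask, when present, is always
#' written as PNG: ground truth must survive the round trip losslessly,
#' so lossy JPEG is used for images only.
#'
#' @param sample a [slice_sample()].
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"jpg"`.
#' @return Path of the written image file.
#' @export
export_slice <- function(sample, dir, format = c("png", "jpg")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_s%04d", sample$volume_id, sample$slice_index)
  img01 <- sample$image / 255
  path <- file.path(dir, paste0(stem, ".", format))
  if (format == "png") {
    png::writePNG(img01, path)
  } else {
    jpeg::writeJPEG(img01, path, quality = 0.95)
  }
  if (!is.null(sample$mask)) {
    png::writePNG(sample$mask + 0, file.path(dir, paste0(stem, "_mask.png")))
  }
  path
}

#' Patient-level train/test split
#'
#' Randomly partitions volume (patient) identifiers so no volume
#' contributes slices to both sides. `|train| = round(ratio * n)`.
#'
#' @param volume_ids unique identifiers.
#' @param ratio training fraction in (0, 1); default 0.8 for an 8:2 split.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return `list(train = ..., test = ...)`, disjoint and exhaustive.
#' @export
split_dataset <- function(volume_ids, ratio = 0.8, seed = 1L) {
  if (anyDuplicated(volume_ids)) stop("volume ids must be unique", call. = FALSE)
  if (!(ratio > 0 && ratio < 1)) stop("`ratio` must be in (0, 1)", call. = FALSE)
  n <- length(volume_ids)
  n_train <- round(ratio * n)
  perm <- with_seed(seed, sample.int(n))
  list(train = volume_ids[sort(perm[seq_len(n_train)])],
       test = volume_ids[sort(perm[setdiff(seq_len(n), seq_len(n_train))])])
}
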