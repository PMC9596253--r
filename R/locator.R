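# Stage A1: find tumor-bearing slices and their boxes, then coarse-segment
# by margin-expanded cropping. The detector is a small anchor-free grid
# CNN behind a stable interface; an oracle detector (ground-truth boxes,
# score 1) isolates the fine-segmentation stage in tests and experiments.

#' Focus (space-to-depth) transform
#'
#' Losslessly rearranges an image so that the four pixel parities become
#' four channel groups: output channel block `g` (1..4) holds, in order,
#' (even row, even col), (even row, odd col), (odd row, even col),
#' (odd row, odd col) pixels — parities of the 0-based indices. Halves the
#' resolution and quadruples the channels; a pure permutation of values.
#'
#' @param x `(H, W, C)` array (or `H x W` matrix), H and W even.
#' @return `(H/2, W/2, 4C)` array; block `g` occupies channels
#'   `((g-1)*C + 1) : (g*C)`.
#' @export
focus_transform <- function(x) {
  x <- as_hwc(x)
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  if (H %% 2 || W %% 2) stop("H and W must be even", call. = FALSE)
  ev_r <- seq(1, H, by = 2); od_r <- seq(2, H, by = 2)
  ev_c <- seq(1, W, by = 2); od_c <- seq(2, W, by = 2)
  out <- array(0, dim = c(H / 2, W / 2, 4 * C))
  out[, , seq_len(C)]           <- x[ev_r, ev_c, , drop = FALSE]
  out[, , C + seq_len(C)]       <- x[ev_r, od_c, , drop = FALSE]
  out[, , 2 * C + seq_len(C)]   <- x[od_r, ev_c, , drop = FALSE]
  out[, , 3 * C + seq_len(C)]   <- x[od_r, od_c, , drop = FALSE]
  out
}

#' @rdname focus_transform
#' @param y `(H/2, W/2, 4C)` array produced by `focus_transform()`.
#' @export
focus_inverse <- function(y) {
  y <- as_hwc(y)
  h <- dim(y)[1]; w <- dim(y)[2]; C4 <- dim(y)[3]
  if (C4 %% 4) stop("channel count must be a multiple of 4", call. = FALSE)
  C <- C4 / 4
  x <- array(0, dim = c(2 * h, 2 * w, C))
  ev_r <- seq(1, 2 * h, by = 2); od_r <- seq(2, 2 * h, by = 2)
  ev_c <- seq(1, 2 * w, by = 2); od_c <- seq(2, 2 * w, by = 2)
  x[ev_r, ev_c, ] <- y[, , seq_len(C), drop = FALSE]
  x[ev_r, od_c, ] <- y[, , C + seq_len(C), drop = FALSE]
  x[od_r, ev_c, ] <- y[, , 2 * C + seq_len(C), drop = FALSE]
  x[od_r, od_c, ] <- y[, , 3 * C + seq_len(C), drop = FALSE]
  x
}

# adjoint of focus_transform (it is a permutation, so adjoint = inverse
# restricted to the value layout)
focus_bwd <- function(dy) focus_inverse(dy)

# nearest-neighbor resize of a matrix (used by mosaic placement)
resize_nearest <- function(m, h, w) {
  m <- as.matrix(m)
  ri <- pmin(nrow(m), floor((seq_len(h) - 0.5) * nrow(m) / h) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(w) - 0.5) * ncol(m) / w) + 1L)
  m[ri, ci, drop = FALSE]
}

#' Mosaic augmentation
#'
#' Composes four slice samples into one: a center point is drawn uniformly
#' in the middle half of the output canvas, and each input is rescaled
#' (nearest-neighbor) into its quadrant. Masks are transformed identically
#' to images; boxes are recomputed from the transformed mask, so boxes
#' scaled out of existence are dropped and `has_tumor` stays consistent.
#' Deterministic given `seed`.
#'
#' @param samples list of exactly 4 [slice_sample()] objects with masks.
#' @param out_size output `(H, W)`.
#' @param seed integer seed for the center draw.
#' @return A new `slice_sample`.
#' @export
mosaic_augment <- function(samples, out_size = NULL, seed = 1L) {
  if (length(samples) != 4L) stop("mosaic requires exactly 4 samples", call. = FALSE)
  if (is.null(out_size)) out_size <- dim(samples[[1]]$image)
  H <- out_size[1]; W <- out_size[2]
  ctr <- with_seed(seed, {
    c(sample.int(round(H / 2), 1) + round(H / 4),
      sample.int(round(W / 2), 1) + round(W / 4))
  })
  img <- matrix(0, H, W)
  msk <- matrix(0L, H, W)
  quads <- list(list(r = 1:ctr[1], c = 1:ctr[2]),
                list(r = 1:ctr[1], c = (ctr[2] + 1):W),
                list(r = (ctr[1] + 1):H, c = 1:ctr[2]),
                list(r = (ctr[1] + 1):H, c = (ctr[2] + 1):W))
  for (k in 1:4) {
    q <- quads[[k]]
    img[q$r, q$c] <- resize_nearest(samples[[k]]$image, length(q$r), length(q$c))
    if (!is.null(samples[[k]]$mask)) {
      msk[q$r, q$c] <- resize_nearest(samples[[k]]$mask, length(q$r), length(q$c))
    }
  }
  slice_sample(image = img, mask = msk,
               volume_id = paste0(samples[[1]]$volume_id, "_mosaic"),
               slice_index = samples[[1]]$slice_index)
}

#' Grid detector configuration
#'
#' The slice-level localization head: the slice is reduced by an optional
#' focus transform and conv/pool blocks to a `grid_stride`-pixel grid; at
#' every cell a 1x1 head predicts an objectness score and a box (center
#' offsets within the cell plus log-sizes). This treats tumor-slice
#' finding as a per-cell binary classification with box regression.
#'
#' @param grid_stride cell size in pixels (a power of 2; default 8).
#' @param score_threshold confidence cutoff in `[0, 1]` for emitting
#'   detections (default 0.5).
#' @param channels widths of the successive conv layers.
#' @param use_focus apply the focus transform before the backbone.
#' @param nms apply greedy non-maximum suppression to the detections
#'   (default off: every above-threshold box is cropped and predictions
#'   are unioned at paste-back, which is conservative for recall).
#' @param nms_iou IoU threshold for suppression when `nms = TRUE`.
#' @return An object of class `grid_detector_config`.
#' @export
grid_detector_config <- function(grid_stride = 8L, score_threshold = 0.5,
                                 channels = c(16L, 32L, 64L),
                                 use_focus = TRUE, nms = FALSE,
                                 nms_iou = 0.5) {
  if (grid_stride < 1 || bitwAnd(grid_stride, grid_stride - 1L) != 0) {
    stop("`grid_stride` must be a positive power of 2", call. = FALSE)
  }
  if (score_threshold < 0) stop("`score_threshold` must be >= 0", call. = FALSE)
  n_down <- as.integer(log2(grid_stride))
  if (use_focus && n_down < 1) {
    stop("`use_focus` needs grid_stride >= 2", call. = FALSE)
  }
  structure(list(grid_stride = as.integer(grid_stride),
                 score_threshold = score_threshold,
                 channels = as.integer(channels),
                 use_focus = isTRUE(use_focus),
                 nms = isTRUE(nms), nms_iou = nms_iou),
            class = "grid_detector_config")
}

#' Build the grid detector
#'
#' @param config a [grid_detector_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `grid_detector`.
#' @export
build_grid_detector <- function(config = grid_detector_config(), seed = 1L) {
  stopifnot(inherits(config, "grid_detector_config"))
  n_down <- as.integer(log2(config$grid_stride))
  n_blocks <- n_down - as.integer(config$use_focus)
  widths <- rep_len(config$channels, n_blocks + 1L)
  with_seed(seed, {
    p <- list()
    cin <- if (config$use_focus) 12L else 3L
    for (k in seq_len(n_blocks + 1L)) {
      p[[paste0("conv_", k)]] <- init_conv(3, 3, cin, widths[k])
      cin <- widths[k]
    }
    p[["head"]] <- init_conv(1, 1, cin, 5L)   # obj, tx, ty, tw, th
    p[["head"]]$b[1] <- -3                    # objectness starts at the prior
    structure(list(config = config, params = p, n_blocks = n_blocks,
                   trained = FALSE),
              class = "grid_detector")
  })
}

# Backbone forward: returns the (gh, gw, 5) raw head map; with cache for
# training. Input x: (H, W, 3) in [0, 1], H and W divisible by grid_stride.
grid_forward <- function(det, x, want_cache = FALSE) {
  p <- det$params
  cache <- list(x = x)
  cur <- x
  if (det$config$use_focus) cur <- focus_transform(cur)
  cache$focus_out <- cur
  A <- R <- Pidx <- list()
  for (k in seq_len(det$n_blocks + 1L)) {
    A[[k]] <- cur
    r <- nn_lrelu(nn_conv2d(cur, p[[paste0("conv_", k)]]$w,
                            p[[paste0("conv_", k)]]$b, pad1))
    R[[k]] <- r
    if (k <= det$n_blocks) {
      pl <- nn_maxpool2(r)
      Pidx[[k]] <- pl$idx
      cur <- pl$y
    } else {
      cur <- r
    }
  }
  head <- nn_conv2d(cur, p[["head"]]$w, p[["head"]]$b)
  if (!want_cache) return(head)
  cache$A <- A; cache$R <- R; cache$Pidx <- Pidx
  list(head = head, cache = cache)
}

grid_backward <- function(det, cache, dhead) {
  p <- det$params
  g <- list()
  bw <- nn_conv2d_bwd(cache$R[[det$n_blocks + 1L]], p[["head"]]$w, dhead)
  g[["head"]] <- list(w = bw$dw, b = bw$db)
  dcur <- bw$dx
  for (k in (det$n_blocks + 1L):1) {
    if (k <= det$n_blocks) {
      hp <- dim(cache$R[[k]])[1]; wp <- dim(cache$R[[k]])[2]
      dcur <- nn_maxpool2_bwd(cache$Pidx[[k]], dcur, hp, wp)
    }
    dz <- nn_lrelu_bwd(cache$R[[k]], dcur)
    bw <- nn_conv2d_bwd(cache$A[[k]], p[[paste0("conv_", k)]]$w, dz, pad1,
                        need_dx = k > 1)
    g[[paste0("conv_", k)]] <- list(w = bw$dw, b = bw$db)
    if (k > 1) dcur <- bw$dx
  }
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))

prep_det_input <- function(image, stride, bit_top = 255) {
  pm <- pad_to_multiple(image / bit_top, stride)
  x <- array(rep(pm$image, 3L), dim = c(dim(pm$image), 3L))
  list(x = x, pad = pm$pad)
}

#' Run the grid detector on a slice
#'
#' Decodes every grid cell into a candidate box; cells whose objectness
#' score reaches `score_threshold` emit detections, clipped to the slice
#' bounds and sorted by descending score.
#'
#' @param det a `grid_detector` (trained via [train_locator()], or freshly
#'   initialized).
#' @param sample a [slice_sample()].
#' @param config optional override of the detector's config (e.g. a
#'   different score threshold).
#' @return List of detections, each `list(score, box)`.
#' @export
detect <- function(det, sample, config = det$config) {
  stride <- config$grid_stride
  H <- nrow(sample$image); W <- ncol(sample$image)
  if (H < stride || W < stride) {
    stop("image smaller than one grid cell", call. = FALSE)
  }
  inp <- prep_det_input(sample$image, stride)
  head <- grid_forward(det, inp$x)
  gh <- dim(head)[1]; gw <- dim(head)[2]
  dets <- list()
  for (gy in seq_len(gh)) {
    for (gx in seq_len(gw)) {
      sc <- sigmoid(head[gy, gx, 1])
      if (sc < config$score_threshold) next
      cx <- (gx - 1 + sigmoid(head[gy, gx, 2])) * stride
      cy <- (gy - 1 + sigmoid(head[gy, gx, 3])) * stride
      bw_ <- exp(min(head[gy, gx, 4], 8)) * stride
      bh <- exp(min(head[gy, gx, 5], 8)) * stride
      x0 <- max(0L, min(W - 1L, as.integer(round(cx - bw_ / 2))))
      y0 <- max(0L, min(H - 1L, as.integer(round(cy - bh / 2))))
      x1 <- max(x0 + 1L, min(W, as.integer(round(cx + bw_ / 2))))
      y1 <- max(y0 + 1L, min(H, as.integer(round(cy + bh / 2))))
      dets[[length(dets) + 1L]] <-
        list(score = sc, box = bounding_box(x0, y0, x1, y1))
    }
  }
  if (length(dets) == 0) return(list())
  dets <- dets[order(vapply(dets, `[[`, numeric(1), "score"),
                     decreasing = TRUE)]
  if (isTRUE(config$nms)) dets <- nms_filter(dets, config$nms_iou)
  dets
}

box_iou <- function(a, b) {
  ix <- max(0, min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"]))
  iy <- max(0, min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"]))
  inter <- ix * iy
  area <- function(z) (z["x_max"] - z["x_min"]) * (z["y_max"] - z["y_min"])
  un <- area(a) + area(b) - inter
  if (un <= 0) 0 else unname(inter / un)
}

nms_filter <- function(dets, iou_thr) {
  keep <- list()
  for (d in dets) {
    if (all(vapply(keep, function(k) box_iou(k$box, d$box) < iou_thr,
                   logical(1)))) {
      keep[[length(keep) + 1L]] <- d
    }
  }
  keep
}

#' Oracle detector
#'
#' Returns the ground-truth component boxes of a sample with score 1.0 —
#' the perfect-localizer mode that isolates the fine-segmentation stage.
#'
#' @param sample a [slice_sample()] carrying a mask.
#' @return List of detections, each `list(score = 1, box)`.
#' @export
oracle_detect <- function(sample) {
  if (is.null(sample$mask)) stop("sample has no mask", call. = FALSE)
  lapply(sample$boxes, function(b) list(score = 1.0, box = b))
}

#' Margin-expanded crop (coarse segmentation)
#'
#' Expands a detection box by `margin` pixels on all four sides, clamps the
#' window to the slice bounds, and crops image and mask identically. The
#' default 10-pixel margin is the cascade's coarse-segmentation rule: the
#' crop, not the raw box, becomes the fine-segmentation input.
#'
#' @param sample a [slice_sample()].
#' @param box a [bounding_box()].
#' @param margin non-negative expansion in pixels (default 10).
#' @return A `crop_result`: `image_crop`, `mask_crop` (or `NULL`), `offset`
#'   (`(y_min, x_min)` of the window, 0-based) and the source identifiers.
#' @export
crop_with_margin <- function(sample, box, margin = 10L) {
  if (margin < 0) stop("`margin` must be >= 0", call. = FALSE)
  H <- nrow(sample$image); W <- ncol(sample$image)
  x0 <- max(0L, box[["x_min"]] - margin)
  y0 <- max(0L, box[["y_min"]] - margin)
  x1 <- min(W, box[["x_max"]] + margin)
  y1 <- min(H, box[["y_max"]] + margin)
  rows <- (y0 + 1L):y1
  cols <- (x0 + 1L):x1
  structure(list(
    image_crop = sample$image[rows, cols, drop = FALSE],
    mask_crop = if (!is.null(sample$mask)) sample$mask[rows, cols, drop = FALSE],
    offset = c(y_min = y0, x_min = x0),
    volume_id = sample$volume_id,
    slice_index = sample$slice_index), class = "crop_result")
}

# --- detector training ------------------------------------------------------

# Build the per-cell training targets for one sample: objectness 1 at the
# cell containing each ground-truth box center, plus box regression
# targets (center offset within the cell, log width/height over stride).
grid_targets <- function(boxes, gh, gw, stride) {
  obj <- matrix(0, gh, gw)
  reg <- array(0, dim = c(gh, gw, 4))
  for (b in boxes) {
    cx <- (b[["x_min"]] + b[["x_max"]]) / 2
    cy <- (b[["y_min"]] + b[["y_max"]]) / 2
    gx <- min(gw, floor(cx / stride) + 1L)
    gy <- min(gh, floor(cy / stride) + 1L)
    obj[gy, gx] <- 1
    reg[gy, gx, 1] <- cx / stride - (gx - 1)          # sigmoid-space tx
    reg[gy, gx, 2] <- cy / stride - (gy - 1)
    reg[gy, gx, 3] <- log((b[["x_max"]] - b[["x_min"]]) / stride)
    reg[gy, gx, 4] <- log((b[["y_max"]] - b[["y_min"]]) / stride)
  }
  list(obj = obj, reg = reg)
}

# BCE-with-logits on objectness over all cells + squared error on box
# parameters at positive cells. Positive cells are rare (typically one per
# tumor on an 8x8 grid, and many slices have none), so the positive term
# is up-weighted by `pos_weight`. Returns loss and gradient w.r.t. the head.
grid_loss <- function(head, tgt, box_weight = 2, pos_weight = 8) {
  gh <- dim(head)[1]; gw <- dim(head)[2]
  n <- gh * gw
  s <- sigmoid(head[, , 1])
  eps <- 1e-12
  obj_loss <- -mean(pos_weight * tgt$obj * log(s + eps) +
                      (1 - tgt$obj) * log(1 - s + eps))
  dhead <- array(0, dim = dim(head))
  dhead[, , 1] <- (s * (pos_weight * tgt$obj + 1 - tgt$obj) -
                     pos_weight * tgt$obj) / n
  pos <- tgt$obj > 0
  box_loss <- 0
  if (any(pos)) {
    # normalized over all cells, like the objectness term, so the two
    # gradients are on a common scale regardless of the positive count
    sx <- sigmoid(head[, , 2]); sy <- sigmoid(head[, , 3])
    dx <- sx - tgt$reg[, , 1]; dy <- sy - tgt$reg[, , 2]
    dw <- head[, , 4] - tgt$reg[, , 3]; dh <- head[, , 5] - tgt$reg[, , 4]
    box_loss <- sum((dx^2 + dy^2 + dw^2 + dh^2)[pos]) / n
    sc <- box_weight / n
    dhead[, , 2] <- ifelse(pos, sc * 2 * dx * sx * (1 - sx), 0)
    dhead[, , 3] <- ifelse(pos, sc * 2 * dy * sy * (1 - sy), 0)
    dhead[, , 4] <- ifelse(pos, sc * 2 * dw, 0)
    dhead[, , 5] <- ifelse(pos, sc * 2 * dh, 0)
  }
  list(loss = obj_loss + box_weight * box_loss, dhead = dhead,
       obj_loss = obj_loss)
}

#' Train the localization network
#'
#' Minimizes per-cell binary cross-entropy on objectness plus squared error
#' on box parameters at positive cells, with SGD + momentum. With
#' probability `mosaic_prob` a training slice is replaced by a mosaic of
#' four slices drawn from the training set. Deterministic given
#' `train_cfg$seed`.
#'
#' @param train_samples list of [slice_sample()] objects (tumor and
#'   background slices).
#' @param config a [grid_detector_config()].
#' @param train_cfg a [train_config()].
#' @param mosaic_prob probability of mosaic augmentation per drawn sample.
#' @param verbose print epoch summaries.
#' @return `list(model, history)`; history columns include the objectness
#'   loss per epoch.
#' @export
train_locator <- function(train_samples, config = grid_detector_config(),
                          train_cfg = train_config(), mosaic_prob = 0.5,
                          verbose = FALSE) {
  if (length(train_samples) == 0) stop("empty training set", call. = FALSE)
  det <- build_grid_detector(config, seed = train_cfg$seed)
  state <- sgd_state(det$params)
  stride <- config$grid_stride
  hist <- list()
  iter <- 0L
  with_seed(train_cfg$seed + 1L, {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(length(train_samples))
      losses <- obj_losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))) {
        grads <- zero_grads(det$params)
        bl <- bo <- 0
        for (i in b) {
          smp <- train_samples[[i]]
          if (mosaic_prob > 0 && runif(1) < mosaic_prob) {
            others <- sample.int(length(train_samples), 3, replace = TRUE)
            smp <- mosaic_augment(c(list(smp), train_samples[others]),
                                  out_size = dim(smp$image),
                                  seed = sample.int(.Machine$integer.max, 1))
          }
          inp <- prep_det_input(smp$image, stride)
          fw <- grid_forward(det, inp$x, want_cache = TRUE)
          tgt <- grid_targets(smp$boxes, dim(fw$head)[1], dim(fw$head)[2],
                              stride)
          ls <- grid_loss(fw$head, tgt)
          bl <- bl + ls$loss; bo <- bo + ls$obj_loss
          grads <- add_grads(grads, grid_backward(det, fw$cache, ls$dhead),
                             scale = 1 / length(b))
        }
        grads <- clip_grads(grads, train_cfg$clip_norm)
        st <- sgd_step(det$params, grads, state, train_cfg$lr,
                       train_cfg$momentum, train_cfg$weight_decay)
        det$params <- st$params
        state <- st$state
        iter <- iter + 1L
        losses <- c(losses, bl / length(b))
        obj_losses <- c(obj_losses, bo / length(b))
      }
      hist[[length(hist) + 1L]] <- data.frame(
        iteration = iter, epoch = ep, loss = mean(losses),
        obj_loss = mean(obj_losses))
      if (verbose) {
        message(sprintf("locator epoch %3d  loss %.5f", ep, mean(losses)))
      }
    }
  })
  det$trained <- TRUE
  list(model = det, history = do.call(rbind, hist))
}

#' Export detections as JSON lines
#'
#' One JSON object per detection: volume id, slice index, score and box.
#'
#' @param detections list of per-slice detection lists, named or paired
#'   with `samples`.
#' @param samples the corresponding [slice_sample()] list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_detections <- function(detections, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(detections)) {
    for (d in detections[[i]]) {
      writeLines(jsonlite::toJSON(
        list(volume_id = samples[[i]]$volume_id,
             slice_index = samples[[i]]$slice_index,
             score = d$score, box = as.list(unclass(d$box))),
        auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
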