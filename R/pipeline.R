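# Cascade orchestration: preprocess -> detect -> margin crop -> fine
# segmentation -> paste back -> evaluate.

#' Pad an image to a size multiple
#'
#' Reflect-pads on the bottom and right to the next multiple of `multiple`,
#' recording the pad amounts so the inverse crop is exact. The network
#' requires spatial sizes divisible by `2^depth`; callers pad with this and
#' crop the prediction back.
#'
#' @param image 2-D matrix or `(H, W, C)` array.
#' @param multiple positive integer.
#' @return `list(image = padded, pad = c(pad_h, pad_w))`.
#' @export
pad_to_multiple <- function(image, multiple) {
  if (multiple < 1) stop("`multiple` must be >= 1", call. = FALSE)
  d <- dim(image)
  if (is.null(d)) d <- dim(as.matrix(image))
  H <- d[1]; W <- d[2]
  ph <- (multiple - H %% multiple) %% multiple
  pw <- (multiple - W %% multiple) %% multiple
  if (ph == 0 && pw == 0) return(list(image = image, pad = c(0L, 0L)))
  refl <- function(n, p) {
    # reflected indices past the edge: n-1, n-2, ... (repeating if short)
    idx <- n - (seq_len(p) - 1L) %% max(n - 1L, 1L) - 1L
    idx[idx < 1L] <- 1L
    idx
  }
  ri <- c(seq_len(H), refl(H, ph))
  ci <- c(seq_len(W), refl(W, pw))
  padded <- if (length(d) == 3L) {
    image[ri, ci, , drop = FALSE]
  } else {
    as.matrix(image)[ri, ci, drop = FALSE]
  }
  list(image = padded, pad = c(as.integer(ph), as.integer(pw)))
}

#' Cascade configuration
#'
#' Runtime configuration of the two-stage pipeline.
#'
#' @param window a [window_spec()] applied to raw volumes.
#' @param margin crop expansion in pixels (default 10).
#' @param detector_mode `"oracle"` (ground-truth boxes), `"grid"` (the
#'   trained detector) or `"whole_slice"` (no localization: every full
#'   slice is segmented — the no-locator ablation).
#' @param score_threshold optional override of the detector threshold.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(window = window_spec(), margin = 10L,
                           detector_mode = c("grid", "oracle", "whole_slice"),
                           score_threshold = NULL) {
  detector_mode <- match.arg(detector_mode)
  if (margin < 0) stop("`margin` must be >= 0", call. = FALSE)
  structure(list(window = window, margin = as.integer(margin),
                 detector_mode = detector_mode,
                 score_threshold = score_threshold),
            class = "cascade_config")
}

# Segment one crop with the fine network, returning a binary mask of the
# crop's original size.
segment_crop <- function(segmodel, crop_image, bit_top = 255) {
  mult <- 2^segmodel$config$depth
  pm <- pad_to_multiple(crop_image / bit_top, mult)
  logits <- segnet_forward(segmodel, pm$image)
  mask <- predict_mask(logits)
  mask[seq_len(nrow(crop_image)), seq_len(ncol(crop_image)), drop = FALSE]
}

#' Run the full cascade on a volume
#'
#' For every axial slice: detect tumor candidates, expand each detection by
#' the margin, finely segment the crop, and paste the predicted mask back
#' at its offset, unioning overlapping crops. Slices without detections
#' stay all-background.
#'
#' @param volume a raw `ct_volume` (windowing is applied internally).
#' @param labels optional `label_volume`; required for
#'   `detector_mode = "oracle"`.
#' @param detector a trained `grid_detector` (ignored in oracle and
#'   whole-slice modes).
#' @param segmodel a trained `seg_model`.
#' @param cfg a [cascade_config()].
#' @param volume_id identifier recorded in the provenance.
#' @return A `volume_prediction`: binary `mask` volume of the input shape
#'   plus per-slice detection provenance.
#' @export
run_cascade <- function(volume, labels = NULL, detector = NULL, segmodel,
                        cfg = cascade_config(), volume_id = "vol") {
  mode <- cfg$detector_mode
  if (mode == "oracle" && is.null(labels)) {
    stop("oracle detector mode requires `labels`", call. = FALSE)
  }
  if (mode == "grid") {
    if (is.null(detector)) stop("grid mode requires a detector", call. = FALSE)
    if (!isTRUE(detector$trained)) {
      stop("grid detector is untrained; train with train_locator()",
           call. = FALSE)
    }
    dcfg <- detector$config
    if (!is.null(cfg$score_threshold)) dcfg$score_threshold <- cfg$score_threshold
  }
  shape <- dim(volume$data)
  win <- apply_window(volume, cfg$window)
  pred <- array(0L, dim = shape)
  prov <- vector("list", shape[1])
  for (k in seq_len(shape[1])) {
    smp <- slice_sample(win$data[k, , ],
                        mask = if (!is.null(labels)) labels$data[k, , ],
                        volume_id = volume_id, slice_index = k)
    dets <- switch(mode,
      oracle = oracle_detect(smp),
      grid = detect(detector, smp, dcfg),
      whole_slice = list(list(score = 1.0,
                              box = bounding_box(0L, 0L, ncol(smp$image),
                                                 nrow(smp$image)))))
    prov[[k]] <- dets
    if (length(dets) == 0) next
    canvas <- matrix(0L, shape[2], shape[3])
    for (d in dets) {
      cr <- crop_with_margin(smp, d$box, cfg$margin)
      m <- segment_crop(segmodel, cr$image_crop)
      rows <- cr$offset[["y_min"]] + seq_len(nrow(m))
      cols <- cr$offset[["x_min"]] + seq_len(ncol(m))
      canvas[rows, cols] <- pmax(canvas[rows, cols], m)   # union overlaps
    }
    pred[k, , ] <- canvas
  }
  structure(list(mask = pred, detections = prov, volume_id = volume_id),
            class = "volume_prediction")
}

# ---------------------------------------------------------------------------

# Ground-truth margin crops of the tumor slices of a sample list: the
# training material of the fine-segmentation stage.
oracle_crops <- function(samples, margin = 10L) {
  out <- list()
  for (s in samples) {
    for (d in oracle_detect(s)) {
      cr <- crop_with_margin(s, d$box, margin)
      out[[length(out) + 1L]] <- list(image = cr$image_crop,
                                      mask = cr$mask_crop)
    }
  }
  out
}

# Windowed slice samples of a list of phantom (volume, labels) pairs.
dataset_slices <- function(data, window) {
  out <- list()
  for (id in names(data)) {
    out <- c(out, extract_slices(data[[id]]$volume, data[[id]]$labels,
                                 window, volume_id = id))
  }
  out
}

#' End-to-end phantom experiment
#'
#' Generates a phantom dataset, splits it at the volume level, trains the
#' locator on all training slices and the fine-segmentation network on
#' ground-truth margin crops, then runs the full cascade on the held-out
#' volumes. Reports the tumor-slice segmentation metrics, the slice-level
#' detection recall (a tumor slice counts as found if any detection fires
#' on it), and the segmentation IoU convergence history.
#'
#' @param n_train,n_test number of phantom volumes per side.
#' @param spec a [phantom_spec()].
#' @param seed master seed for generation, initialization and shuffling.
#' @param seg_config a [segnet_config()]; the default here is a reduced
#'   width suited to CPU-scale runs.
#' @param det_config a [grid_detector_config()].
#' @param epochs segmentation training epochs.
#' @param locator_epochs detector training epochs.
#' @param window a [window_spec()].
#' @param margin crop margin in pixels.
#' @param verbose print progress.
#' @return A list: `report` (metrics_report on held-out tumor slices),
#'   `locator_recall`, `history` (segmentation training history),
#'   `locator`, `segmodel`, and the test predictions.
#' @export
run_phantom_experiment <- function(n_train = 30L, n_test = 10L,
                                   spec = phantom_spec(),
                                   seed = 1L,
                                   seg_config = segnet_config(
                                     base_channels = 24L, fpn_channels = 48L),
                                   det_config = grid_detector_config(
                                     score_threshold = 0.35),
                                   epochs = 24L, locator_epochs = 20L,
                                   window = window_spec(), margin = 10L,
                                   verbose = FALSE) {
  data <- generate_phantoms(n_train + n_test, spec, seed = seed)
  split <- split_dataset(names(data), ratio = n_train / (n_train + n_test),
                         seed = seed)
  train_slices <- dataset_slices(data[split$train], window)
  tumor_slices <- Filter(function(s) s$has_tumor, train_slices)
  eval_pool <- tumor_slices[seq_len(min(8L, length(tumor_slices)))]

  if (verbose) message("training locator on ", length(train_slices), " slices")
  loc <- train_locator(train_slices, det_config,
                       train_config(epochs = locator_epochs, seed = seed),
                       verbose = verbose)

  crops <- oracle_crops(tumor_slices, margin)
  eval_crops <- oracle_crops(eval_pool, margin)
  if (verbose) message("training segnet on ", length(crops), " crops")
  seg0 <- build_segnet(seg_config, seed = seed)
  tr <- train_segnet(seg0, crops, eval_crops,
                     train_config(epochs = epochs, seed = seed,
                                  eval_every = 25L),
                     verbose = verbose)

  cfg <- cascade_config(window = window, margin = margin,
                        detector_mode = "grid")
  preds <- truths <- list()
  ids <- character(0)
  found <- total_tumor <- 0L
  predictions <- list()
  for (id in split$test) {
    vp <- run_cascade(data[[id]]$volume, data[[id]]$labels, loc$model,
                      tr$model, cfg, volume_id = id)
    predictions[[id]] <- vp
    lab <- data[[id]]$labels$data
    for (k in seq_len(dim(lab)[1])) {
      preds[[length(preds) + 1L]] <- vp$mask[k, , ]
      truths[[length(truths) + 1L]] <- lab[k, , ]
      ids <- c(ids, sprintf("%s_s%02d", id, k))
      if (sum(lab[k, , ]) > 0) {
        total_tumor <- total_tumor + 1L
        if (length(vp$detections[[k]]) > 0) found <- found + 1L
      }
    }
  }
  report <- evaluate(preds, truths, ids)
  list(report = report,
       locator_recall = if (total_tumor > 0) found / total_tumor else NA_real_,
       history = tr$history,
       locator = loc$model, segmodel = tr$model,
       predictions = predictions, split = split)
}

#' Ablation harness
#'
#' Trains and evaluates the cascade under toggles of its three design
#' choices on one shared phantom split and seed: `use_shallow` (3 vs 4
#' downsamplings), `use_locator` (margin-crop cascade vs whole-slice
#' segmentation) and `use_fpn` (pyramid-merged vs plain skips). Returns a
#' table with one row per configuration.
#'
#' @param train_data,test_data named lists of `list(volume, labels)` pairs,
#'   e.g. from [generate_phantoms()].
#' @param toggles data frame with logical columns `use_shallow`,
#'   `use_locator`, `use_fpn`; defaults to the four rows ablating each
#'   choice from the full strategy.
#' @param seed shared seed for every configuration.
#' @param base_channels network width used for all rows.
#' @param epochs,locator_epochs training lengths; `epochs` counts passes
#'   over the margin-crop set.
#' @param match_steps when `TRUE` (default), arms that train on a
#'   different-sized set (the whole-slice arm sees every slice, the
#'   cascade arms only the tumor crops) get their epoch count rescaled so
#'   all arms take the same number of optimizer steps — the toggle then
#'   compares pipelines at matched optimization budget rather than
#'   matched passes over unequal datasets.
#' @param window,margin preprocessing parameters.
#' @param verbose print progress.
#' @return Data frame: toggle columns plus volume-level pooled `dice` and
#'   `jaccard` on the held-out volumes.
#' @export
run_ablation <- function(train_data, test_data,
                         toggles = data.frame(
                           use_shallow = c(TRUE, TRUE, TRUE, FALSE),
                           use_locator = c(TRUE, FALSE, TRUE, TRUE),
                           use_fpn = c(TRUE, TRUE, FALSE, TRUE)),
                         seed = 1L, base_channels = 16L,
                         epochs = 8L, locator_epochs = 20L,
                         match_steps = TRUE,
                         window = window_spec(), margin = 10L,
                         verbose = FALSE) {
  if (nrow(toggles) < 1) stop("empty configuration grid", call. = FALSE)
  need <- c("use_shallow", "use_locator", "use_fpn")
  if (!all(need %in% names(toggles))) {
    stop("`toggles` needs columns use_shallow, use_locator, use_fpn",
         call. = FALSE)
  }
  train_slices <- dataset_slices(train_data, window)
  tumor_slices <- Filter(function(s) s$has_tumor, train_slices)
  loc <- NULL
  if (any(toggles$use_locator)) {
    if (verbose) message("training shared locator")
    loc <- train_locator(train_slices,
                         grid_detector_config(score_threshold = 0.35),
                         train_config(epochs = locator_epochs, seed = seed))
  }
  crops <- oracle_crops(tumor_slices, margin)
  res <- toggles
  res$dice <- res$jaccard <- NA_real_
  for (r in seq_len(nrow(toggles))) {
    tg <- toggles[r, ]
    if (verbose) {
      message(sprintf("ablation row %d: shallow=%s locator=%s fpn=%s",
                      r, tg$use_shallow, tg$use_locator, tg$use_fpn))
    }
    scfg <- segnet_config(base_channels = base_channels,
                          depth = if (tg$use_shallow) 3L else 4L,
                          fpn_channels = 2L * base_channels,
                          use_fpn = tg$use_fpn)
    # the no-locator arm has no slice-selection mechanism, so its training
    # set is every slice its pipeline sees; pre-filtering slices by the
    # ground-truth tumor flag would inject localization supervision by
    # hand (see the methods vignette)
    train_set <- if (tg$use_locator) {
      crops
    } else {
      lapply(train_slices, function(s) list(image = s$image, mask = s$mask))
    }
    arm_epochs <- epochs
    if (match_steps && !tg$use_locator) {
      arm_epochs <- max(1L, as.integer(round(
        epochs * length(crops) / length(train_set))))
    }
    seg0 <- build_segnet(scfg, seed = seed)
    tr <- train_segnet(seg0, train_set, NULL,
                       train_config(epochs = arm_epochs, seed = seed))
    cfg <- cascade_config(window = window, margin = margin,
                          detector_mode = if (tg$use_locator) "grid"
                                          else "whole_slice")
    preds <- truths <- list()
    for (id in names(test_data)) {
      vp <- run_cascade(test_data[[id]]$volume, test_data[[id]]$labels,
                        if (tg$use_locator) loc$model, tr$model, cfg,
                        volume_id = id)
      lab <- test_data[[id]]$labels$data
      for (k in seq_len(dim(lab)[1])) {
        preds[[length(preds) + 1L]] <- vp$mask[k, , ]
        truths[[length(truths) + 1L]] <- lab[k, , ]
      }
    }
    # pooled (volume-level) metrics: false positives on tumor-free slices
    # must count against a configuration, or removing the locator would
    # be costless by construction
    rep <- evaluate(preds, truths, policy = "pooled")
    res$dice[r] <- rep$aggregate[["dice"]]
    res$jaccard[r] <- rep$aggregate[["jaccard"]]
  }
  res
}
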