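#' Training protocol configuration
#'
#' Small-batch stochastic gradient descent with momentum, at the constants
#' used throughout: learning rate 0.01, momentum 0.9, weight decay 0.0005,
#' batch size 2, 100 epochs (reduce `epochs` for desk-scale runs).
#'
#' @param lr learning rate (> 0).
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param weight_decay L2 weight decay (>= 0).
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size samples per optimizer step (>= 1).
#' @param seed integer seed driving shuffling (and any augmentation).
#' @param eval_every iterations between IoU evaluations on the eval set.
#' @param clip_norm global gradient-norm ceiling per step (`Inf` disables);
#'   a numerical safeguard against occasional exploding SGD steps.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 5e-4,
                         epochs = 100L, batch_size = 2L, seed = 1L,
                         eval_every = 50L, clip_norm = 5) {
  if (lr <= 0) stop("`lr` must be > 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("`momentum` must be in [0, 1)", call. = FALSE)
  if (weight_decay < 0) stop("`weight_decay` must be >= 0", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 clip_norm = clip_norm),
            class = "train_config")
}

#' Pixelwise cross-entropy loss
#'
#' `L = -sum_i p(x_i) log q(x_i)` per pixel, with `q` the softmax of the
#' logits and `p` the one-hot true distribution, averaged over pixels.
#' Computed in log-softmax form for numerical stability. An optional class
#' weight vector is supported but off (uniform) by default: the loss is
#' unweighted despite the tumor/background imbalance.
#'
#' @param logits `(H, W, n_classes)` array.
#' @param target integer matrix of 0-based class indices (`H x W`).
#' @param class_weights optional length-`n_classes` weights.
#' @return Scalar loss (mean over pixels).
#' @export
cross_entropy_loss <- function(logits, target, class_weights = NULL) {
  logits <- as_hwc(logits)
  target <- as.matrix(target)
  nc <- dim(logits)[3]
  if (any(target < 0) || any(target >= nc)) {
    stop("target classes must be in [0, n_classes)", call. = FALSE)
  }
  m <- apply(logits, c(1, 2), max)
  lse <- m + log(apply(exp(logits - array(m, dim = dim(logits))), c(1, 2), sum))
  idx <- cbind(as.vector(row(target)), as.vector(col(target)),
               as.vector(target) + 1L)
  nll <- as.vector(lse) - logits[idx]
  if (!is.null(class_weights)) {
    w <- class_weights[as.vector(target) + 1L]
    sum(w * nll) / sum(w)
  } else {
    mean(nll)
  }
}

# Loss gradient w.r.t. logits: (softmax - onehot) / n_pixels.
cross_entropy_grad <- function(logits, target, class_weights = NULL) {
  logits <- as_hwc(logits)
  target <- as.matrix(target)
  q <- softmax_probs(logits)
  idx <- cbind(as.vector(row(target)), as.vector(col(target)),
               as.vector(target) + 1L)
  g <- q
  g[idx] <- g[idx] - 1
  if (!is.null(class_weights)) {
    w <- matrix(class_weights[as.vector(target) + 1L], nrow(target))
    g * array(w, dim = dim(g)) / sum(w)
  } else {
    g / length(target)
  }
}

# Prepare one training sample for the network: image scaled to [0, 1],
# reflect-padded (with its mask) to a multiple of 2^depth.
prep_seg_sample <- function(image, mask, depth, bit_top = 255) {
  pm <- pad_to_multiple(image / bit_top, 2^depth)
  tm <- pad_to_multiple(mask, 2^depth)
  list(x = pm$image, target = tm$image, pad = pm$pad,
       orig = dim(as.matrix(image)))
}

#' Train the segmentation network
#'
#' SGD with momentum and weight decay; gradients are averaged over each
#' mini-batch. Shuffling is deterministic given `cfg$seed`, so two runs
#' with the same configuration produce identical loss sequences. The mean
#' loss is recorded per epoch, and the tumor-class IoU on `eval_samples`
#' (pixel counts pooled over the eval set) every `eval_every` iterations.
#'
#' @param model a `seg_model` from [build_segnet()] (possibly already
#'   trained: training resumes from the given parameters).
#' @param train_samples list of `list(image, mask)` crops; images in the
#'   windowed bit range, masks binary.
#' @param eval_samples optional held-out list in the same format.
#' @param cfg a [train_config()].
#' @param stop_at_accuracy optional early-stop: training halts once the
#'   per-pixel training accuracy (checked each epoch) reaches this value.
#' @param verbose print epoch summaries.
#' @return `list(model, history)`; `history` is a `train_history` with one
#'   row per recorded event.
#' @export
train_segnet <- function(model, train_samples, eval_samples = NULL,
                         cfg = train_config(), stop_at_accuracy = NULL,
                         verbose = FALSE) {
  if (length(train_samples) == 0) stop("empty training set", call. = FALSE)
  d <- model$config$depth
  prepped <- lapply(train_samples, function(s) {
    prep_seg_sample(s$image, s$mask, d)
  })
  prepped_eval <- lapply(eval_samples %||% list(), function(s) {
    prep_seg_sample(s$image, s$mask, d)
  })
  state <- sgd_state(model$params)
  hist <- list()
  iter <- 0L
  eval_iou <- function() {
    if (length(prepped_eval) == 0) return(NA_real_)
    inter <- uni <- 0
    for (s in prepped_eval) {
      pm <- predict_mask(segnet_forward(model, s$x))
      inter <- inter + sum(pm == 1 & s$target == 1)
      uni <- uni + sum(pm == 1 | s$target == 1)
    }
    if (uni == 0) NA_real_ else inter / uni
  }
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(prepped))
      losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        grads <- zero_grads(model$params)
        bl <- 0
        for (i in b) {
          s <- prepped[[i]]
          fw <- segnet_forward(model, s$x, want_cache = TRUE)
          bl <- bl + cross_entropy_loss(fw$logits, s$target)
          dlog <- cross_entropy_grad(fw$logits, s$target)
          grads <- add_grads(grads, segnet_backward(model, fw$cache, dlog),
                             scale = 1 / length(b))
        }
        grads <- clip_grads(grads, cfg$clip_norm)
        st <- sgd_step(model$params, grads, state, cfg$lr, cfg$momentum,
                       cfg$weight_decay)
        model$params <- st$params
        state <- st$state
        iter <- iter + 1L
        losses <- c(losses, bl / length(b))
        if (length(prepped_eval) > 0 && iter %% cfg$eval_every == 0L) {
          hist[[length(hist) + 1L]] <- data.frame(
            iteration = iter, epoch = ep, loss = mean(losses),
            eval_iou = eval_iou(), event = "eval")
        }
      }
      hist[[length(hist) + 1L]] <- data.frame(
        iteration = iter, epoch = ep, loss = mean(losses),
        eval_iou = NA_real_, event = "epoch")
      if (verbose) {
        message(sprintf("epoch %3d  iter %5d  loss %.5f", ep, iter,
                        mean(losses)))
      }
      if (!is.null(stop_at_accuracy)) {
        acc <- train_accuracy(model, prepped)
        if (acc >= stop_at_accuracy) break
      }
    }
  })
  history <- do.call(rbind, hist)
  class(history) <- c("train_history", class(history))
  list(model = model, history = history)
}

train_accuracy <- function(model, prepped) {
  ok <- tot <- 0
  for (s in prepped) {
    pm <- predict_mask(segnet_forward(model, s$x))
    ok <- ok + sum(pm == s$target)
    tot <- tot + length(pm)
  }
  ok / tot
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the IoU convergence curve from a training history
#'
#' Returns the `(iteration, IoU)` pairs recorded during training — the
#' tumor-class Jaccard index on the evaluation set — suitable for plotting
#' the convergence trend.
#'
#' @param history a `train_history` from [train_segnet()].
#' @return Data frame with columns `iteration` and `iou`.
#' @export
iou_of_history <- function(history) {
  if (is.null(history) || nrow(history) == 0) {
    stop("empty training history", call. = FALSE)
  }
  ev <- history[history$event == "eval" & !is.na(history$eval_iou), ,
                drop = FALSE]
  data.frame(iteration = ev$iteration, iou = ev$eval_iou)
}

#' Write a training history to CSV
#'
#' @param history a `train_history`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}
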