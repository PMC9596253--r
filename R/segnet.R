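#' Segmentation network configuration
#'
#' Architecture of the fine-segmentation stage: a shallow U-shaped
#' encoder-decoder (one stage fewer than the classic four-downsampling
#' U-Net, to limit overfitting on small tumor datasets) whose skip
#' connections are replaced by the merged maps of an embedded feature
#' pyramid. Encoder stage `s` has `base_channels * 2^s` channels; the
#' decoder mirrors it with bilinear 2x upsampling.
#'
#' @param base_channels first-stage width (default 64).
#' @param depth number of downsamplings (default 3; use 4 for the classic
#'   non-shallow U-Net in ablations).
#' @param n_classes output classes (default 2: background/tumor).
#' @param fpn_channels lateral width of the feature pyramid (default 128).
#' @param fpn_fusion how merged pyramid maps enter the decoder:
#'   `"concat_into_skip"` (default) concatenates them with the upsampled
#'   decoder features; `"add_into_skip"` projects them to the decoder width
#'   and adds pixel-by-pixel.
#' @param use_fpn set `FALSE` for plain U-Net skip connections (ablation).
#' @param in_channels input channels (3: grayscale replicated).
#' @return An object of class `segnet_config`.
#' @export
segnet_config <- function(base_channels = 64L, depth = 3L, n_classes = 2L,
                          fpn_channels = 128L,
                          fpn_fusion = c("concat_into_skip", "add_into_skip"),
                          use_fpn = TRUE, in_channels = 3L) {
  fpn_fusion <- match.arg(fpn_fusion)
  if (depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  if (base_channels < 1) stop("`base_channels` must be >= 1", call. = FALSE)
  if (n_classes < 2) stop("`n_classes` must be >= 2", call. = FALSE)
  structure(list(base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 n_classes = as.integer(n_classes),
                 fpn_channels = as.integer(fpn_channels),
                 fpn_fusion = fpn_fusion,
                 use_fpn = isTRUE(use_fpn),
                 in_channels = as.integer(in_channels)),
            class = "segnet_config")
}

seg_channels <- function(config) config$base_channels * 2^(0:config$depth)

#' Build the segmentation network
#'
#' Allocates and initializes all parameters (He-normal, deterministic given
#' `seed`). Encoder: `depth + 1` stages of two 3x3 conv + ReLU, 2x2 max
#' pooling between stages, channel width doubling per stage. Decoder:
#' `depth` steps of bilinear 2x upsampling, a 2x2 convolution halving the
#' channels, fusion with the (pyramid-merged) skip, then two 3x3 conv +
#' ReLU. A final 1x1 convolution maps to class logits.
#'
#' @param config a [segnet_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `seg_model`.
#' @export
build_segnet <- function(config = segnet_config(), seed = 1L) {
  stopifnot(inherits(config, "segnet_config"))
  d <- config$depth
  ch <- seg_channels(config)
  with_seed(seed, {
    p <- list()
    cin <- config$in_channels
    for (s in 0:d) {
      p[[paste0("enc_a_", s)]] <- init_conv(3, 3, cin, ch[s + 1])
      p[[paste0("enc_b_", s)]] <- init_conv(3, 3, ch[s + 1], ch[s + 1])
      cin <- ch[s + 1]
    }
    if (config$use_fpn) {
      for (s in 0:d) {
        p[[paste0("lat_", s)]] <- init_conv(1, 1, ch[s + 1], config$fpn_channels)
      }
    }
    skip_ch <- if (config$use_fpn) rep(config$fpn_channels, d) else ch[1:d]
    for (t in 0:(d - 1)) {
      p[[paste0("up_", t)]] <- init_conv(2, 2, ch[t + 2], ch[t + 1])
      if (config$fpn_fusion == "add_into_skip") {
        p[[paste0("proj_", t)]] <- init_conv(1, 1, skip_ch[t + 1], ch[t + 1])
        fused <- ch[t + 1]
      } else {
        fused <- ch[t + 1] + skip_ch[t + 1]
      }
      p[[paste0("dec_a_", t)]] <- init_conv(3, 3, fused, ch[t + 1])
      p[[paste0("dec_b_", t)]] <- init_conv(3, 3, ch[t + 1], ch[t + 1])
    }
    p[["out"]] <- init_conv(1, 1, ch[1], config$n_classes)
    structure(list(config = config, params = p), class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf(
    "<seg_model> depth %d, base %d, fpn %s, %s params\n",
    x$config$depth, x$config$base_channels,
    if (x$config$use_fpn) sprintf("%d (%s)", x$config$fpn_channels,
                                  x$config$fpn_fusion) else "off",
    format(n_params(x$params), big.mark = ",")))
  invisible(x)
}

#' Merge encoder maps into a feature pyramid
#'
#' Lateral 1x1 projections bring every bottom-up map to a common channel
#' width; starting from the coarsest level, each map is 2x-upsampled and
#' added pixel-by-pixel to the next finer lateral map, repeating until the
#' finest level. Spatial sizes are preserved per level.
#'
#' @param encoder_maps list of `(H, W, C)` arrays, finest to coarsest, with
#'   spatial sizes halving per level.
#' @param laterals list of lateral 1x1 conv parameters (one per level), as
#'   produced by [build_segnet()] (`lat_*` entries) or [init_conv()].
#' @return `list(levels = ...)` of merged maps, finest to coarsest, all at
#'   the lateral channel width.
#' @export
fpn_merge <- function(encoder_maps, laterals) {
  n <- length(encoder_maps)
  if (length(laterals) != n) stop("one lateral conv per level required", call. = FALSE)
  sz <- lapply(encoder_maps, function(m) dim(as_hwc(m))[1:2])
  for (k in seq_len(n - 1)) {
    if (!all(sz[[k + 1]] == floor(sz[[k]] / 2))) {
      stop("encoder maps must halve in spatial size per level", call. = FALSE)
    }
  }
  L <- lapply(seq_len(n), function(k) {
    nn_conv2d(encoder_maps[[k]], laterals[[k]]$w, laterals[[k]]$b)
  })
  M <- vector("list", n)
  M[[n]] <- L[[n]]
  if (n > 1) {
    for (k in (n - 1):1) M[[k]] <- L[[k]] + nn_upsample2(M[[k + 1]])
  }
  list(levels = M)
}

pad1 <- c(1L, 1L, 1L, 1L)
pad_2x2 <- c(0L, 1L, 0L, 1L)   # 2x2 kernel, pad bottom/right: size-preserving

#' Forward pass of the segmentation network
#'
#' Maps a 3-channel crop to per-pixel class logits at the input resolution.
#'
#' @param model a `seg_model`.
#' @param x `(H, W, 3)` array (or `(H, W)` grayscale, replicated), with H
#'   and W divisible by `2^depth` — pad first with [pad_to_multiple()].
#' @param want_cache keep intermediate activations for a backward pass.
#' @return `(H, W, n_classes)` logits array; with `want_cache`, a list
#'   `(logits, cache)`.
#' @export
segnet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  x <- as_hwc(x)
  if (dim(x)[3] == 1L && cfg$in_channels == 3L) {
    x <- array(rep(x, 3L), dim = c(dim(x)[1:2], 3L))
  }
  if (dim(x)[3] != cfg$in_channels) stop("wrong input channel count", call. = FALSE)
  if (any(dim(x)[1:2] %% 2^d != 0)) {
    stop("input H and W must be divisible by ", 2^d,
         "; pad with pad_to_multiple()", call. = FALSE)
  }
  A <- E <- vector("list", d + 1)   # stage inputs / outputs
  R1 <- vector("list", d + 1)
  Pidx <- vector("list", d)
  cur <- x
  for (s in 0:d) {
    A[[s + 1]] <- cur
    r1 <- nn_relu(nn_conv2d(cur, p[[paste0("enc_a_", s)]]$w,
                            p[[paste0("enc_a_", s)]]$b, pad1))
    e <- nn_relu(nn_conv2d(r1, p[[paste0("enc_b_", s)]]$w,
                           p[[paste0("enc_b_", s)]]$b, pad1))
    R1[[s + 1]] <- r1
    E[[s + 1]] <- e
    if (s < d) {
      pl <- nn_maxpool2(e)
      Pidx[[s + 1]] <- pl$idx
      cur <- pl$y
    }
  }
  if (cfg$use_fpn) {
    lat <- lapply(0:d, function(s) p[[paste0("lat_", s)]])
    M <- fpn_merge(E, lat)$levels
    skips <- M[1:d]
  } else {
    skips <- E[1:d]
  }
  Dstates <- vector("list", d + 1)  # Dstates[[t+1]] = decoder output at level t
  Dstates[[d + 1]] <- E[[d + 1]]
  U <- RU <- FU <- RD <- vector("list", d)
  cur <- E[[d + 1]]
  for (t in (d - 1):0) {
    u <- nn_upsample2(cur)
    ru <- nn_relu(nn_conv2d(u, p[[paste0("up_", t)]]$w,
                            p[[paste0("up_", t)]]$b, pad_2x2))
    sk <- skips[[t + 1]]
    if (cfg$fpn_fusion == "add_into_skip") {
      fused <- ru + nn_conv2d(sk, p[[paste0("proj_", t)]]$w,
                              p[[paste0("proj_", t)]]$b)
    } else {
      fused <- array(c(ru, sk), dim = c(dim(ru)[1:2], dim(ru)[3] + dim(sk)[3]))
    }
    r1d <- nn_relu(nn_conv2d(fused, p[[paste0("dec_a_", t)]]$w,
                             p[[paste0("dec_a_", t)]]$b, pad1))
    cur <- nn_relu(nn_conv2d(r1d, p[[paste0("dec_b_", t)]]$w,
                             p[[paste0("dec_b_", t)]]$b, pad1))
    U[[t + 1]] <- u; RU[[t + 1]] <- ru; FU[[t + 1]] <- fused; RD[[t + 1]] <- r1d
    Dstates[[t + 1]] <- cur
  }
  logits <- nn_conv2d(cur, p[["out"]]$w, p[["out"]]$b)
  if (!want_cache) return(logits)
  list(logits = logits,
       cache = list(x = x, A = A, R1 = R1, E = E, Pidx = Pidx, skips = skips,
                    U = U, RU = RU, FU = FU, RD = RD, Dstates = Dstates))
}

# Backward pass: returns parameter gradients for a given upstream gradient
# on the logits. Mirrors segnet_forward exactly; gradients into each
# encoder output accumulate from the pooling chain, the lateral pyramid
# path, the (possible) plain skip, and the bottleneck.
segnet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  d <- cfg$depth
  g <- list()

  bw <- nn_conv2d_bwd(cache$Dstates[[1]], p[["out"]]$w, dlogits)
  g[["out"]] <- list(w = bw$dw, b = bw$db)
  dD <- bw$dx
  dskips <- vector("list", d)
  for (t in 0:(d - 1)) {
    nm_a <- paste0("dec_a_", t); nm_b <- paste0("dec_b_", t)
    dz2 <- nn_relu_bwd(cache$Dstates[[t + 1]], dD)
    bw <- nn_conv2d_bwd(cache$RD[[t + 1]], p[[nm_b]]$w, dz2, pad1)
    g[[nm_b]] <- list(w = bw$dw, b = bw$db)
    dz1 <- nn_relu_bwd(cache$RD[[t + 1]], bw$dx)
    bw <- nn_conv2d_bwd(cache$FU[[t + 1]], p[[nm_a]]$w, dz1, pad1)
    g[[nm_a]] <- list(w = bw$dw, b = bw$db)
    dfused <- bw$dx
    if (cfg$fpn_fusion == "add_into_skip") {
      dru <- dfused
      nm_p <- paste0("proj_", t)
      bw <- nn_conv2d_bwd(cache$skips[[t + 1]], p[[nm_p]]$w, dfused)
      g[[nm_p]] <- list(w = bw$dw, b = bw$db)
      dskips[[t + 1]] <- bw$dx
    } else {
      cu <- dim(cache$RU[[t + 1]])[3]
      dru <- dfused[, , seq_len(cu), drop = FALSE]
      dskips[[t + 1]] <- dfused[, , -seq_len(cu), drop = FALSE]
    }
    nm_u <- paste0("up_", t)
    dzu <- nn_relu_bwd(cache$RU[[t + 1]], dru)
    bw <- nn_conv2d_bwd(cache$U[[t + 1]], p[[nm_u]]$w, dzu, pad_2x2)
    g[[nm_u]] <- list(w = bw$dw, b = bw$db)
    dD <- nn_upsample2_bwd(bw$dx)       # gradient w.r.t. D_{t+1}
  }
  dE <- lapply(cache$E, function(e) array(0, dim(e)))
  dE[[d + 1]] <- dE[[d + 1]] + dD       # bottleneck use
  if (cfg$use_fpn) {
    dM <- vector("list", d + 1)
    for (s in 0:(d - 1)) dM[[s + 1]] <- dskips[[s + 1]]
    dM[[d + 1]] <- array(0, dim(cache$E[[d + 1]])[c(1, 2)] |>
                           c(cfg$fpn_channels))
    for (s in 0:(d - 1)) {
      dM[[s + 2]] <- dM[[s + 2]] + nn_upsample2_bwd(dM[[s + 1]])
    }
    for (s in 0:d) {
      nm <- paste0("lat_", s)
      bw <- nn_conv2d_bwd(cache$E[[s + 1]], p[[nm]]$w, dM[[s + 1]])
      g[[nm]] <- list(w = bw$dw, b = bw$db)
      dE[[s + 1]] <- dE[[s + 1]] + bw$dx
    }
  } else {
    for (t in 0:(d - 1)) dE[[t + 1]] <- dE[[t + 1]] + dskips[[t + 1]]
  }
  for (s in d:0) {
    nm_a <- paste0("enc_a_", s); nm_b <- paste0("enc_b_", s)
    dz2 <- nn_relu_bwd(cache$E[[s + 1]], dE[[s + 1]])
    bw <- nn_conv2d_bwd(cache$R1[[s + 1]], p[[nm_b]]$w, dz2, pad1)
    g[[nm_b]] <- list(w = bw$dw, b = bw$db)
    dz1 <- nn_relu_bwd(cache$R1[[s + 1]], bw$dx)
    bw <- nn_conv2d_bwd(cache$A[[s + 1]], p[[nm_a]]$w, dz1, pad1,
                        need_dx = s > 0)
    g[[nm_a]] <- list(w = bw$dw, b = bw$db)
    if (s > 0) {
      hp <- dim(cache$E[[s]])[1]; wp <- dim(cache$E[[s]])[2]
      dE[[s]] <- dE[[s]] + nn_maxpool2_bwd(cache$Pidx[[s]], bw$dx, hp, wp)
    }
  }
  g
}

#' Per-pixel class probabilities
#'
#' Numerically stable softmax over the channel dimension of a logits array.
#'
#' @param logits `(H, W, C)` array.
#' @return `(H, W, C)` array of probabilities summing to 1 per pixel.
#' @export
softmax_probs <- function(logits) {
  logits <- as_hwc(logits)
  m <- apply(logits, c(1, 2), max)
  e <- exp(logits - array(m, dim = dim(logits)))
  s <- apply(e, c(1, 2), sum)
  e / array(s, dim = dim(logits))
}

#' Decide the binary tumor mask from logits
#'
#' Softmax over the two channels; a pixel is tumor where the tumor-class
#' probability strictly exceeds 0.5, so an exact tie goes to background
#' (conservative against false positives).
#'
#' @param logits `(H, W, 2)` logits array.
#' @return Binary integer matrix of the same spatial size.
#' @export
predict_mask <- function(logits) {
  logits <- as_hwc(logits)
  if (dim(logits)[3] != 2L) {
    stop("expected 2 channels (background, tumor)", call. = FALSE)
  }
  p_tumor <- 1 / (1 + exp(logits[, , 1] - logits[, , 2]))
  matrix(as.integer(p_tumor > 0.5), dim(logits)[1], dim(logits)[2])
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with the architecture config embedded, so a load
#' reconstructs the model without external information.
#'
#' @param model a `seg_model` or `grid_detector`.
#' @param path checkpoint path (`.rds`).
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
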