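# Primitive differentiable operations over (H, W, C) arrays, backed by the
# compiled im2col/GEMM kernels. These are internal: the segmentation and
# detection networks are wired together from them by explicit
# forward/backward passes (no autodiff).

as_hwc <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    array(as.numeric(x), dim = c(dim(as.matrix(x)), 1L))
  } else if (length(d) == 3L) {
    storage.mode(x) <- "double"
    x
  } else {
    stop("expected a 2-D or 3-D array", call. = FALSE)
  }
}

# pad = c(top, bottom, left, right); zero padding.
nn_conv2d <- function(x, w, b, pad = c(0L, 0L, 0L, 0L)) {
  cc_conv2d_fwd(as_hwc(x), w, b, as.integer(pad))
}

nn_conv2d_bwd <- function(x, w, dy, pad = c(0L, 0L, 0L, 0L), need_dx = TRUE) {
  cc_conv2d_bwd(as_hwc(x), w, as_hwc(dy), as.integer(pad), need_dx)
}

nn_relu <- function(x) {
  x[x < 0] <- 0
  x
}

nn_relu_bwd <- function(y, dy) {
  dy[y <= 0] <- 0
  dy
}

# leaky variant (slope 0.1), used in the detector backbone where plain
# ReLUs are prone to dying under the sparse objectness gradients
nn_lrelu <- function(x, slope = 0.1) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

nn_lrelu_bwd <- function(y, dy, slope = 0.1) {
  dy[y < 0] <- slope * dy[y < 0]
  dy
}

nn_maxpool2 <- function(x) cc_maxpool2_fwd(as_hwc(x))

nn_maxpool2_bwd <- function(idx, dy, H, W) {
  cc_maxpool2_bwd(idx, as_hwc(dy), as.integer(H), as.integer(W))
}

nn_upsample2 <- function(x) cc_upsample2_fwd(as_hwc(x))

nn_upsample2_bwd <- function(dy) cc_upsample2_bwd(as_hwc(dy))

# Kaiming (He) normal initialization for a conv layer feeding a ReLU.
init_conv <- function(kh, kw, c_in, c_out) {
  fan_in <- kh * kw * c_in
  list(
    w = array(rnorm(kh * kw * c_in * c_out, sd = sqrt(2 / fan_in)),
              dim = c(kh, kw, c_in, c_out)),
    b = numeric(c_out)
  )
}

# --- SGD with momentum and decoupled-from-nothing classic weight decay ----
# v <- momentum * v + (g + weight_decay * p);  p <- p - lr * v
sgd_state <- function(params) {
  lapply(params, function(p) list(w = array(0, dim(p$w)), b = numeric(length(p$b))))
}

sgd_step <- function(params, grads, state, lr, momentum, weight_decay) {
  for (nm in names(params)) {
    gw <- grads[[nm]]$w + weight_decay * params[[nm]]$w
    gb <- grads[[nm]]$b + weight_decay * params[[nm]]$b
    state[[nm]]$w <- momentum * state[[nm]]$w + gw
    state[[nm]]$b <- momentum * state[[nm]]$b + gb
    params[[nm]]$w <- params[[nm]]$w - lr * state[[nm]]$w
    params[[nm]]$b <- params[[nm]]$b - lr * state[[nm]]$b
  }
  list(params = params, state = state)
}

# Global-norm gradient clipping: if the joint L2 norm of all gradients
# exceeds `max_norm`, scale them down to it. Guards plain SGD against the
# occasional exploding step without touching healthy updates.
clip_grads <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g$w^2) + sum(g$b^2),
                           numeric(1))))
  if (!is.finite(total)) {
    stop("non-finite gradient encountered; training diverged", call. = FALSE)
  }
  if (total > max_norm) {
    sc <- max_norm / total
    grads <- lapply(grads, function(g) list(w = g$w * sc, b = g$b * sc))
  }
  grads
}

zero_grads <- function(params) {
  lapply(params, function(p) list(w = array(0, dim(p$w)), b = numeric(length(p$b))))
}

add_grads <- function(acc, g, scale = 1) {
  for (nm in names(g)) {
    acc[[nm]]$w <- acc[[nm]]$w + scale * g[[nm]]$w
    acc[[nm]]$b <- acc[[nm]]$b + scale * g[[nm]]$b
  }
  acc
}

n_params <- function(params) {
  sum(vapply(params, function(p) length(p$w) + length(p$b), numeric(1)))
}
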