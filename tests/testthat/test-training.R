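test_that("cross-entropy matches direct evaluation on hand-built distributions", {
  # uniform prediction over 2 classes -> ln 2 per pixel
  lo <- array(0, dim = c(3, 3, 2))
  tgt <- matrix(sample(0:1, 9, replace = TRUE), 3, 3)
  expect_equal(cross_entropy_loss(lo, tgt), log(2), tolerance = 1e-12)

  # single pixel, q = (0.25, 0.75), true class = 2 -> -ln 0.75
  lo1 <- array(log(c(0.25, 0.75)), dim = c(1, 1, 2))
  expect_equal(cross_entropy_loss(lo1, matrix(1L)), -log(0.75),
               tolerance = 1e-6)

  # near-one-hot correct prediction -> loss ~ 0
  lo2 <- array(0, dim = c(2, 2, 2))
  t2 <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  for (i in 1:2) for (j in 1:2) lo2[i, j, t2[i, j] + 1L] <- 50
  expect_lt(cross_entropy_loss(lo2, t2), 1e-12)

  expect_error(cross_entropy_loss(lo, matrix(2L, 3, 3)), "classes")
})

test_that("loss is non-negative, shift-invariant, and zero only at one-hot truth", {
  set.seed(51)
  for (i in 1:20) {
    lo <- array(rnorm(4 * 4 * 2, sd = 3), dim = c(4, 4, 2))
    tgt <- matrix(rbinom(16, 1, 0.5), 4, 4)
    l <- cross_entropy_loss(lo, tgt)
    expect_gte(l, 0)
    shift <- array(rep(rnorm(16, sd = 5), 2), dim = c(4, 4, 2))
    expect_equal(cross_entropy_loss(lo + shift, tgt), l, tolerance = 1e-6)
    expect_gt(l, 0)   # random logits never exactly one-hot
  }
})

test_that("loss gradient matches finite differences", {
  set.seed(52)
  lo <- array(rnorm(3 * 3 * 2), dim = c(3, 3, 2))
  tgt <- matrix(rbinom(9, 1, 0.5), 3, 3)
  g <- ctcascade:::cross_entropy_grad(lo, tgt)
  eps <- 1e-6
  for (k in sample(length(lo), 6)) {
    lp <- lo; lp[k] <- lp[k] + eps
    lm <- lo; lm[k] <- lm[k] - eps
    num <- (cross_entropy_loss(lp, tgt) - cross_entropy_loss(lm, tgt)) / (2 * eps)
    expect_equal(g[k], num, tolerance = 1e-5)
  }
})

test_that("one SGD step with zero momentum and decay is vanilla gradient descent", {
  set.seed(53)
  m <- build_segnet(segnet_config(base_channels = 2, fpn_channels = 4), seed = 53)
  x <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  tgt <- matrix(rbinom(64, 1, 0.3), 8, 8)
  fw <- segnet_forward(m, x, want_cache = TRUE)
  gr <- ctcascade:::segnet_backward(m, fw$cache,
                                    ctcascade:::cross_entropy_grad(fw$logits, tgt))
  st <- ctcascade:::sgd_step(m$params, gr, ctcascade:::sgd_state(m$params),
                             lr = 0.05, momentum = 0, weight_decay = 0)
  for (nm in names(m$params)) {
    expect_equal(st$params[[nm]]$w, m$params[[nm]]$w - 0.05 * gr[[nm]]$w)
    expect_equal(st$params[[nm]]$b, m$params[[nm]]$b - 0.05 * gr[[nm]]$b)
  }
  # and the loss decreases at a small enough learning rate
  l0 <- cross_entropy_loss(fw$logits, tgt)
  m1 <- m
  small <- ctcascade:::sgd_step(m$params, gr, ctcascade:::sgd_state(m$params),
                                lr = 1e-4, momentum = 0, weight_decay = 0)
  m1$params <- small$params
  expect_lt(cross_entropy_loss(segnet_forward(m1, x), tgt), l0)
})

test_that("training descends on an overfit run and is seed-reproducible", {
  ph <- tiny_phantom(seed = 3, noise_sd = 3, irregularity = 0.2)
  sl <- extract_slices(ph$volume, ph$labels, window_spec())
  crops <- ctcascade:::oracle_crops(Filter(function(s) s$has_tumor, sl))[1:2]
  m <- build_segnet(segnet_config(base_channels = 4, fpn_channels = 8), seed = 1)
  cfg <- train_config(epochs = 25, seed = 7, eval_every = 10)
  tr1 <- train_segnet(m, crops, crops, cfg)
  ep <- tr1$history[tr1$history$event == "epoch", ]
  expect_lt(tail(ep$loss, 1), ep$loss[1])
  expect_true(all(is.finite(tr1$history$loss)))

  tr2 <- train_segnet(m, crops, crops, cfg)
  expect_identical(tr1$history, tr2$history)       # bit-identical rerun
  expect_identical(tr1$model$params, tr2$model$params)

  expect_error(train_segnet(m, list(), NULL, cfg), "empty")
})

test_that("iou history exposes the convergence curve consistently", {
  ph <- tiny_phantom(seed = 5, noise_sd = 3, irregularity = 0.2)
  sl <- extract_slices(ph$volume, ph$labels, window_spec())
  crops <- ctcascade:::oracle_crops(Filter(function(s) s$has_tumor, sl))
  m <- build_segnet(segnet_config(base_channels = 4, fpn_channels = 8), seed = 2)
  tr <- train_segnet(m, crops[1:2], crops[1:2],
                     train_config(epochs = 9, seed = 1, eval_every = 3))
  curve <- iou_of_history(tr$history)
  expect_gt(nrow(curve), 1)
  expect_true(all(curve$iou >= 0 & curve$iou <= 1))
  expect_true(all(diff(curve$iteration) > 0))

  # the recorded IoU is the tumor-class Jaccard of the current model's
  # predictions on the eval crops (recompute for the final state)
  pred <- lapply(crops[1:2], function(cr) {
    ctcascade:::segment_crop(tr$model, cr$image)
  })
  pooled <- evaluate(pred, lapply(crops[1:2], `[[`, "mask"),
                     policy = "pooled")
  expect_equal(tail(curve$iou, 1),
               unname(pooled$aggregate["jaccard"]), tolerance = 1e-9)

  expect_error(iou_of_history(NULL), "empty")
})
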