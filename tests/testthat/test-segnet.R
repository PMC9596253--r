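test_that("encoder widths double per stage from the base width", {
  cfg <- segnet_config()
  expect_equal(ctcascade:::seg_channels(cfg), c(64, 128, 256, 512))
  m <- build_segnet(cfg, seed = 1)
  for (s in 0:3) {
    expect_equal(dim(m$params[[paste0("enc_a_", s)]]$w)[4], 64 * 2^s)
  }
})

test_that("model construction is deterministic and platform-stable in size", {
  cfg <- segnet_config(base_channels = 4, fpn_channels = 8)
  a <- build_segnet(cfg, seed = 5)
  b <- build_segnet(cfg, seed = 5)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, build_segnet(cfg, seed = 6)$params))
  expect_equal(ctcascade:::n_params(a$params),
               ctcascade:::n_params(b$params))
})

test_that("forward maps (H, W, 3) to (H, W, 2) for divisible sizes", {
  m <- build_segnet(segnet_config(base_channels = 4, fpn_channels = 8), seed = 1)
  for (sz in list(c(64, 64), c(24, 40), c(8, 16))) {
    x <- array(runif(sz[1] * sz[2] * 3), dim = c(sz, 3))
    lo <- segnet_forward(m, x)
    expect_equal(dim(lo), c(sz, 2L))
  }
  expect_error(segnet_forward(m, array(0, dim = c(30, 32, 3))), "divisible")

  # grayscale input is replicated to the 3-channel convention
  g <- matrix(runif(64 * 64), 64, 64)
  expect_equal(dim(segnet_forward(m, g)), c(64L, 64L, 2L))
})

test_that("fpn_merge preserves spatial sizes and unifies channel widths", {
  set.seed(9)
  maps <- list(array(rnorm(16 * 16 * 4), dim = c(16, 16, 4)),
               array(rnorm(8 * 8 * 8), dim = c(8, 8, 8)),
               array(rnorm(4 * 4 * 16), dim = c(4, 4, 16)))
  lats <- lapply(c(4, 8, 16), function(cin) ctcascade:::init_conv(1, 1, cin, 6))
  fp <- fpn_merge(maps, lats)
  expect_length(fp$levels, 3)
  for (k in 1:3) {
    expect_equal(dim(fp$levels[[k]])[1:2], dim(maps[[k]])[1:2])
    expect_equal(dim(fp$levels[[k]])[3], 6L)
  }

  # single level: output is the lateral projection alone
  one <- fpn_merge(maps[1], lats[1])
  expect_equal(one$levels[[1]],
               ctcascade:::nn_conv2d(maps[[1]], lats[[1]]$w, lats[[1]]$b))

  # an all-zero coarsest map contributes nothing after a zero-bias lateral
  zlat <- list(ctcascade:::init_conv(1, 1, 4, 6),
               list(w = array(0, c(1, 1, 8, 6)), b = numeric(6)))
  two <- fpn_merge(list(maps[[1]], maps[[2]]), zlat)
  lone <- ctcascade:::nn_conv2d(maps[[1]], zlat[[1]]$w, zlat[[1]]$b)
  expect_equal(two$levels[[1]], lone)

  expect_error(fpn_merge(list(maps[[1]], maps[[1]]), lats[1:2]), "halve")
})

test_that("predict_mask applies the softmax decision rule with ties to background", {
  lo <- array(0, dim = c(2, 2, 2))
  expect_equal(predict_mask(lo), matrix(0L, 2, 2))   # exact tie -> background
  lo[1, 1, ] <- c(-5, 5)
  lo[2, 2, ] <- c(3, -3)
  m <- predict_mask(lo)
  expect_equal(m[1, 1], 1L)
  expect_equal(m[2, 2], 0L)
  expect_error(predict_mask(array(0, dim = c(2, 2, 3))), "channels")

  set.seed(2)
  lg <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2))
  pr <- softmax_probs(lg)
  expect_equal(apply(pr, c(1, 2), sum), matrix(1, 4, 4), tolerance = 1e-6)
})

test_that("batched evaluation equals per-sample forward passes", {
  m <- build_segnet(segnet_config(base_channels = 4, fpn_channels = 8), seed = 2)
  x1 <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  x2 <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  l1 <- segnet_forward(m, x1)
  l2 <- segnet_forward(m, x2)
  # recompute in the other order: results identical, no cross-sample state
  expect_equal(segnet_forward(m, x2), l2)
  expect_equal(segnet_forward(m, x1), l1)
})

test_that("fusion modes and plain-skip ablation run and differ", {
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  for (cfg in list(segnet_config(4, fpn_channels = 8),
                   segnet_config(4, fpn_channels = 8,
                                 fpn_fusion = "add_into_skip"),
                   segnet_config(4, use_fpn = FALSE),
                   segnet_config(4, depth = 4L, fpn_channels = 8))) {
    m <- build_segnet(cfg, seed = 3)
    lo <- segnet_forward(m, x)
    expect_equal(dim(lo), c(16L, 16L, 2L))
  }
})

test_that("analytic gradients match finite differences through the full network", {
  set.seed(12)
  m <- build_segnet(segnet_config(base_channels = 2, fpn_channels = 4), seed = 12)
  x <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  tgt <- matrix(rbinom(64, 1, 0.3), 8, 8)
  fw <- segnet_forward(m, x, want_cache = TRUE)
  gr <- ctcascade:::segnet_backward(m, fw$cache,
                                    ctcascade:::cross_entropy_grad(fw$logits, tgt))
  eps <- 1e-5
  for (nm in c("enc_a_0", "enc_b_3", "lat_1", "up_0", "dec_a_2", "out")) {
    ks <- sample(length(m$params[[nm]]$w), 2)
    for (k in ks) {
      mp <- m; mp$params[[nm]]$w[k] <- mp$params[[nm]]$w[k] + eps
      mm <- m; mm$params[[nm]]$w[k] <- mm$params[[nm]]$w[k] - eps
      num <- (cross_entropy_loss(segnet_forward(mp, x), tgt) -
                cross_entropy_loss(segnet_forward(mm, x), tgt)) / (2 * eps)
      expect_equal(gr[[nm]]$w[k], num, tolerance = 1e-3)
    }
  }
})

test_that("checkpoints round-trip model and config", {
  m <- build_segnet(segnet_config(base_channels = 2, fpn_channels = 4), seed = 4)
  p <- tempfile(fileext = ".rds")
  save_model(m, p)
  m2 <- load_model(p)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
})
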