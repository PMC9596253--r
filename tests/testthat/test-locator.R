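test_that("focus transform is the documented lossless space-to-depth permutation", {
  x <- array(c(1, 3, 2, 4), dim = c(2, 2, 1))   # [[a,b],[c,d]] = [[1,2],[3,4]]
  y <- focus_transform(x)
  expect_equal(dim(y), c(1L, 1L, 4L))
  expect_equal(as.vector(y), c(1, 2, 3, 4))     # (ee, eo, oe, oo) parity order

  set.seed(21)
  x2 <- array(rnorm(8 * 6 * 3), dim = c(8, 6, 3))
  y2 <- focus_transform(x2)
  expect_equal(dim(y2), c(4L, 3L, 12L))
  expect_equal(sort(as.vector(y2)), sort(as.vector(x2)))  # permutation
  expect_equal(focus_inverse(y2), x2)                     # bijection
  expect_error(focus_transform(array(0, dim = c(3, 4, 1))), "even")
})

test_that("mosaic augmentation composes four samples consistently", {
  bgs <- replicate(4, slice_sample(matrix(10, 32, 32), matrix(0L, 32, 32)),
                   simplify = FALSE)
  m0 <- mosaic_augment(bgs, seed = 5)
  expect_false(m0$has_tumor)
  expect_length(m0$boxes, 0)
  expect_equal(sum(m0$mask), 0)

  # one solid box per quadrant-source sample, away from the seams
  smps <- list(rect_sample(y = 6:9, x = 6:9), rect_sample(y = 6:9, x = 22:25),
               rect_sample(y = 22:25, x = 6:9), rect_sample(y = 22:25, x = 22:25))
  mz <- mosaic_augment(smps, seed = 1)
  expect_true(mz$has_tumor)
  expect_gte(length(mz$boxes), 1)
  expect_equal(mz$has_tumor, sum(mz$mask) > 0)
  expect_identical(mz$boxes, mask_to_boxes(mz$mask))

  expect_identical(mosaic_augment(smps, seed = 9), mosaic_augment(smps, seed = 9))
  expect_error(mosaic_augment(smps[1:3]), "4 samples")
})

test_that("oracle detector returns ground-truth boxes with unit score", {
  s <- rect_sample()
  d <- oracle_detect(s)
  expect_length(d, 1)
  expect_equal(d[[1]]$score, 1.0)
  expect_identical(d[[1]]$box, s$boxes[[1]])
  expect_identical(d[[1]]$box, mask_to_boxes(s$mask)[[1]])

  bg <- slice_sample(matrix(0, 16, 16), matrix(0L, 16, 16))
  expect_length(oracle_detect(bg), 0)
  nomask <- slice_sample(matrix(0, 16, 16))
  expect_error(oracle_detect(nomask), "mask")
})

test_that("margin crop implements the 10-pixel expansion with clamping", {
  img <- matrix(seq_len(100 * 100), 100, 100)
  s <- slice_sample(img, matrix(0L, 100, 100))
  cr <- crop_with_margin(s, bounding_box(20, 30, 50, 60), margin = 10)
  expect_equal(unname(cr$offset), c(20, 10))
  expect_equal(dim(cr$image_crop), c(50L, 50L))
  expect_equal(cr$image_crop[1, 1], img[21, 11])

  cr2 <- crop_with_margin(s, bounding_box(0, 0, 5, 5), margin = 10)
  expect_equal(unname(cr2$offset), c(0, 0))
  expect_equal(dim(cr2$image_crop), c(15L, 15L))

  cr3 <- crop_with_margin(s, bounding_box(20, 30, 50, 60), margin = 0)
  expect_equal(dim(cr3$image_crop), c(30L, 30L))
  expect_equal(cr3$image_crop, img[31:60, 21:50])
  expect_error(crop_with_margin(s, bounding_box(1, 1, 3, 3), margin = -1),
               "margin")
})

test_that("crop/paste of the mask restricted to the window is exact", {
  set.seed(77)
  for (i in 1:10) {
    s <- rect_sample(y = sample(5:20, 1) + 0:4, x = sample(5:20, 1) + 0:5)
    b <- s$boxes[[1]]
    cr <- crop_with_margin(s, b, margin = sample(0:12, 1))
    canvas <- matrix(0L, nrow(s$mask), ncol(s$mask))
    rows <- cr$offset[["y_min"]] + seq_len(nrow(cr$mask_crop))
    cols <- cr$offset[["x_min"]] + seq_len(ncol(cr$mask_crop))
    canvas[rows, cols] <- cr$mask_crop
    expect_identical(canvas[rows, cols], s$mask[rows, cols])
    # margin >= 0 guarantees the component is inside the crop window
    expect_equal(sum(cr$mask_crop), sum(s$mask))
  }
})

test_that("detect respects threshold, ordering and box validity", {
  det <- build_grid_detector(grid_detector_config(), seed = 3)
  s <- rect_sample()
  cfg <- det$config
  cfg$score_threshold <- 1.01                   # unreachable
  expect_length(detect(det, s, cfg), 0)

  cfg$score_threshold <- 0
  ds <- detect(det, s, cfg)
  sc <- vapply(ds, `[[`, numeric(1), "score")
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(all(diff(sc) <= 0))               # sorted descending
  for (d in ds) {
    b <- d$box
    expect_true(b[["x_min"]] >= 0 && b[["x_max"]] <= ncol(s$image))
    expect_true(b[["y_min"]] >= 0 && b[["y_max"]] <= nrow(s$image))
    expect_true(b[["x_min"]] < b[["x_max"]] && b[["y_min"]] < b[["y_max"]])
  }
  tiny <- slice_sample(matrix(0, 4, 4), matrix(0L, 4, 4))
  expect_error(detect(det, tiny), "grid cell")
})

test_that("detector construction is seed-deterministic", {
  a <- build_grid_detector(grid_detector_config(), seed = 8)
  b <- build_grid_detector(grid_detector_config(), seed = 8)
  expect_identical(a$params, b$params)
  c <- build_grid_detector(grid_detector_config(), seed = 9)
  expect_false(identical(a$params, c$params))
})

test_that("locator training descends and overfits a small slice set", {
  ph <- generate_phantoms(3, phantom_spec(), seed = 5)
  sl <- list()
  for (id in names(ph)) {
    sl <- c(sl, extract_slices(ph[[id]]$volume, ph[[id]]$labels,
                               window_spec(), id))
  }
  tum <- Filter(function(s) s$has_tumor, sl)[1:8]
  bg <- Filter(function(s) !s$has_tumor, sl)[1:8]
  loc <- train_locator(c(tum, bg), grid_detector_config(),
                       train_config(epochs = 100, seed = 2), mosaic_prob = 0)
  h <- loc$history
  expect_true(all(is.finite(h$loss)))
  expect_lt(tail(h$obj_loss, 1), h$obj_loss[1])   # descent on objectness

  hits <- vapply(tum, function(s) length(detect(loc$model, s)) > 0, logical(1))
  expect_gte(mean(hits), 0.9)                     # slice-level recall on overfit

  # detections overlap the ground truth box
  ious <- vapply(tum, function(s) {
    ds <- detect(loc$model, s)
    if (length(ds) == 0) return(0)
    max(vapply(ds, function(d) ctcascade:::box_iou(d$box, s$boxes[[1]]),
               numeric(1)))
  }, numeric(1))
  expect_gt(mean(ious > 0.3), 0.5)
  expect_error(train_locator(list(), grid_detector_config()), "empty")
})
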