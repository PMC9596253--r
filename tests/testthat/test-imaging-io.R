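test_that("NIfTI volumes round-trip through write and read", {
  arr <- array(seq_len(4 * 8 * 8), dim = c(4L, 8L, 8L))
  vol <- ct_volume(arr, spacing = c(3, 1, 1))

  p1 <- tempfile(fileext = ".nii")
  write_volume(vol, p1)
  back <- read_volume(p1)
  expect_equal(back$data, arr, ignore_attr = TRUE)
  expect_equal(dim(back$data), c(4L, 8L, 8L))
  expect_equal(back$spacing, c(3, 1, 1), tolerance = 1e-6)

  p2 <- tempfile(fileext = ".nii.gz")
  write_volume(vol, p2)
  expect_equal(read_volume(p2)$data, back$data)   # compression transparent

  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  bad <- tempfile(fileext = ".nii")
  writeLines("this is not a nifti header", bad)
  expect_error(suppressWarnings(read_volume(bad)))
})

test_that("intensity windowing follows the clip-scale-round mapping", {
  w <- window_spec(level = 40, width = 400)
  v <- function(x) {
    vol <- ct_volume(array(x, dim = c(1, 1, 1)))
    apply_window(vol, w)$data[1, 1, 1]
  }
  expect_equal(v(40), 128)                 # center -> rounded midpoint
  expect_equal(v(-160), 0)                 # lower edge
  expect_equal(v(-500), 0)                 # below window clips
  expect_equal(v(240), 255)                # (240 + 160)/400 = 1 -> 255
  expect_equal(v(1000), 255)
  expect_error(window_spec(width = 0), "width")

  # monotone non-decreasing in the input
  xs <- seq(-300, 300, by = 7)
  ys <- vapply(xs, v, numeric(1))
  expect_true(all(diff(ys) >= 0))

  # idempotent under a full-scale re-window of already-windowed data
  vol <- ct_volume(array(runif(64, -200, 300), dim = c(4, 4, 4)))
  w8 <- apply_window(vol, w)
  again <- apply_window(w8, window_spec(level = 127.5, width = 255))
  expect_equal(again$data, w8$data)
})

test_that("mask_to_boxes finds tight 8-connected component boxes", {
  m <- matrix(0L, 8, 8)
  m[4:6, 3:5] <- 1L                        # rows 3-5, cols 2-4 in 0-based
  b <- mask_to_boxes(m)
  expect_length(b, 1)
  expect_equal(unclass(b[[1]]), c(x_min = 2L, y_min = 3L, x_max = 5L, y_max = 6L),
               ignore_attr = TRUE)

  expect_equal(mask_to_boxes(matrix(0L, 5, 5)), list())

  m2 <- matrix(0L, 8, 8); m2[1, 1] <- 1L; m2[8, 8] <- 1L
  b2 <- mask_to_boxes(m2)
  expect_length(b2, 2)
  expect_equal(b2[[1]][["x_max"]] - b2[[1]][["x_min"]], 1)

  # diagonal touching pixels are one 8-connected component
  m3 <- matrix(0L, 5, 5); m3[2, 2] <- 1L; m3[3, 3] <- 1L
  expect_length(mask_to_boxes(m3), 1)

  expect_error(mask_to_boxes(matrix(2L, 2, 2)), "binary")
})

test_that("every box is tight: covers its component and only foreground", {
  set.seed(31)
  for (i in 1:20) {
    m <- random_mask(16, 0.2)
    boxes <- mask_to_boxes(m)
    covered <- matrix(FALSE, 16, 16)
    for (b in boxes) {
      sub <- m[(b[["y_min"]] + 1):b[["y_max"]], (b[["x_min"]] + 1):b[["x_max"]],
               drop = FALSE]
      expect_gte(sum(sub), 1)              # box contains foreground
      covered[(b[["y_min"]] + 1):b[["y_max"]],
              (b[["x_min"]] + 1):b[["x_max"]]] <- TRUE
    }
    expect_true(all(covered[m > 0]))       # union of boxes covers the mask
  }
})

test_that("extract_slices flags exactly the tumor-bearing slices", {
  ph <- tiny_phantom()
  sl <- extract_slices(ph$volume, ph$labels, window_spec(), "t1")
  expect_length(sl, dim(ph$volume$data)[1])
  truth <- apply(ph$labels$data, 1, sum) > 0
  expect_equal(vapply(sl, `[[`, logical(1), "has_tumor"), unname(truth))
  empty <- label_volume(array(0L, dim = dim(ph$volume$data)))
  sl0 <- extract_slices(ph$volume, empty, window_spec())
  expect_true(all(vapply(sl0, function(s) length(s$boxes) == 0, logical(1))))

  # two disjoint blobs in one slice give two boxes
  lab <- array(0L, dim = c(3, 16, 16))
  lab[2, 2:4, 2:4] <- 1L
  lab[2, 10:12, 10:13] <- 1L
  vol <- ct_volume(array(100, dim = c(3, 16, 16)))
  sl2 <- extract_slices(vol, label_volume(lab), window_spec())
  expect_length(sl2[[2]]$boxes, 2)
  expect_error(extract_slices(vol, label_volume(array(0L, c(2, 16, 16)))),
               "shape")
})

test_that("slice export is lossless for PNG and masks, shape-safe for JPEG", {
  s <- rect_sample()
  d <- tempfile(); dir.create(d)
  p <- export_slice(s, d, "png")
  img <- round(png::readPNG(p) * 255)
  expect_equal(img, s$image, ignore_attr = TRUE)
  mask <- png::readPNG(file.path(d, sub("\\.png$", "_mask.png", basename(p))))
  expect_equal(round(mask), s$mask, ignore_attr = TRUE)

  pj <- export_slice(s, d, "jpg")
  jimg <- jpeg::readJPEG(pj)
  expect_equal(dim(jimg), dim(s$image))
})

test_that("dataset split is patient-level, disjoint, exhaustive, seeded", {
  ids <- sprintf("pat%02d", 1:70)
  sp <- split_dataset(ids, 0.8, seed = 3)
  expect_length(sp$train, 56)
  expect_length(sp$test, 14)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_dataset(ids, 0.8, seed = 3))
  expect_false(identical(sp, split_dataset(ids, 0.8, seed = 4)))

  sp5 <- split_dataset(letters[1:5], 0.8, seed = 1)
  expect_length(sp5$train, 4)
  expect_length(sp5$test, 1)
  expect_error(split_dataset(c("a", "a", "b"), 0.8, 1), "unique")
  expect_error(split_dataset(letters[1:4], 1.2, 1), "ratio")
})
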