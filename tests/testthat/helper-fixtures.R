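# Shared fixtures, all generated in code.

# A small deterministic phantom pair.
tiny_phantom <- function(seed = 11L, shape = c(10L, 32L, 32L),
                         noise_sd = 0, irregularity = 0) {
  generate_phantom(phantom_spec(shape = shape, tumor_radius = c(3, 4),
                                noise_sd = noise_sd,
                                irregularity = irregularity),
                   seed = seed)
}

# A slice sample with a rectangular tumor at known coordinates.
rect_sample <- function(H = 32L, W = 32L, y = 10:14, x = 8:13,
                        fg = 200, bg = 40) {
  img <- matrix(bg, H, W)
  msk <- matrix(0L, H, W)
  img[y, x] <- fg
  msk[y, x] <- 1L
  slice_sample(img, msk, volume_id = "rect", slice_index = 1L)
}

# Brute-force overlap metrics by explicit pixel loops: the independent
# oracle the fast implementations are checked against.
brute_metrics <- function(pred, truth) {
  vs <- vg <- inter <- uni <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] > 0
      g <- truth[i, j] > 0
      if (p) vs <- vs + 1
      if (g) vg <- vg + 1
      if (p && g) inter <- inter + 1
      if (p || g) uni <- uni + 1
    }
  }
  list(dice = if (vs + vg > 0) 2 * inter / (vs + vg) else NA_real_,
       jaccard = if (uni > 0) inter / uni else NA_real_,
       precision = if (vs > 0) inter / vs else NA_real_,
       recall = if (vg > 0) inter / vg else NA_real_)
}

random_mask <- function(n = 32L, p = 0.3) {
  matrix(rbinom(n * n, 1L, p), n, n)
}
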