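#' Synthetic CT phantom specification
#'
#' Parameters of the synthetic volumes used to exercise the cascade without
#' external data. Each phantom holds one ellipsoidal "organ" on a dark
#' background, with one or more small, bright, irregular tumor blobs placed
#' strictly inside the organ; tumors span only a minority of axial slices,
#' mirroring how small renal lesions appear in abdominal CT stacks.
#'
#' Default intensities (pre-window units): background 0-20, organ 80-120,
#' tumor 140-180, so the default abdominal window renders organ and tumor
#' clearly distinguishable while keeping the contrast learnable rather than
#' trivial against the noise floor.
#'
#' @param shape integer vector `(n_slices, H, W)`.
#' @param organ_intensity,tumor_intensity,background_intensity intensity
#'   intervals `(lo, hi)`; a per-volume constant is drawn from each.
#' @param tumor_radius in-plane tumor radius interval in pixels.
#' @param tumor_slice_fraction fraction of slices the tumor should span
#'   (controls the blob's through-plane extent).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param irregularity boundary perturbation amplitude in `[0, 1]`; 0 gives
#'   an exact discretized ellipsoid.
#' @param n_tumors number of tumor blobs per volume.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(16L, 64L, 64L),
                         organ_intensity = c(80, 120),
                         tumor_intensity = c(140, 180),
                         background_intensity = c(0, 20),
                         tumor_radius = c(3, 6),
                         tumor_slice_fraction = 0.3,
                         noise_sd = 5,
                         irregularity = 0.3,
                         n_tumors = 1L) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2]) {
      stop("`", nm, "` must be a (lo, hi) interval", call. = FALSE)
    }
  }
  if (length(shape) != 3L || any(shape < 1)) {
    stop("`shape` must be 3 positive integers", call. = FALSE)
  }
  chk_range(organ_intensity, "organ_intensity")
  chk_range(tumor_intensity, "tumor_intensity")
  chk_range(background_intensity, "background_intensity")
  chk_range(tumor_radius, "tumor_radius")
  if (!(tumor_slice_fraction > 0 && tumor_slice_fraction <= 1)) {
    stop("`tumor_slice_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (irregularity < 0 || irregularity > 1) {
    stop("`irregularity` must be in [0, 1]", call. = FALSE)
  }
  if (n_tumors < 1) stop("`n_tumors` must be >= 1", call. = FALSE)
  structure(list(shape = as.integer(shape),
                 organ_intensity = organ_intensity,
                 tumor_intensity = tumor_intensity,
                 background_intensity = background_intensity,
                 tumor_radius = tumor_radius,
                 tumor_slice_fraction = tumor_slice_fraction,
                 noise_sd = noise_sd,
                 irregularity = irregularity,
                 n_tumors = as.integer(n_tumors)),
            class = "phantom_spec")
}

# Organ ellipsoid semi-axes and center for a given shape: the organ fills
# most of the field of view so tumors have room strictly inside it.
organ_geometry <- function(shape) {
  list(center = (shape + 1) / 2,
       semi = c(0.46 * shape[1], 0.38 * shape[2], 0.38 * shape[3]))
}

# Normalized ellipsoid coordinate of every voxel relative to (center, semi).
ellipsoid_rho <- function(shape, center, semi) {
  dz <- (seq_len(shape[1]) - center[1]) / semi[1]
  dy <- (seq_len(shape[2]) - center[2]) / semi[2]
  dx <- (seq_len(shape[3]) - center[3]) / semi[3]
  outer(outer(dz^2, dy^2, `+`), dx^2, `+`)    # rho^2, dim (D, H, W)
}

#' Generate one synthetic phantom volume
#'
#' Deterministic given `seed`. The tumor support is a discretized spheroid
#' (in-plane radius drawn from `tumor_radius`, through-plane extent set by
#' `tumor_slice_fraction`) whose boundary is perturbed radially by a
#' low-order mixture of direction harmonics scaled by `irregularity`.
#' Tumor voxels always lie strictly inside the organ ellipsoid.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return `list(volume = ct_volume, labels = label_volume)`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    shape <- spec$shape
    geom <- organ_geometry(shape)
    rho2_organ <- ellipsoid_rho(shape, geom$center, geom$semi)
    organ <- rho2_organ <= 1

    bg <- runif(1, spec$background_intensity[1], spec$background_intensity[2])
    org <- runif(1, spec$organ_intensity[1], spec$organ_intensity[2])
    tum <- runif(1, spec$tumor_intensity[1], spec$tumor_intensity[2])

    data <- array(bg, dim = shape)
    data[organ] <- org
    labels <- array(0L, dim = shape)

    rz <- max(1, round(spec$tumor_slice_fraction * shape[1] / 2))
    for (t in seq_len(spec$n_tumors)) {
      r <- runif(1, spec$tumor_radius[1], spec$tumor_radius[2])
      # margin (in normalized organ units) that keeps the whole blob inside
      marg <- (1 + spec$irregularity * 0.35) *
        max(rz / geom$semi[1], r / geom$semi[2], r / geom$semi[3])
      if (marg >= 0.95) {
        stop("tumor radius too large for the organ at this volume shape",
             call. = FALSE)
      }
      # draw a center uniformly in the (normalized) ball that keeps the
      # whole blob strictly inside the organ
      dir <- rnorm(3)
      u <- dir / sqrt(sum(dir^2)) * (0.95 - marg) * runif(1)^(1 / 3)
      ctr <- geom$center + u * geom$semi

      rho2 <- ellipsoid_rho(shape, ctr, c(rz, r, r))
      thr <- 1
      if (spec$irregularity > 0) {
        # low-order angular perturbation of the boundary radius
        ph <- runif(3, 0, 2 * pi)
        a <- runif(3, 0.5, 1)
        dz <- slice_coord(shape, 1) - ctr[1]
        dy <- slice_coord(shape, 2) - ctr[2]
        dx <- slice_coord(shape, 3) - ctr[3]
        theta <- atan2(dy, dx)
        psi <- atan2(dz, sqrt(dx^2 + dy^2) + 1e-9)
        pert <- a[1] * sin(2 * theta + ph[1]) + a[2] * sin(3 * theta + ph[2]) +
          a[3] * sin(2 * psi + ph[3])
        thr <- (1 + spec$irregularity * 0.35 * pert / sum(a))^2
      }
      blob <- rho2 <= thr
      blob <- blob & organ                     # invariant: tumor inside organ
      data[blob] <- tum
      labels[blob] <- 1L
    }

    if (spec$noise_sd > 0) {
      data <- data + array(rnorm(length(data), sd = spec$noise_sd), dim = shape)
    }
    list(volume = ct_volume(data, spacing = c(3, 1, 1)),
         labels = label_volume(labels))
  })
}

# broadcast the coordinate along axis `ax` over the full (D, H, W) grid
slice_coord <- function(shape, ax) {
  v <- seq_len(shape[ax])
  if (ax == 1) array(v, dim = shape)
  else if (ax == 2) array(rep(v, each = shape[1]), dim = shape)
  else array(rep(v, each = shape[1] * shape[2]), dim = shape)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_volumes` phantom image/label NIfTI pairs plus a JSON manifest.
#' Per-volume seeds are derived reproducibly from the master seed, so the
#' same call regenerates byte-identical volumes.
#'
#' @param n_volumes number of volumes (>= 1).
#' @param spec a [phantom_spec()].
#' @param seed master seed.
#' @param out_dir output directory.
#' @return Path of the written manifest file.
#' @export
generate_dataset <- function(n_volumes, spec = phantom_spec(), seed = 1L,
                             out_dir) {
  if (n_volumes < 1) stop("`n_volumes` must be >= 1", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seeds <- derive_seeds(seed, n_volumes)
  entries <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    id <- sprintf("phantom%03d", i)
    ph <- generate_phantom(spec, seed = seeds[i])
    img_path <- file.path(out_dir, paste0(id, "_image.nii.gz"))
    lbl_path <- file.path(out_dir, paste0(id, "_label.nii.gz"))
    write_volume(ph$volume, img_path)
    write_volume(ph$labels, lbl_path)
    entries[[i]] <- list(volume_id = id, seed = seeds[i],
                         image = basename(img_path), label = basename(lbl_path))
  }
  manifest <- list(n_volumes = n_volumes, master_seed = seed,
                   shape = spec$shape, volumes = entries)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' In-memory phantom dataset
#'
#' Convenience wrapper generating `n_volumes` phantoms without touching
#' disk, for training and evaluation runs.
#'
#' @inheritParams generate_dataset
#' @return A named list of `list(volume, labels)` pairs keyed by volume id.
#' @export
generate_phantoms <- function(n_volumes, spec = phantom_spec(), seed = 1L) {
  seeds <- derive_seeds(seed, n_volumes)
  out <- lapply(seq_len(n_volumes), function(i) generate_phantom(spec, seeds[i]))
  names(out) <- sprintf("phantom%03d", seq_len(n_volumes))
  out
}
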