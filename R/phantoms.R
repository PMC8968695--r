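# Deterministic synthetic CT-like phantoms.
#
# Each volume contains one or two bright elliptic-cylinder "kidneys" extruded
# over a sub-interval of slices, each optionally embedding a circular-cylinder
# "tumor" whose disk sits strictly inside the kidney ellipse. Extruding 2D
# shapes (rather than using ellipsoids/spheres) keeps the per-slice tumor
# cross-section constant, so every connected tumor component on every slice
# honours tumor_area_range exactly. Additive Gaussian noise and sparse
# extreme-intensity artifact voxels emulate the outliers that percentile
# clipping is meant to remove.

#' Phantom generator configuration
#'
#' Defaults define the desk-scale study conditions used throughout the
#' package's tests: 96-pixel slices, one or two kidneys, tumors in 60-280 px
#' of cross-section area.
#'
#' @param image_size Pixels per side (>= 32).
#' @param n_slices Number of axial slices (>= 1).
#' @param kidney_count_range Integer range (lo, hi) within 1..2.
#' @param tumor_probability Probability that a kidney (volume generator) or a
#'   sample (slice-dataset generator) carries a tumor.
#' @param tumor_area_range (min, max) tumor cross-section area in pixels.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units, >= 0).
#' @param artifact_rate Per-voxel probability of an extreme-intensity
#'   artifact.
#' @param seed Integer seed; the generator is a pure function of the
#'   configuration including the seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 96, n_slices = 16,
                           kidney_count_range = c(1, 2),
                           tumor_probability = 0.7,
                           tumor_area_range = c(60, 280),
                           noise_sd = 8, artifact_rate = 5e-4, seed = 1) {
  if (!is_count(image_size) || image_size < 32) stopf("image_size must be an integer >= 32")
  if (!is_count(n_slices) || n_slices < 1) stopf("n_slices must be an integer >= 1")
  kidney_count_range <- as.integer(kidney_count_range)
  if (length(kidney_count_range) != 2 || any(kidney_count_range < 1) ||
      any(kidney_count_range > 2) || kidney_count_range[1] > kidney_count_range[2])
    stopf("kidney_count_range must be an integer range within 1..2")
  if (!(tumor_probability >= 0 && tumor_probability <= 1))
    stopf("tumor_probability must lie in [0, 1]")
  if (length(tumor_area_range) != 2 || any(tumor_area_range <= 0) ||
      tumor_area_range[1] > tumor_area_range[2])
    stopf("tumor_area_range must be positive with min <= max")
  if (!(noise_sd >= 0)) stopf("noise_sd must be >= 0")
  if (!(artifact_rate >= 0 && artifact_rate <= 1)) stopf("artifact_rate must lie in [0, 1]")
  structure(list(image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices),
                 kidney_count_range = kidney_count_range,
                 tumor_probability = tumor_probability,
                 tumor_area_range = as.numeric(tumor_area_range),
                 noise_sd = noise_sd, artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Pixel-set of a rotated filled ellipse on an s x s grid (logical matrix).
ellipse_mask <- function(s, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(s), s, s) - cy
  xx <- matrix(seq_len(s), s, s, byrow = TRUE) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

disk_mask <- function(s, cy, cx, r) {
  yy <- matrix(seq_len(s), s, s) - cy
  xx <- matrix(seq_len(s), s, s, byrow = TRUE) - cx
  yy^2 + xx^2 <= r^2
}

# Rasterized area of a disk of radius r centred on a lattice point
# (tumor centres are snapped to the lattice so this is exact).
disk_area_lattice <- function(r) {
  dy <- (-floor(r)):floor(r)
  sum(2 * floor(sqrt(pmax(0, r^2 - dy^2))) + 1)
}

# Radius whose lattice-rasterized area lies in [lo, hi] and is closest to
# `target`; NA when no radius below r_max is feasible.
disk_radius_for_area <- function(target, lo, hi, r_max) {
  if (r_max < 1) return(NA_real_)
  rs <- seq(1, r_max, by = 0.05)
  areas <- vapply(rs, disk_area_lattice, numeric(1))
  ok <- areas >= lo & areas <= hi
  if (!any(ok)) return(NA_real_)
  rs[ok][which.min(abs(areas[ok] - target))]
}

sample1 <- function(x) x[sample.int(length(x), 1)]

# Draw the per-volume geometry: kidneys (ellipse params, slice interval,
# intensity) and tumors (disk params, slice interval, intensity). Consumes the
# current RNG stream.
sample_geometry <- function(cfg, tumor_per_kidney = TRUE, force_tumor = FALSE) {
  s <- cfg$image_size
  n_k <- if (cfg$kidney_count_range[1] == cfg$kidney_count_range[2])
    cfg$kidney_count_range[1] else
    sample(cfg$kidney_count_range[1]:cfg$kidney_count_range[2], 1)
  sides <- if (n_k == 2) c(0.30, 0.70) else sample1(c(0.30, 0.70))
  tumor_in <- if (tumor_per_kidney) {
    runif(n_k) < cfg$tumor_probability
  } else {
    # one decision per sample: put a tumor in one random kidney
    has <- if (force_tumor) TRUE else runif(1) < cfg$tumor_probability
    idx <- sample.int(n_k, 1)
    seq_len(n_k) == idx & has
  }
  kidneys <- vector("list", n_k)
  for (i in seq_len(n_k)) {
    cx <- s * (sides[i] + runif(1, -0.03, 0.03))
    cy <- s * (0.5 + runif(1, -0.08, 0.08))
    a <- s * runif(1, 0.10, 0.15)
    b <- s * runif(1, 0.09, 0.13)
    theta <- runif(1, -pi / 4, pi / 4)
    z <- if (cfg$n_slices == 1) c(1L, 1L) else {
      len <- max(1L, as.integer(round(cfg$n_slices * runif(1, 0.4, 0.9))))
      z0 <- sample1(seq_len(cfg$n_slices - len + 1L))
      c(z0, z0 + len - 1L)
    }
    intensity <- 160 + runif(1, -10, 10)
    tumor <- NULL
    if (tumor_in[i]) {
      lo <- cfg$tumor_area_range[1]; hi <- cfg$tumor_area_range[2]
      r_cap <- min(a, b) - 1.5               # disk must fit inside the ellipse
      target <- runif(1, lo, hi)
      r <- disk_radius_for_area(target, lo, hi, r_cap)
      if (!is.na(r)) {
        kmask <- ellipse_mask(s, cy, cx, a, b, theta)
        zt <- if (z[1] == z[2]) z else {
          len <- max(1L, as.integer(round((z[2] - z[1] + 1L) * runif(1, 0.4, 0.9))))
          zt0 <- sample1(z[1]:(z[2] - len + 1L))
          c(zt0, zt0 + len - 1L)
        }
        bright <- runif(1) < 0.5
        t_int <- if (bright) 225 + runif(1, -8, 8) else 95 + runif(1, -8, 8)
        # rejection-sample an integer centre; the kidney centre itself always
        # fits (r <= min(a, b) - 1.5), so placement cannot fail
        cand <- matrix(round(c(cy + runif(60, -(b - r - 1), b - r - 1),
                               cx + runif(60, -(b - r - 1), b - r - 1))), ncol = 2)
        cand <- rbind(cand, round(c(cy, cx)))
        for (j in seq_len(nrow(cand))) {
          # containment is checked with a 1.5 px margin so the rendered tumor
          # never touches the kidney boundary
          dmask <- disk_mask(s, cand[j, 1], cand[j, 2], r + 1.5)
          if (sum(dmask) > 0 && all(kmask[dmask])) {
            tumor <- list(cy = cand[j, 1], cx = cand[j, 2], r = r, z = zt,
                          intensity = t_int)
            break
          }
        }
      }
    }
    kidneys[[i]] <- list(cy = cy, cx = cx, a = a, b = b, theta = theta,
                         z = z, intensity = intensity, tumor = tumor)
  }
  kidneys
}

render_slice <- function(cfg, kidneys, z, background = 30) {
  s <- cfg$image_size
  img <- matrix(background, s, s)
  lab <- matrix(0L, s, s)
  for (k in kidneys) {
    if (z < k$z[1] || z > k$z[2]) next
    kmask <- ellipse_mask(s, k$cy, k$cx, k$a, k$b, k$theta)
    img[kmask] <- k$intensity
    lab[kmask] <- 1L
    t <- k$tumor
    if (!is.null(t) && z >= t$z[1] && z <= t$z[2]) {
      dmask <- disk_mask(s, t$cy, t$cx, t$r)
      img[dmask] <- t$intensity
      lab[dmask] <- 2L
    }
  }
  if (cfg$noise_sd > 0) img <- img + rnorm(s * s, 0, cfg$noise_sd)
  if (cfg$artifact_rate > 0) {
    hit <- which(runif(s * s) < cfg$artifact_rate)
    if (length(hit) > 0)
      img[hit] <- sample(c(-500, 1500), length(hit), replace = TRUE)
  }
  list(image = img, label = lab)
}

#' Generate a synthetic phantom volume
#'
#' @param cfg A [phantom_config()].
#' @return A list with `image` and `label` arrays, both shaped
#'   `(n_slices, image_size, image_size)`. Labels are 0 background, 1 kidney,
#'   2 tumor; every tumor pixel lies spatially inside a kidney ellipse.
#'   Identical configurations (including seed) give bit-identical output.
#' @export
generate_phantom_volume <- function(cfg) {
  if (!inherits(cfg, "phantom_config")) stopf("cfg must be a phantom_config")
  with_seed(cfg$seed, {
    kidneys <- sample_geometry(cfg, tumor_per_kidney = TRUE)
    s <- cfg$image_size
    img <- array(0, c(cfg$n_slices, s, s))
    lab <- array(0L, c(cfg$n_slices, s, s))
    for (z in seq_len(cfg$n_slices)) {
      sl <- render_slice(cfg, kidneys, z)
      img[z, , ] <- sl$image
      lab[z, , ] <- sl$label
    }
    list(image = img, label = lab)
  })
}

#' Generate a dataset of 2D slice samples
#'
#' Each sample is an independent single-slice phantom guaranteed to contain
#' at least one kidney pixel (slices without kidney markers are discarded by
#' construction, mirroring the preprocessing rule). Tumor presence is decided
#' once per sample with probability `cfg$tumor_probability`, so the number of
#' tumor-bearing samples is Binomial(n, p).
#'
#' @param n Number of samples (>= 1).
#' @param cfg A [phantom_config()]; `n_slices` is ignored (each sample is one
#'   slice).
#' @return A list of `n` [slice_sample()] objects.
#' @export
generate_slice_dataset <- function(n, cfg = phantom_config()) {
  if (!is_count(n) || n < 1) stopf("n must be an integer >= 1")
  if (!inherits(cfg, "phantom_config")) stopf("cfg must be a phantom_config")
  cfg1 <- cfg
  cfg1$n_slices <- 1L
  with_seed(cfg$seed, {
    lapply(seq_len(n), function(i) {
      kid <- sample_geometry(cfg1, tumor_per_kidney = FALSE)
      sl <- render_slice(cfg1, kid, 1L)
      slice_sample(sl$image, sl$label,
                   case_id = sprintf("synthetic_%05d", i), slice_index = 0L)
    })
  })
}

#' Write a phantom volume as a KiTS19-style case directory
#'
#' Creates `<dir>/<case_id>/imaging.nii.gz` and `segmentation.nii.gz`.
#'
#' @param volume A list with `image` and `label` arrays as returned by
#'   [generate_phantom_volume()].
#' @param dir Output directory (created if missing).
#' @param case_id Case directory name, e.g. `"case_00000"`.
#' @return The case directory path, invisibly.
#' @export
write_phantom_case <- function(volume, dir, case_id) {
  case_dir <- file.path(dir, case_id)
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(volume$image, file.path(case_dir, "imaging.nii.gz"))
  RNifti::writeNifti(volume$label, file.path(case_dir, "segmentation.nii.gz"))
  invisible(case_dir)
}

#' Export a single slice as PNG
#'
#' Min-max scales the slice to `[0, 1]` and writes an 8-bit gray PNG.
#'
#' @param image 2D numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(image, path) {
  rng <- range(image)
  g <- if (rng[1] == rng[2]) matrix(0, nrow(image), ncol(image))
       else (image - rng[1]) / (rng[2] - rng[1])
  png::writePNG(g, path)
  invisible(path)
}
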