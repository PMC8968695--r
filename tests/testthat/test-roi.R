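test_that("mask component boxes are tight, per 8-connected component, size-ordered", {
  m <- matrix(0L, 100, 100)
  m[20:39, 30:59] <- 1L                 # 20x30 blob
  boxes <- mask_to_rois(m)
  expect_length(boxes, 1)
  expect_equal(unlist(boxes[[1]][c("row0", "col0", "row1", "col1")]),
               c(row0 = 19, col0 = 29, row1 = 39, col1 = 59))

  m[70:75, 70:75] <- 1L                 # second, smaller blob
  boxes <- mask_to_rois(m)
  expect_length(boxes, 2)
  expect_gt(boxes[[1]]$area, boxes[[2]]$area)

  # diagonal touch merges under 8-connectivity
  d <- matrix(0L, 10, 10)
  d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_length(mask_to_rois(d), 1)

  expect_length(mask_to_rois(matrix(0L, 5, 5)), 0)
})

test_that("component labeling agrees with the flood-fill oracle on random masks", {
  set.seed(8)
  for (rep in 1:10) {
    m <- matrix(runif(40 * 40) < 0.35, 40, 40)
    areas_pkg <- sort(tabulate(label_components(m)))
    areas_pkg <- areas_pkg[areas_pkg > 0]
    expect_equal(areas_pkg, sort(flood_fill_areas(m)))
  }
})

test_that("the window-expansion rule yields exactly 128 or 256 windows inside the canvas", {
  # worked example: tight 60x80 centred at (130,140) on a 512 canvas
  tight <- list(row0 = 100, col0 = 100, row1 = 160, col1 = 180)
  roi <- expand_roi(tight, 512)
  expect_equal(unlist(unclass(roi)),
               c(row0 = 66, col0 = 76, row1 = 194, col1 = 204, size_class = 128))

  # second clause: any side above 128 promotes to 256
  big <- list(row0 = 0, col0 = 0, row1 = 150, col1 = 140)
  expect_equal(expand_roi(big, 512)$size_class, 256)

  # corner box is translated flush with the border, still full size
  corner <- list(row0 = 0, col0 = 0, row1 = 100, col1 = 100)
  roic <- expand_roi(corner, 512)
  expect_equal(c(roic$row0, roic$col0), c(0, 0))
  expect_equal(roic$size_class, 128)

  # property: random tight boxes
  set.seed(13)
  for (rep in 1:100) {
    r0 <- sample(0:300, 1); c0 <- sample(0:300, 1)
    h <- sample(1:200, 1); w <- sample(1:200, 1)
    tb <- list(row0 = r0, col0 = c0, row1 = min(r0 + h, 512), col1 = min(c0 + w, 512))
    roi <- expand_roi(tb, 512)
    want <- if (tb$row1 - tb$row0 <= 128 && tb$col1 - tb$col0 <= 128) 128 else 256
    expect_equal(roi$size_class, want)
    expect_gte(roi$row0, 0); expect_gte(roi$col0, 0)
    expect_lte(roi$row1, 512); expect_lte(roi$col1, 512)
    if (roi$size_class >= max(tb$row1 - tb$row0, tb$col1 - tb$col0)) {
      expect_lte(roi$row0, tb$row0); expect_gte(roi$row1, tb$row1)
      expect_lte(roi$col0, tb$col0); expect_gte(roi$col1, tb$col1)
    }
  }
})

test_that("crop equals manual slicing and preserves label values", {
  set.seed(2)
  canvas <- matrix(rnorm(512 * 512), 512, 512)
  roi <- roi_box(66, 76, 194, 204, 128)
  expect_identical(crop_patch(canvas, roi), canvas[67:194, 77:204])

  lab <- matrix(sample(0:2, 512 * 512, TRUE), 512, 512)
  expect_true(all(crop_patch(lab, roi) %in% 0:2))
  expect_error(crop_patch(matrix(0, 100, 100), roi), "exceeds")
})

test_that("crop/paste round-trips hold on random boxes", {
  set.seed(17)
  for (rep in 1:100) {
    size <- sample(c(128, 256), 1)
    r0 <- sample(0:(512 - size), 1); c0 <- sample(0:(512 - size), 1)
    roi <- roi_box(r0, c0, r0 + size, c0 + size, size)
    canvas <- matrix(sample(0:2, 512 * 512, TRUE), 512, 512)
    patch <- matrix(sample(0:2, size * size, TRUE), size, size)
    pasted <- paste_back(canvas, patch, roi)
    expect_identical(crop_patch(pasted, roi), patch)
    # outside the box the canvas is untouched
    pasted[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size)] <-
      canvas[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size)]
    expect_identical(pasted, canvas)
  }
})

test_that("paste order: disjoint pastes commute, overlapping pastes let the later win", {
  canvas <- matrix(0L, 512, 512)
  a <- roi_box(0, 0, 128, 128, 128)
  b <- roi_box(200, 200, 328, 328, 128)
  pa <- matrix(1L, 128, 128); pb <- matrix(2L, 128, 128)
  expect_identical(paste_back(paste_back(canvas, pa, a), pb, b),
                   paste_back(paste_back(canvas, pb, b), pa, a))

  # paste onto a zero canvas: sum equals the patch sum
  expect_equal(sum(paste_back(canvas, pa, a)), sum(pa))

  # overlap: the later paste wins inside the overlap
  c2 <- roi_box(64, 64, 192, 192, 128)
  out <- paste_back(paste_back(canvas, pa, a), pb, c2)
  expect_true(all(out[65:192, 65:192] == 2L))
  expect_true(all(out[1:64, 1:64] == 1L))
})

test_that("fine-input rescaling passes 128 through, halves 256, and round-trips constants", {
  p128 <- matrix(rnorm(128 * 128), 128, 128)
  expect_identical(to_fine_input(p128, 128, "image"), p128)

  lab256 <- matrix(sample(0:2, 256 * 256, TRUE), 256, 256)
  down <- to_fine_input(lab256, 128, "label")
  expect_equal(dim(down), c(128, 128))
  expect_true(all(down %in% 0:2))

  const <- matrix(1L, 256, 256)
  expect_identical(from_fine_output(to_fine_input(const, 128, "label"), 256), const)

  # 2x2-blockwise-constant content also survives the nearest round trip
  blocky <- matrix(0L, 256, 256)
  blocky[, 129:256] <- 2L
  expect_identical(from_fine_output(to_fine_input(blocky, 128, "label"), 256), blocky)
})

test_that("the cascade composed with oracle stubs reproduces the ground truth", {
  s <- toy_sample(96, kidney = c(20, 50, 20, 50), tumor = c(30, 40, 30, 40))
  coarse_stub <- function(img) s$label > 0
  fine_stub <- function(patch, roi) crop_patch(s$label, roi)
  out <- run_cascade(coarse_stub, fine_stub, s$image, roi_sizes = c(48, 96))
  expect_identical(out, s$label)
  rep <- evaluate_segmentation(list(out), list(s$label))
  expect_equal(rep$kidney_dice_mean, 1)
  expect_equal(rep$tumor_dice_mean, 1)

  # all-background coarse output short-circuits to an all-zero map
  none <- run_cascade(function(img) matrix(0L, 96, 96), fine_stub, s$image,
                      roi_sizes = c(48, 96))
  expect_true(all(none == 0L))
})

test_that("a two-kidney phantom drives two pasted ROIs through the cascade", {
  cfg <- phantom_config(image_size = 96, kidney_count_range = c(2, 2),
                        tumor_probability = 1, seed = 31, noise_sd = 0,
                        artifact_rate = 0)
  s <- generate_slice_dataset(1, cfg)[[1]]
  coarse_stub <- function(img) s$label > 0
  fine_stub <- function(patch, roi) crop_patch(s$label, roi)
  res <- run_cascade(coarse_stub, fine_stub, s$image, roi_sizes = c(48, 96),
                     return_rois = TRUE)
  expect_length(res$rois, 2)
  expect_identical(res$labels, s$label)
})
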