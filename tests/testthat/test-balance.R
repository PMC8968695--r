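test_that("tumor areas are pooled per 8-connected component (flood-fill oracle)", {
  s1 <- toy_sample(32, tumor = c(10, 16, 10, 16))          # 7x7 = 49 px
  expect_equal(tumor_areas(list(s1)), 49)

  # two disjoint tumors in one slice
  s2 <- toy_sample(64, kidney = c(4, 60, 4, 60))
  s2$label[10:19, 10:19] <- 2L                              # 100 px
  s2$label[35:44, 20:44] <- 2L                              # 250 px
  expect_setequal(tumor_areas(list(s2)), c(100, 250))
  expect_equal(sort(tumor_areas(list(s2))),
               sort(flood_fill_areas(s2$label == 2L)))

  expect_length(tumor_areas(list(toy_sample(32))), 0)
})

test_that("histograms bin right-open with an absorbing final bin and conserve counts", {
  h <- build_tumor_histogram(c(100, 450, 600), bin_width = 500, max_area = 1000)
  expect_equal(h$counts[1:2], c(2, 1))
  expect_equal(sum(h$counts), 3)

  # counting-loop oracle on random areas
  set.seed(23)
  areas <- runif(1000, 0, 5000)
  h2 <- build_tumor_histogram(areas, bin_width = 500, max_area = 3000)
  brute <- integer(length(h2$counts))
  for (a in areas) {
    b <- min(floor(a / 500) + 1, length(brute))
    brute[b] <- brute[b] + 1L
  }
  expect_equal(h2$counts, brute)
  expect_equal(sum(h2$counts), 1000)
  expect_error(build_tumor_histogram(areas, bin_width = 0), "positive")
})

test_that("augmentations are involutions / period-4 and preserve tumor area", {
  s <- toy_sample(32, tumor = c(10, 14, 18, 24))
  s$image <- s$image + matrix(rnorm(32 * 32), 32, 32)

  hf <- augmentation_op("horizontal_flip")
  expect_identical(apply_augmentation(apply_augmentation(s, hf), hf), s)
  vf <- augmentation_op("vertical_flip")
  expect_identical(apply_augmentation(apply_augmentation(s, vf), vf), s)
  mi <- augmentation_op("mirror")
  expect_identical(apply_augmentation(apply_augmentation(s, mi), mi), s)

  r1 <- augmentation_op("rotate90k", k = 1)
  r <- s
  for (i in 1:4) r <- apply_augmentation(r, r1)
  expect_identical(r, s)

  area0 <- sum(s$label == 2L)
  for (op in list(hf, vf, mi, r1, augmentation_op("rotate90k", k = 2),
                  augmentation_op("rotate90k", k = 3))) {
    expect_equal(sum(apply_augmentation(s, op)$label == 2L), area0)
    expect_true(all(apply_augmentation(s, op)$label %in% 0:2))
  }

  # shifts translate and pad with the intensity floor / background label
  sh <- augmentation_op("shift", dx = 3, dy = -2)
  out <- apply_augmentation(s, sh)
  expect_equal(dim(out$image), dim(s$image))
  expect_true(all(out$label %in% 0:2))
  expect_equal(out$label[8, 21 + 3], s$label[10, 21])
  expect_error(apply_augmentation(s, augmentation_op("shift", dx = 40)),
               "magnitude")
})

test_that("balance_dataset equalizes bins to the maximum count, deterministically", {
  # skewed pools: 10 small tumors, 20 large ones
  small <- lapply(1:10, function(i) toy_sample(32, tumor = c(10, 12, 10, 12)))  # 9 px
  large <- lapply(1:20, function(i) toy_sample(32, tumor = c(8, 17, 8, 17)))    # 100 px
  samples <- c(small, large)
  hist <- build_tumor_histogram(tumor_areas(samples), bin_width = 50,
                                max_area = 150)
  expect_equal(hist$counts, c(10, 0, 20))

  bal <- balance_dataset(samples, hist, rng_seed = 5)
  areas <- vapply(bal, function(s) sum(s$label == 2L), numeric(1))
  bins <- pmin(findInterval(areas, hist$bin_edges), length(hist$counts))
  expect_equal(as.integer(table(bins)), c(20L, 20L))
  expect_length(bal, 40)

  # every original appears exactly once (object identity by value)
  for (s in samples) {
    expect_gte(sum(vapply(bal, identical, logical(1), s)), 1)
  }

  # determinism and the no-op case
  bal2 <- balance_dataset(samples, hist, rng_seed = 5)
  expect_identical(bal, bal2)
  uniform <- c(small, small)
  hu <- build_tumor_histogram(tumor_areas(uniform), bin_width = 50, max_area = 150)
  bu <- balance_dataset(uniform, hu, rng_seed = 1)
  attr(bu, "manifest") <- NULL
  expect_identical(bu, uniform)
})
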