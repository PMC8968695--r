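test_that("slice_volume keeps exactly the labeled slices, in order, at full size", {
  img <- array(rnorm(30 * 40 * 40), c(30, 40, 40))
  lab <- array(0L, c(30, 40, 40))
  for (z in 6:11) lab[z, 18:22, 15:20] <- 1L   # 0-based slices 5..10
  samples <- slice_volume(img, lab, "case_x")
  expect_length(samples, 6)
  expect_equal(vapply(samples, `[[`, numeric(1), "slice_index"), 5:10)
  expect_equal(dim(samples[[1]]$image), c(40, 40))
  expect_true(all(vapply(samples, function(s) s$case_id, character(1)) == "case_x"))

  # all-zero labels: empty result
  expect_length(slice_volume(img, array(0L, dim(lab)), "e"), 0)
  expect_error(slice_volume(img, array(0L, c(30, 40, 39)), "e"), "shape")

  # slicing a stack rebuilt from samples is the identity on retained slices
  expect_equal(samples[[1]]$image, matrix(img[6, , ], 40))
})

test_that("fit_preprocess_stats pins percentile clipping and excludes spikes", {
  # a clean pooled set 0..998 plus one large spike
  vals <- c(0:998, 1e6)
  img <- matrix(vals, 40, 25)
  lab <- matrix(0L, 40, 25); lab[10:20, 10:20] <- 1L
  sam <- slice_sample(img, lab)
  st <- fit_preprocess_stats(list(sam), lo = 0.5, hi = 99.5)
  expect_equal(st$clip_hi, unname(quantile(vals, 0.995, type = 7)))
  expect_lt(st$clip_hi, 1e6)
  expect_equal(st$clip_lo, unname(quantile(vals, 0.005, type = 7)))

  # lo=0 / hi=100 reduce to pooled min and max
  st2 <- fit_preprocess_stats(list(sam), lo = 0, hi = 100)
  expect_equal(st2$clip_lo, 0)
  expect_equal(st2$clip_hi, 1e6)

  # constant foreground is degenerate
  cs <- toy_sample(32)
  cs$image[cs$label > 0] <- 5
  expect_error(fit_preprocess_stats(list(cs)), "zero variance")
  expect_error(fit_preprocess_stats(list()), "non-empty")
})

test_that("apply_preprocess clips then z-scores, matching a two-step reference", {
  set.seed(11)
  samples <- lapply(1:4, function(i) {
    img <- matrix(rnorm(32 * 32, 100, 30), 32, 32)
    lab <- matrix(0L, 32, 32); lab[8:24, 8:24] <- 1L
    img[1, 1] <- 1e6                     # artifact spike
    slice_sample(img, lab)
  })
  st <- fit_preprocess_stats(samples)
  out <- lapply(samples, apply_preprocess, stats = st)

  # two-step brute-force reference on the spike pixel
  ref <- (min(max(1e6, st$clip_lo), st$clip_hi) - st$fg_mean) / st$fg_sd
  expect_equal(out[[1]]$image[1, 1], ref)

  # z-scoring on the fitting pool: foreground mean ~ 0, sd ~ 1
  fg <- unlist(lapply(out, function(s) s$image[s$label > 0]))
  expect_lt(abs(mean(fg)), 1e-6)
  expect_lt(abs(sd(fg) - 1), 1e-6)

  # pixel equal to the foreground mean maps to 0
  s0 <- samples[[1]]
  s0$image[2, 2] <- st$fg_mean
  expect_equal(apply_preprocess(s0, st)$image[2, 2], 0)

  # labels untouched, monotone non-decreasing in input intensity
  expect_identical(out[[1]]$label, samples[[1]]$label)
  x <- sort(rnorm(100, 100, 50))
  sx <- slice_sample(matrix(x, 10, 10), samples[[1]]$label[1:10, 1:10])
  y <- apply_preprocess(sx, st)$image
  expect_true(all(diff(as.numeric(y)[order(as.numeric(sx$image))]) >= 0))
})

test_that("clipping is idempotent", {
  set.seed(3)
  img <- matrix(rnorm(20 * 20, 50, 20), 20, 20)
  lab <- matrix(0L, 20, 20); lab[5:15, 5:15] <- 1L
  st <- fit_preprocess_stats(list(slice_sample(img, lab)))
  clip <- function(x) pmax(pmin(x, st$clip_hi), st$clip_lo)
  expect_equal(clip(clip(img)), clip(img))
})

test_that("preprocess statistics survive a JSON round trip", {
  s <- toy_sample(32, tumor = c(12, 16, 12, 16))
  s$image <- s$image + matrix(rnorm(32 * 32), 32, 32)
  st <- fit_preprocess_stats(list(s))
  path <- tempfile(fileext = ".json")
  write_preprocess_stats(st, path)
  back <- read_preprocess_stats(path)
  expect_equal(back$clip_lo, st$clip_lo)
  expect_equal(back$clip_hi, st$clip_hi)
  expect_equal(back$fg_mean, st$fg_mean)
  expect_equal(back$fg_sd, st$fg_sd)
  unlink(path)
})
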