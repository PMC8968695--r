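test_that("membership degrees follow the piecewise-linear rule shapes", {
  p <- membership_params()
  expect_equal(unlist(membership(0, p)), c(mu_dark = 1, mu_gray = 0, mu_bright = 0))
  expect_equal(unlist(membership(1, p)), c(mu_dark = 0, mu_gray = 0, mu_bright = 1))
  # hand evaluation of the linear interpolant at m = 0.29
  mu <- membership(0.29, p)
  expect_equal(mu$mu_dark, (0.43 - 0.29) / (0.43 - 0.15))
  expect_equal(mu$mu_dark, 0.5)
  expect_equal(mu$mu_gray, 0.5)
  expect_equal(mu$mu_bright, 0)
  # degrees in [0,1], never all zero, over a dense grid
  m <- seq(0, 1, by = 0.01)
  mus <- membership(m, p)
  for (comp in mus) expect_true(all(comp >= 0 & comp <= 1))
  expect_true(all(mus$mu_dark + mus$mu_gray + mus$mu_bright > 0))
  expect_error(membership(-0.1), "\\[0, 1\\]")
  expect_error(membership(1.1), "\\[0, 1\\]")
})

test_that("center-of-gravity defuzzification matches hand arithmetic and is scale-invariant", {
  p <- membership_params()
  one <- function(d, g, b) list(mu_dark = d, mu_gray = g, mu_bright = b)
  expect_equal(defuzzify_cog(one(1, 0, 0), p), 0)
  expect_equal(defuzzify_cog(one(0, 0, 1), p), 255)
  expect_equal(defuzzify_cog(one(0.5, 0.5, 0), p), 63.5)
  # invariance to uniform scaling of the memberships
  for (s in c(0.2, 1, 7)) {
    expect_equal(defuzzify_cog(one(0.3 * s, 0.5 * s, 0.2 * s), p),
                 defuzzify_cog(one(0.3, 0.5, 0.2), p))
  }
  expect_error(defuzzify_cog(one(0, 0, 0), p), "degenerate")
})

test_that("the piecewise transform reproduces its printed branch values", {
  expect_equal(enhance_pixel(0.10), 0)
  expect_equal(enhance_pixel(0.90), 255)
  expect_equal(enhance_pixel(0.29), (0.29 - 0.15) / 0.28 * 127)
  expect_equal(enhance_pixel(0.29), 63.5)
  expect_equal(enhance_pixel(0.50),
               (0.50 - 0.45) / 0.28 * 255 + (0.71 - 0.50) / 0.28 * 127)
  expect_equal(enhance_pixel(0.50), 140.7857, tolerance = 1e-4)
  expect_error(enhance_pixel(-0.01), "\\[0, 1\\]")
})

test_that("the transform is monotone within each branch but discontinuous between them", {
  branches <- list(seq(0, 0.1499, length.out = 50),
                   seq(0.15, 0.4299, length.out = 50),
                   seq(0.43, 0.7099, length.out = 50),
                   seq(0.71, 1, length.out = 50))
  for (m in branches) {
    v <- enhance_pixel(m)
    expect_true(all(diff(v) >= 0))
  }
  # printed discontinuities: second branch reaches 127 at 0.43-, third starts
  # lower because of the 0.45 offset; third ends below 255 at 0.71-
  expect_lt(enhance_pixel(0.43), enhance_pixel(0.4299999))
  expect_lt(enhance_pixel(0.7099999), 255)
  # the continuous variant closes both gaps
  expect_equal(enhance_pixel(0.43, continuous = TRUE),
               enhance_pixel(0.4299999, continuous = TRUE), tolerance = 1e-4)
  expect_equal(enhance_pixel(0.7099999, continuous = TRUE), 255,
               tolerance = 1e-4)
})

test_that("rule directions hold: dark pixels darken, bright pixels brighten", {
  p <- membership_params()
  m <- seq(0, 1, by = 0.01)
  v <- enhance_pixel(m)
  expect_true(all(v[m < p$b1] <= p$v_g))
  expect_true(all(v[m > p$b3] == p$v_b))
})

test_that("LUT image enhancement equals the naive per-pixel loop bit for bit", {
  set.seed(4)
  for (rep in 1:5) {
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    lut_out <- enhance_image(img, bit_depth = 8, integer_output = FALSE)
    rng <- range(img)
    naive <- matrix(enhance_pixel((img - rng[1]) / (rng[2] - rng[1])), 64, 64)
    expect_identical(lut_out, naive)
  }
})

test_that("enhanced images stay in [0,255]; high-normalized images saturate at 255", {
  set.seed(5)
  img <- matrix(rnorm(32 * 32, 100, 40), 32, 32)
  out <- enhance_image(img, bit_depth = 8)
  expect_true(all(out >= 0 & out <= 255))

  # all normalized values >= 0.71 after min-max: construct an image whose
  # range is dominated by one dark pixel so the rest normalizes above 0.71
  img2 <- matrix(250L, 16, 16)
  img2[1, 1] <- 0L
  img2[2, 1] <- 255L
  out2 <- enhance_image(img2, bit_depth = 8)
  expect_true(all(out2[-1] == 255))

  expect_warning(enhance_image(matrix(7, 4, 4)), "constant image")
})
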