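# Direct same-padded convolution by explicit loops: the independent oracle
# for the block-equivalence checks.
naive_conv <- function(x, w, b) {
  d <- dim(x); K <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  pad <- (K - 1) / 2
  out <- array(0, c(d[1], d[2], cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(cout)) {
    acc <- matrix(b[co], d[1], d[2])
    for (ci in seq_len(cin)) for (ki in seq_len(K)) for (kj in seq_len(K)) {
      ii <- seq_len(d[1]) + ki - 1 - pad
      jj <- seq_len(d[2]) + kj - 1 - pad
      ok_i <- ii >= 1 & ii <= d[1]; ok_j <- jj >= 1 & jj <= d[2]
      acc[ok_i, ok_j] <- acc[ok_i, ok_j] +
        x[ii[ok_i], jj[ok_j], ci, n] * w[ki, kj, ci, co]
    }
    out[, , co, n] <- acc
  }
  out
}

test_that("leaky_relu passes positives, scales negatives, and limits to the rectifier", {
  expect_equal(leaky_relu(3), 3)
  expect_equal(leaky_relu(-2, 0.01), -0.02)
  v <- c(-5, -0.1, 0, 0.1, 5)
  expect_equal(leaky_relu(v, 1e-9), pmax(v, 0), tolerance = 1e-7)
  expect_error(leaky_relu(1, slope = 0), "slope")
})

test_that("R2P block output has the contracted shape and channel bookkeeping", {
  cfg <- r2p_block_config(in_channels = 32, out_channels = 64,
                          kernel_sizes = c(3, 5), t = 1, dropout_rate = 0)
  params <- init_r2p_block(cfg, seed = 2)
  x <- array(rnorm(16 * 16 * 32 * 2), c(16, 16, 32, 2))
  y <- r2p_block_forward(x, cfg, params)
  expect_equal(dim(y), c(16, 16, 64, 2))

  # two branches concatenate to 2 x out_channels before the 1x1 projection
  expect_equal(dim(params[["proj.w"]]), c(1, 1, 2 * 64, 64))

  expect_error(r2p_block_forward(array(0, c(16, 16, 8, 2)), cfg, params),
               "channels")
})

test_that("t=0 single-kernel block with zeroed residual equals a plain two-conv block", {
  cfg <- r2p_block_config(in_channels = 2, out_channels = 4, kernel_sizes = 3,
                          t = 0, use_batchnorm = FALSE, dropout_rate = 0,
                          leaky_slope = 0.05)
  params <- init_r2p_block(cfg, seed = 3)
  params[["res.w"]][] <- 0
  params[["res.b"]][] <- 0
  set.seed(6)
  x <- array(rnorm(10 * 10 * 2 * 2), c(10, 10, 2, 2))
  got <- r2p_block_forward(x, cfg, params)

  h1 <- leaky_relu(naive_conv(x, params[["b1.rcl1.w_in"]],
                              params[["b1.rcl1.b_in"]]), 0.05)
  h2 <- leaky_relu(naive_conv(h1, params[["b1.rcl2.w_in"]],
                              params[["b1.rcl2.b_in"]]), 0.05)
  expect_equal(got, h2, tolerance = 1e-12)
})

test_that("attention gate output matches x's shape; zeroed psi gives exactly x/2", {
  params <- init_attention_params(8, 16)
  x <- array(rnorm(12 * 12 * 8 * 2), c(12, 12, 8, 2))
  g <- array(rnorm(6 * 6 * 16 * 2), c(6, 6, 16, 2))
  res <- attention_gate_forward(x, g, params, return_map = TRUE)
  expect_equal(dim(res$out), dim(x))
  expect_true(all(res$map > 0 & res$map < 1))

  params[["psi.w"]][] <- 0
  params[["psi.b"]][] <- 0
  res0 <- attention_gate_forward(x, g, params, return_map = TRUE)
  expect_true(all(res0$map == 0.5))
  expect_identical(res0$out, 0.5 * x)

  expect_error(attention_gate_forward(x, array(0, c(5, 5, 16, 2)), params),
               "coarser")
})

test_that("bottleneck side follows input_size / 2^depth for depths 4, 5, 6", {
  blk <- r2p_block_config(kernel_sizes = 3, t = 0, dropout_rate = 0)
  for (case in list(c(4, 8), c(5, 4), c(6, 2))) {
    cfg <- network_config(input_size = 128, depth = case[1], base_filters = 1,
                          n_classes = 3, block = blk)
    model <- build_network(cfg, seed = 1)
    expect_equal(model$bottleneck_side, case[2])
  }
  expect_error(network_config(input_size = 100, depth = 4), "divisible")
})

test_that("parameter count is a pure function of the configuration", {
  blk <- r2p_block_config(kernel_sizes = c(3, 5), t = 2)
  cfg <- network_config(input_size = 32, depth = 2, base_filters = 4,
                        n_classes = 2, block = blk)
  m1 <- build_network(cfg, seed = 1)
  m2 <- build_network(cfg, seed = 99)
  expect_equal(count_params(m1), count_params(m2))
})

test_that("forward softmax normalizes at every pixel and is per-sample pure", {
  blk <- r2p_block_config(kernel_sizes = 3, t = 1, dropout_rate = 0)
  cfg <- network_config(input_size = 16, depth = 2, base_filters = 4,
                        n_classes = 3, block = blk)
  model <- build_network(cfg, seed = 5)
  set.seed(8)
  img <- matrix(rnorm(16 * 16), 16, 16)
  batch <- array(0, c(16, 16, 1, 3))
  batch[, , 1, 1] <- img
  batch[, , 1, 2] <- matrix(rnorm(16 * 16), 16, 16)
  batch[, , 1, 3] <- img                       # duplicate of sample 1
  p <- net_forward(model, batch)
  expect_equal(dim(p), c(16, 16, 3, 3))
  sums <- p[, , 1, ] + p[, , 2, ] + p[, , 3, ]
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-6)
  expect_equal(p[, , , 1], p[, , , 3])         # no cross-sample leakage

  expect_error(net_forward(model, array(0, c(8, 8, 1, 1))), "spatial size")

  lab <- predict_labels(model, img)
  expect_true(all(lab %in% 0:2))
  expect_equal(dim(lab), c(16, 16))
})

test_that("model checkpoints round-trip through disk", {
  blk <- r2p_block_config(kernel_sizes = 3, t = 0, dropout_rate = 0)
  cfg <- network_config(input_size = 16, depth = 1, base_filters = 2,
                        n_classes = 2, block = blk)
  model <- build_network(cfg, seed = 3)
  img <- matrix(rnorm(256), 16, 16)
  before <- predict_labels(model, img)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(predict_labels(back, img), before)
  unlink(path)
})
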