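# The attention-gated U-shaped segmentation network with recurrent-residual
# parallel-convolution (R2P) blocks.
#
# An R2P block runs one recurrent conv layer pair per kernel size in
# parallel, concatenates the branch outputs ("stitching all outputs into one
# deep feature map"), projects back to out_channels when there is more than
# one branch, and adds a residual copy of the input (1x1-projected when the
# channel counts differ). A recurrent conv layer computes an initial
# convolution x1 and then t accumulation steps h <- act(norm(conv(h) + x1))
# with shared recurrent weights. Activations are Leaky-ReLU throughout;
# batch normalization follows every convolution (conv -> norm -> activation).

#' R2P block configuration
#'
#' @param in_channels,out_channels Channel counts (>= 1).
#' @param kernel_sizes Odd kernel sides run in parallel (e.g. `c(3)` or
#'   `c(3, 5)`).
#' @param t Recurrence (accumulation) steps, >= 0; `t = 0` reduces each
#'   branch to a plain two-convolution block.
#' @param leaky_slope Leaky-ReLU negative slope in (0, 1).
#' @param use_batchnorm Apply batch normalization after every convolution.
#' @param dropout_rate Dropout rate in `[0, 1)`, applied at the network
#'   bottleneck during training.
#' @return An object of class `r2p_block_config`.
#' @export
r2p_block_config <- function(in_channels = 1, out_channels = 32,
                             kernel_sizes = c(3, 5), t = 2,
                             leaky_slope = 0.01, use_batchnorm = TRUE,
                             dropout_rate = 0.2) {
  if (length(kernel_sizes) == 0 || any(kernel_sizes %% 2 != 1))
    stopf("kernel_sizes must be a non-empty set of odd integers")
  if (!is_count(t) || t < 0) stopf("t must be an integer >= 0")
  if (!(leaky_slope > 0 && leaky_slope < 1)) stopf("leaky_slope must be in (0, 1)")
  if (!(dropout_rate >= 0 && dropout_rate < 1)) stopf("dropout_rate must be in [0, 1)")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_sizes = as.integer(kernel_sizes), t = as.integer(t),
                 leaky_slope = leaky_slope, use_batchnorm = use_batchnorm,
                 dropout_rate = dropout_rate),
            class = "r2p_block_config")
}

#' Network configuration
#'
#' @param input_size Input side in pixels; must be divisible by `2^depth`.
#' @param depth Number of 2x down-samplings (>= 1). The bottleneck feature
#'   map has side `input_size / 2^depth` (the "last layer image size").
#' @param base_filters Channels of the first encoder level, doubled per
#'   level.
#' @param n_classes 2 (coarse, background vs kidney+tumor) or 3 (fine).
#' @param block An [r2p_block_config()]; its channel fields are overridden
#'   per level.
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_size = 128, depth = 4, base_filters = 32,
                           n_classes = 3, block = r2p_block_config()) {
  if (!is_count(depth) || depth < 1) stopf("depth must be an integer >= 1")
  if (!is_count(base_filters) || base_filters < 1) stopf("base_filters must be >= 1")
  if (input_size %% 2^depth != 0)
    stopf("input_size (%d) must be divisible by 2^depth (%d)", input_size, 2^depth)
  if (!n_classes %in% 2:3) stopf("n_classes must be 2 or 3")
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes), block = block),
            class = "network_config")
}

#' Leaky rectified linear unit
#'
#' @param v Numeric vector/array.
#' @param slope Negative-side slope in (0, 1).
#' @return `v` where `v >= 0`, else `slope * v`.
#' @export
leaky_relu <- function(v, slope = 0.01) {
  if (!(slope > 0 && slope < 1)) stopf("slope must be in (0, 1)")
  ifelse(v >= 0, v, slope * v)
}

# He-normal initial weights for a (K, K, cin, cout) kernel.
he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

# ---- parameter construction -------------------------------------------------

# Named parameter list for one R2P block; names are prefixed so multiple
# blocks share one flat model parameter list.
init_r2p_params <- function(cfg, prefix = "") {
  cin <- cfg$in_channels; cout <- cfg$out_channels
  p <- list()
  put <- function(name, val) p[[paste0(prefix, name)]] <<- val
  for (i in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[i]
    for (layer in 1:2) {
      lin <- if (layer == 1) cin else cout
      pf <- sprintf("b%d.rcl%d.", i, layer)
      put(paste0(pf, "w_in"), he_init(k, lin, cout))
      put(paste0(pf, "b_in"), numeric(cout))
      if (cfg$t > 0) {
        put(paste0(pf, "w_rec"), he_init(k, cout, cout))
        put(paste0(pf, "b_rec"), numeric(cout))
      }
      if (cfg$use_batchnorm) {
        put(paste0(pf, "bn_in.gamma"), rep(1, cout))
        put(paste0(pf, "bn_in.beta"), numeric(cout))
        if (cfg$t > 0) {
          put(paste0(pf, "bn_rec.gamma"), rep(1, cout))
          put(paste0(pf, "bn_rec.beta"), numeric(cout))
        }
      }
    }
  }
  if (length(cfg$kernel_sizes) > 1) {
    put("proj.w", he_init(1, length(cfg$kernel_sizes) * cout, cout))
    put("proj.b", numeric(cout))
  }
  if (cin != cout) {
    put("res.w", he_init(1, cin, cout))
    put("res.b", numeric(cout))
  }
  p
}

#' Attention gate parameters
#'
#' The intermediate channel count is half of the skip signal's channels
#' (at least 1).
#'
#' @param x_channels Channels of the encoder skip feature x.
#' @param g_channels Channels of the coarser gating signal g.
#' @param prefix Optional name prefix for the parameter list.
#' @return Named list of parameter arrays.
#' @export
init_attention_params <- function(x_channels, g_channels, prefix = "") {
  ci <- max(1L, x_channels %/% 2L)
  p <- list()
  p[[paste0(prefix, "theta.w")]] <- he_init(1, x_channels, ci)
  p[[paste0(prefix, "theta.b")]] <- numeric(ci)
  p[[paste0(prefix, "phi.w")]] <- he_init(1, g_channels, ci)
  p[[paste0(prefix, "phi.b")]] <- numeric(ci)
  p[[paste0(prefix, "psi.w")]] <- he_init(1, ci, 1)
  p[[paste0(prefix, "psi.b")]] <- numeric(1)
  p
}

#' R2P block parameter initialization
#'
#' @param cfg An [r2p_block_config()] with channel counts set.
#' @param seed Integer seed for the weight draw.
#' @return Named list of parameter arrays for [r2p_block_forward()].
#' @export
init_r2p_block <- function(cfg, seed = 1) {
  with_seed(seed, init_r2p_params(cfg))
}

# ---- graph builders ---------------------------------------------------------

# Recurrent conv layer as tape nodes. pget(name) -> parameter node.
rcl_node <- function(x, pf, cfg, pget, state, training) {
  act <- function(n) op_leaky_relu(n, cfg$leaky_slope)
  norm <- function(n, tag) {
    if (!cfg$use_batchnorm) return(n)
    op_batchnorm(n, pget(paste0(pf, tag, ".gamma")), pget(paste0(pf, tag, ".beta")),
                 state, paste0(pf, tag), training)
  }
  x1 <- op_conv2d(x, pget(paste0(pf, "w_in")), pget(paste0(pf, "b_in")))
  h <- act(norm(x1, "bn_in"))
  if (cfg$t > 0) {
    for (i in seq_len(cfg$t)) {
      hc <- op_conv2d(h, pget(paste0(pf, "w_rec")), pget(paste0(pf, "b_rec")))
      h <- act(norm(op_add(hc, x1), "bn_rec"))
    }
  }
  h
}

r2p_node <- function(x, cfg, pget, state, training, prefix = "") {
  pg <- function(name) pget(paste0(prefix, name))
  branches <- lapply(seq_along(cfg$kernel_sizes), function(i) {
    h <- rcl_node(x, sprintf("%sb%d.rcl1.", prefix, i), cfg, pget, state, training)
    rcl_node(h, sprintf("%sb%d.rcl2.", prefix, i), cfg, pget, state, training)
  })
  main <- if (length(branches) > 1) {
    op_conv2d(op_concat(branches), pg("proj.w"), pg("proj.b"))
  } else branches[[1]]
  res <- if (cfg$in_channels != cfg$out_channels) {
    op_conv2d(x, pg("res.w"), pg("res.b"))
  } else x
  op_add(main, res)
}

attention_node <- function(x, g, pget, prefix, slope) {
  pg <- function(name) pget(paste0(prefix, name))
  gu <- if (dim4(g$value)[1] * 2 == dim4(x$value)[1]) op_upsample2(g) else g
  tx <- op_conv2d(x, pg("theta.w"), pg("theta.b"))
  pgq <- op_conv2d(gu, pg("phi.w"), pg("phi.b"))
  a <- op_leaky_relu(op_add(tx, pgq), slope)
  map <- op_sigmoid(op_conv2d(a, pg("psi.w"), pg("psi.b")))
  list(out = op_mul_map(x, map), map = map)
}

# ---- standalone forward passes (exported contracts) ------------------------

as_tensor4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stopf("x must be an array")
  if (length(d) == 2) dim(x) <- c(d, 1, 1)
  if (length(d) == 3) dim(x) <- c(d, 1)
  x
}

#' Forward pass of a standalone R2P block
#'
#' Runs the block in inference mode (batch-norm layers use their
#' running/default statistics).
#'
#' @param x 4-axis array (rows, cols, channels, batch) with
#'   `cfg$in_channels` channels.
#' @param cfg An [r2p_block_config()].
#' @param params Parameters from [init_r2p_block()].
#' @return Array of shape (rows, cols, `cfg$out_channels`, batch).
#' @export
r2p_block_forward <- function(x, cfg, params) {
  x <- as_tensor4(x)
  if (dim(x)[3] != cfg$in_channels)
    stopf("input has %d channels, block expects %d", dim(x)[3], cfg$in_channels)
  tp <- tape_new()
  pn <- lapply(params, function(p) node_leaf(tp, p))
  xn <- node_leaf(tp, x)
  out <- r2p_node(xn, cfg, function(n) pn[[n]], new.env(), training = FALSE)
  out$value
}

#' Forward pass of a standalone attention gate
#'
#' The gating signal is upsampled to x's grid when it is one level coarser,
#' both signals are 1x1-projected to half of x's channels, summed, passed
#' through Leaky-ReLU and a final 1x1 projection, and squashed by the
#' logistic function into a single-channel attention map in (0, 1); the
#' output is x weighted by the map.
#'
#' @param x Skip feature, 4-axis array.
#' @param g Gating feature, spatially equal to or half of x.
#' @param params Parameters from [init_attention_params()].
#' @param slope Leaky-ReLU slope.
#' @param return_map Also return the attention map.
#' @return The gated feature array (x's shape), or a list `(out, map)` when
#'   `return_map = TRUE`.
#' @export
attention_gate_forward <- function(x, g, params, slope = 0.01,
                                   return_map = FALSE) {
  x <- as_tensor4(x); g <- as_tensor4(g)
  dx <- dim(x); dg <- dim(g)
  if (!(all(dg[1:2] == dx[1:2]) || all(2 * dg[1:2] == dx[1:2])))
    stopf("g must match x spatially or be exactly one level coarser")
  tp <- tape_new()
  pn <- lapply(params, function(p) node_leaf(tp, p))
  res <- attention_node(node_leaf(tp, x), node_leaf(tp, g),
                        function(n) pn[[n]], "", slope)
  if (return_map) list(out = res$out$value, map = res$map$value)
  else res$out$value
}

# ---- full network -----------------------------------------------------------

level_block_cfg <- function(cfg, cin, cout) {
  b <- cfg$block
  b$in_channels <- as.integer(cin)
  b$out_channels <- as.integer(cout)
  b
}

# Per-level channel plan: encoder level k maps enc_in[k] -> enc_out[k].
channel_plan <- function(cfg) {
  f <- cfg$base_filters
  enc_out <- f * 2^(seq_len(cfg$depth) - 1)
  enc_in <- c(1, head(enc_out, -1))
  list(enc_in = enc_in, enc_out = enc_out, bottleneck = f * 2^cfg$depth)
}

#' Build an attention-gated R2P U-Net
#'
#' Constructs the parameter set for a U-shaped network with `depth` encoder
#' levels (R2P block + 2x2 max pooling), an R2P bottleneck (with dropout in
#' training), and symmetric decoder levels (nearest-neighbour 2x upsampling
#' followed by a 3x3 convolution, attention-gated skip concatenation, R2P
#' block), ending in a 1x1 classification head.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `nephroseg_model` with elements `config`,
#'   `params` (named list of arrays), `state` (batch-norm running statistics),
#'   and `bottleneck_side = input_size / 2^depth`.
#' @export
build_network <- function(cfg, seed = 1) {
  if (!inherits(cfg, "network_config")) stopf("cfg must be a network_config")
  plan <- channel_plan(cfg)
  with_seed(seed, {
    params <- list()
    for (k in seq_len(cfg$depth)) {
      params <- c(params, init_r2p_params(
        level_block_cfg(cfg, plan$enc_in[k], plan$enc_out[k]),
        sprintf("enc%d.", k)))
    }
    params <- c(params, init_r2p_params(
      level_block_cfg(cfg, plan$enc_out[cfg$depth], plan$bottleneck), "bott."))
    for (k in rev(seq_len(cfg$depth))) {
      cg <- if (k == cfg$depth) plan$bottleneck else plan$enc_out[k + 1]
      cx <- plan$enc_out[k]
      params[[sprintf("up%d.w", k)]] <- he_init(3, cg, cx)
      params[[sprintf("up%d.b", k)]] <- numeric(cx)
      params <- c(params, init_attention_params(cx, cg, sprintf("att%d.", k)))
      params <- c(params, init_r2p_params(
        level_block_cfg(cfg, 2 * cx, cx), sprintf("dec%d.", k)))
    }
    params[["head.w"]] <- he_init(1, cfg$base_filters, cfg$n_classes)
    params[["head.b"]] <- numeric(cfg$n_classes)
    structure(list(config = cfg, params = params, state = new.env(),
                   bottleneck_side = cfg$input_size %/% 2L^cfg$depth),
              class = "nephroseg_model")
  })
}

# Full forward graph; returns the tape, parameter nodes, logits and softmax
# probabilities. Used by training (with gradients) and inference alike.
forward_graph <- function(model, xarr, training = FALSE) {
  cfg <- model$config
  d <- dim4(xarr)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size)
    stopf("batch spatial size %dx%d does not match input_size %d",
          d[1], d[2], cfg$input_size)
  tp <- tape_new()
  pn <- lapply(model$params, function(p) node_leaf(tp, p))
  pget <- function(name) {
    nd <- pn[[name]]
    if (is.null(nd)) stopf("missing parameter %s", name)
    nd
  }
  plan <- channel_plan(cfg)
  x <- node_leaf(tp, xarr)
  enc <- vector("list", cfg$depth)
  for (k in seq_len(cfg$depth)) {
    bc <- level_block_cfg(cfg, plan$enc_in[k], plan$enc_out[k])
    enc[[k]] <- r2p_node(x, bc, pget, model$state, training, sprintf("enc%d.", k))
    x <- op_maxpool2(enc[[k]])
  }
  bc <- level_block_cfg(cfg, plan$enc_out[cfg$depth], plan$bottleneck)
  x <- r2p_node(x, bc, pget, model$state, training, "bott.")
  x <- op_dropout(x, cfg$block$dropout_rate, training)
  for (k in rev(seq_len(cfg$depth))) {
    gated <- attention_node(enc[[k]], x, pget, sprintf("att%d.", k),
                            cfg$block$leaky_slope)$out
    up <- op_conv2d(op_upsample2(x), pget(sprintf("up%d.w", k)),
                    pget(sprintf("up%d.b", k)))
    up <- op_leaky_relu(up, cfg$block$leaky_slope)
    bc <- level_block_cfg(cfg, 2 * plan$enc_out[k], plan$enc_out[k])
    x <- r2p_node(op_concat(list(up, gated)), bc, pget, model$state, training,
                  sprintf("dec%d.", k))
  }
  logits <- op_conv2d(x, pget("head.w"), pget("head.b"))
  list(tape = tp, pnodes = pn, logits = logits, probs = op_softmax(logits))
}

#' Network forward pass
#'
#' @param model A `nephroseg_model` from [build_network()].
#' @param batch Array (rows, cols, batch) or (rows, cols, 1, batch) of input
#'   images at the configured input size.
#' @param training Use batch statistics and dropout (TRUE) or running
#'   statistics (FALSE).
#' @return Per-pixel class probabilities, shape (rows, cols, n_classes,
#'   batch); the softmax over the class axis sums to 1 at every pixel.
#' @export
net_forward <- function(model, batch, training = FALSE) {
  forward_graph(model, as_tensor4(batch), training)$probs$value
}

#' Predict label maps
#'
#' Runs the network and takes the per-pixel argmax.
#'
#' @param model A `nephroseg_model`.
#' @param images One matrix or a list of matrices at the model's input size.
#' @return One integer label matrix (values `0..n_classes-1`) or a list of
#'   them, mirroring the input.
#' @export
predict_labels <- function(model, images) {
  single <- is.matrix(images)
  if (single) images <- list(images)
  s <- model$config$input_size
  batch <- array(0, c(s, s, 1, length(images)))
  for (i in seq_along(images)) batch[, , 1, i] <- images[[i]]
  p <- net_forward(model, batch, training = FALSE)
  out <- lapply(seq_along(images), function(i) {
    pc <- p[, , , i, drop = FALSE]
    lab <- matrix(0L, s, s)
    best <- pc[, , 1, 1]
    for (c in seq_len(dim(p)[3])[-1]) {
      sel <- pc[, , c, 1] > best
      lab[sel] <- c - 1L
      best <- pmax(best, pc[, , c, 1])
    }
    lab
  })
  if (single) out[[1]] else out
}

#' Number of trainable parameters
#'
#' @param model A `nephroseg_model`.
#' @return Total count of trainable parameter values (batch-norm running
#'   statistics excluded).
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the configuration, parameters, batch-norm running
#' statistics and the seed it was built with.
#'
#' @param model A `nephroseg_model`.
#' @param path Checkpoint file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               state = as.list(model$state),
               bottleneck_side = model$bottleneck_side,
               meta = attr(model, "meta")), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  st <- new.env()
  for (n in names(x$state)) st[[n]] <- x$state[[n]]
  m <- structure(list(config = x$config, params = x$params, state = st,
                      bottleneck_side = x$bottleneck_side),
                 class = "nephroseg_model")
  attr(m, "meta") <- x$meta
  m
}
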