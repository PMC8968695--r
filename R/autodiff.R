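# Minimal reverse-mode automatic differentiation over 4-axis arrays
# (rows, cols, channels, batch). Each operation appends a node holding its
# value and a backward closure; backprop walks nodes in reverse creation
# order. Convolutions lower to im2col (C++) plus one BLAS matmul.
#
# This tape exists because the recurrent-residual parallel-convolution
# attention U-Net is the package's own contribution; the graph per forward
# pass is small (hundreds of nodes), so tape overhead is negligible next to
# the matmuls.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_node <- function(tp, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd$tape <- tp
  nd
}

node_leaf <- function(tp, value) tape_node(tp, value)

add_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through its tape. Consumed gradients
# and backward closures are dropped eagerly: a node's gradient is complete
# once all later-created nodes have run, so after its own backward call
# nothing reads it again (leaf/parameter nodes have no backward and keep
# their gradients for the optimizer).
tape_backward <- function(loss_node) {
  tp <- loss_node$tape
  loss_node$grad <- 1
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) {
      nd$backward(nd$grad)
      nd$grad <- NULL
      nd$backward <- NULL
      nd$value <- NULL
    }
  }
  invisible(NULL)
}

dim4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4) stopf("expected a 4-axis array")
  d
}

# ---- convolution ----------------------------------------------------------

conv2d_value <- function(x, w, b) {
  d <- dim4(x); K <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  if (d[3] != cin) stopf("channel mismatch: input has %d, kernel expects %d", d[3], cin)
  cols <- im2col_cpp(as.numeric(x), d[1], d[2], d[3], d[4], K)
  out <- cols %*% matrix(w, K * K * cin, cout)
  out <- sweep_bias(out, b)
  # rows are ordered (pixel, batch); reorder to (rows, cols, channels, batch)
  dim(out) <- c(d[1] * d[2], d[4], cout)
  out <- aperm(out, c(1, 3, 2))
  dim(out) <- c(d[1], d[2], cout, d[4])
  list(out = out, cols = cols)
}

sweep_bias <- function(mat, b) {
  if (is.null(b)) return(mat)
  mat + rep(b, each = nrow(mat))
}

op_conv2d <- function(x, w, b = NULL) {
  tp <- x$tape
  d <- dim4(x$value); K <- dim(w$value)[1]
  cin <- dim(w$value)[3]; cout <- dim(w$value)[4]
  cv <- conv2d_value(x$value, w$value, if (is.null(b)) NULL else b$value)
  cols <- cv$cols
  nd <- tape_node(tp, cv$out, backward = function(g) {
    gm <- g
    dim(gm) <- c(d[1] * d[2], cout, d[4])
    gm <- aperm(gm, c(1, 3, 2))                    # back to (pixel, batch) rows
    dim(gm) <- c(d[1] * d[2] * d[4], cout)
    dw <- crossprod(cols, gm)                      # (K*K*cin) x cout
    dim(dw) <- dim(w$value)
    add_grad(w, dw)
    if (!is.null(b)) add_grad(b, colSums(gm))
    dcols <- gm %*% t(matrix(w$value, K * K * cin, cout))
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], K)
    dim(dx) <- d
    add_grad(x, dx)
    cols <<- NULL                                  # free the im2col buffer
  })
  nd
}

# ---- pointwise and shape ops ----------------------------------------------

op_leaky_relu <- function(x, slope = 0.01) {
  v <- x$value
  out <- pmax(v, 0) + slope * pmin(v, 0)
  tape_node(x$tape, out, backward = function(g) {
    add_grad(x, g * (slope + (1 - slope) * (v >= 0)))
  })
}

op_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  tape_node(x$tape, s, backward = function(g) add_grad(x, g * s * (1 - s)))
}

op_add <- function(a, b) {
  tape_node(a$tape, a$value + b$value, backward = function(g) {
    add_grad(a, g); add_grad(b, g)
  })
}

op_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- 1 - rate
  mask <- array((runif(length(x$value)) < keep) / keep, dim4(x$value))
  tape_node(x$tape, x$value * mask, backward = function(g) add_grad(x, g * mask))
}

# Concatenate along the channel axis.
op_concat <- function(xs) {
  ds <- lapply(xs, function(x) dim4(x$value))
  chans <- vapply(ds, `[`, numeric(1), 3)
  d <- ds[[1]]
  out <- array(0, c(d[1], d[2], sum(chans), d[4]))
  ofs <- 0L
  for (i in seq_along(xs)) {
    out[, , ofs + seq_len(chans[i]), ] <- xs[[i]]$value
    ofs <- ofs + chans[i]
  }
  tape_node(xs[[1]]$tape, out, backward = function(g) {
    ofs <- 0L
    for (i in seq_along(xs)) {
      add_grad(xs[[i]], g[, , ofs + seq_len(chans[i]), , drop = FALSE])
      ofs <- ofs + chans[i]
    }
  })
}

# Multiply features by a single-channel map, broadcast over channels.
op_mul_map <- function(x, m) {
  d <- dim4(x$value)
  bc <- m$value[, , rep(1L, d[3]), , drop = FALSE]
  tape_node(x$tape, x$value * bc, backward = function(g) {
    add_grad(x, g * bc)
    gm <- g * x$value
    dim(gm) <- c(d[1] * d[2], d[3], d[4])
    dm <- colSums(aperm(gm, c(2, 1, 3)))           # sum over channels
    dim(dm) <- c(d[1], d[2], 1, d[4])
    add_grad(m, dm)
  })
}

# 2x2 max pooling, stride 2 (even input sides).
op_maxpool2 <- function(x) {
  d <- dim4(x$value)
  ro <- seq(1, d[1], by = 2); co <- seq(1, d[2], by = 2)
  a <- x$value[ro, co, , , drop = FALSE]
  b <- x$value[ro + 1, co, , , drop = FALSE]
  cc <- x$value[ro, co + 1, , , drop = FALSE]
  dd <- x$value[ro + 1, co + 1, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  tape_node(x$tape, out, backward = function(g) {
    dx <- array(0, d)
    # route gradient to the first maximal entry (fixed a,b,c,d order)
    m1 <- a == out
    m2 <- b == out & !m1
    m3 <- cc == out & !m1 & !m2
    m4 <- dd == out & !m1 & !m2 & !m3
    dx[ro, co, , ] <- g * m1
    dx[ro + 1, co, , ] <- dx[ro + 1, co, , , drop = FALSE] + g * m2
    dx[ro, co + 1, , ] <- dx[ro, co + 1, , , drop = FALSE] + g * m3
    dx[ro + 1, co + 1, , ] <- dx[ro + 1, co + 1, , , drop = FALSE] + g * m4
    add_grad(x, dx)
  })
}

# Nearest-neighbour 2x upsampling.
op_upsample2 <- function(x) {
  d <- dim4(x$value)
  ri <- rep(seq_len(d[1]), each = 2); ci <- rep(seq_len(d[2]), each = 2)
  out <- x$value[ri, ci, , , drop = FALSE]
  tape_node(x$tape, out, backward = function(g) {
    ro <- seq(1, 2 * d[1], by = 2); co <- seq(1, 2 * d[2], by = 2)
    dx <- g[ro, co, , , drop = FALSE] + g[ro + 1, co, , , drop = FALSE] +
      g[ro, co + 1, , , drop = FALSE] + g[ro + 1, co + 1, , , drop = FALSE]
    add_grad(x, dx)
  })
}

# ---- batch normalization ---------------------------------------------------

# Per-channel mean/variance over (rows, cols, batch). Running statistics live
# in the model's state environment under `key` and are used at inference.
op_batchnorm <- function(x, gamma, beta, state, key, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim4(x$value)
  m <- d[1] * d[2] * d[4]
  per_channel <- function(v) {                 # sum over all but channel axis
    dim(v) <- c(d[1] * d[2], d[3], d[4])
    rowSums(colSums(v))                        # colSums -> (C, N); rowSums -> C
  }
  # broadcast a per-channel vector: elementwise ops recycle the (rows*cols*C)
  # pattern across the batch axis, avoiding a full-size allocation
  bc <- function(v) rep(v, each = d[1] * d[2])
  if (training) {
    mu <- per_channel(x$value) / m
    xc <- x$value - bc(mu)
    var <- per_channel(xc * xc) / m
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = mu * 0, var = mu * 0 + 1)
    state[[key]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                         var = (1 - momentum) * st$var + momentum * var)
  } else {
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = numeric(d[3]), var = rep(1, d[3]))
    mu <- st$mean; var <- st$var
    xc <- x$value - bc(mu)
  }
  inv_sd <- 1 / sqrt(var + eps)
  xhat <- xc * bc(inv_sd)
  out <- xhat * bc(gamma$value) + bc(beta$value)
  tape_node(x$tape, out, backward = function(g) {
    add_grad(gamma, per_channel(g * xhat))
    add_grad(beta, per_channel(g))
    dxhat <- g * bc(gamma$value)
    if (training) {
      s1 <- per_channel(dxhat)
      s2 <- per_channel(dxhat * xhat)
      dx <- (dxhat - bc(s1 / m) - xhat * bc(s2 / m)) * bc(inv_sd)
    } else {
      dx <- dxhat * bc(inv_sd)
    }
    add_grad(x, dx)
  })
}

# ---- softmax and losses ----------------------------------------------------

# Softmax over the channel axis.
op_softmax <- function(x) {
  d <- dim4(x$value)
  v <- x$value
  mx <- v[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, v[, , c, , drop = FALSE])
  e <- exp(v - mx[, , rep(1L, d[3]), , drop = FALSE])
  tot <- e[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) tot <- tot + e[, , c, , drop = FALSE]
  p <- e / tot[, , rep(1L, d[3]), , drop = FALSE]
  tape_node(x$tape, p, backward = function(g) {
    gp <- g * p
    s <- gp[, , 1, , drop = FALSE]
    for (c in seq_len(d[3])[-1]) s <- s + gp[, , c, , drop = FALSE]
    add_grad(x, gp - p * s[, , rep(1L, d[3]), , drop = FALSE])
  })
}

# Cross-entropy of softmax probabilities against a one-hot target.
loss_cross_entropy <- function(p, onehot, eps = 1e-7) {
  d <- dim4(p$value)
  npix <- d[1] * d[2] * d[4]
  val <- -sum(onehot * log(p$value + eps)) / npix
  tape_node(p$tape, val, backward = function(g) {
    add_grad(p, -g * onehot / (p$value + eps) / npix)
  })
}

# Smoothed soft-Dice loss over the foreground classes (channel 1 is
# background): 1 - mean_c (2*sum(p_c y_c) + 1) / (sum p_c + sum y_c + 1).
loss_soft_dice <- function(p, onehot) {
  d <- dim4(p$value)
  fg <- seq_len(d[3])[-1]
  num <- den <- numeric(length(fg))
  for (i in seq_along(fg)) {
    c <- fg[i]
    pc <- p$value[, , c, , drop = FALSE]
    yc <- onehot[, , c, , drop = FALSE]
    num[i] <- 2 * sum(pc * yc) + 1
    den[i] <- sum(pc) + sum(yc) + 1
  }
  val <- 1 - mean(num / den)
  tape_node(p$tape, val, backward = function(g) {
    dp <- array(0, d)
    for (i in seq_along(fg)) {
      c <- fg[i]
      yc <- onehot[, , c, , drop = FALSE]
      dp[, , c, ] <- -g / length(fg) * (2 * yc * den[i] - num[i]) / den[i]^2
    }
    add_grad(p, dp)
  })
}

op_scalar_add <- function(a, b) {
  tape_node(a$tape, a$value + b$value, backward = function(g) {
    add_grad(a, g); add_grad(b, g)
  })
}
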