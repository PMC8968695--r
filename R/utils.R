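# Shared internal helpers: seeded RNG scoping, decimal rounding, resampling.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never clobber global
# reproducibility.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round to `digits` decimals, half away from zero on the *decimal* value.
# Base round() follows the binary representation, so e.g. a true decimal
# 0.9295 (stored slightly below the half) would round down; a small guard
# restores the decimal result. Inputs here are non-negative scores.
round_decimal <- function(x, digits = 3) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9) / s
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x == as.integer(x)

# Nearest-neighbour resample of a matrix to (out_h, out_w); pixel-centre
# alignment. Exact inverse pairs: factor-2 down then up on piecewise-constant
# 2x2 blocks reproduces the input.
resize_nearest <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(h, pmax(1L, as.integer(floor((seq_len(out_h) - 0.5) * h / out_h) + 1L)))
  ci <- pmin(w, pmax(1L, as.integer(floor((seq_len(out_w) - 0.5) * w / out_w) + 1L)))
  m[ri, ci, drop = FALSE]
}

# Bilinear resample of a numeric matrix (pixel-centre alignment).
resize_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  yr <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xr <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(h - 1L, pmax(1L, floor(yr) + 1L)); y1 <- pmin(h, y0 + 1L)
  x0 <- pmin(w - 1L, pmax(1L, floor(xr) + 1L)); x1 <- pmin(w, x0 + 1L)
  fy <- pmin(1, pmax(0, yr - (y0 - 1L)))
  fx <- pmin(1, pmax(0, xr - (x0 - 1L)))
  a <- m[y0, x0, drop = FALSE] * (1 - fy) + m[y1, x0, drop = FALSE] * fy
  b <- m[y0, x1, drop = FALSE] * (1 - fy) + m[y1, x1, drop = FALSE] * fy
  a * rep(1 - fx, each = out_h) + b * rep(fx, each = out_h)
}
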