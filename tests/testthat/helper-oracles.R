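# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately avoid the package's own C++ primitives.

# 8-connected component areas by plain R flood fill.
flood_fill_areas <- function(mask) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  visited <- matrix(FALSE, h, w)
  areas <- numeric(0)
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j] || visited[i, j]) next
      stack <- list(c(i, j))
      visited[i, j] <- TRUE
      a <- 0L
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        a <- a + 1L
        for (di in -1:1) for (dj in -1:1) {
          qi <- p[1] + di; qj <- p[2] + dj
          if (qi >= 1 && qi <= h && qj >= 1 && qj <= w &&
              mask[qi, qj] && !visited[qi, qj]) {
            visited[qi, qj] <- TRUE
            stack[[length(stack) + 1L]] <- c(qi, qj)
          }
        }
      }
      areas <- c(areas, a)
    }
  }
  areas
}

# A minimal valid slice sample: one rectangular kidney with an optional
# square tumor inside.
toy_sample <- function(size = 32, kidney = c(8, 24, 8, 24), tumor = NULL) {
  img <- matrix(30, size, size)
  lab <- matrix(0L, size, size)
  img[kidney[1]:kidney[2], kidney[3]:kidney[4]] <- 160
  lab[kidney[1]:kidney[2], kidney[3]:kidney[4]] <- 1L
  if (!is.null(tumor)) {
    img[tumor[1]:tumor[2], tumor[3]:tumor[4]] <- 220
    lab[tumor[1]:tumor[2], tumor[3]:tumor[4]] <- 2L
  }
  slice_sample(img, lab)
}

# Small phantom configuration for fast tests (tumor areas scaled to fit the
# smaller kidneys a 64-pixel canvas allows).
tiny_phantom <- function(seed = 1, tumor_area_range = c(20, 80), ...) {
  phantom_config(image_size = 64, n_slices = 4, seed = seed,
                 tumor_area_range = tumor_area_range, ...)
}
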