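# Tumor-size statistics and augmentation-based rebalancing. The fine stage's
# training pool is skewed by tumor cross-section area; under-represented
# area bins are topped up with geometrically augmented copies (flips,
# right-angle rotations, integer shifts, diagonal mirror) until every
# non-empty bin matches the largest bin's count.

#' Tumor component areas over a sample list
#'
#' One area (pixel count) per 8-connected component of `label == 2`, pooled
#' over all samples.
#'
#' @param samples List of [slice_sample()] objects.
#' @return Numeric vector of component areas (possibly empty).
#' @export
tumor_areas <- function(samples) {
  unlist(lapply(samples, function(s) {
    lab <- label_components(s$label == 2L)
    if (max(lab) == 0) return(numeric(0))
    as.numeric(tabulate(lab[lab > 0L]))
  }))
}

#' Fixed-width histogram of tumor areas
#'
#' Right-open bins of uniform width starting at 0; the final bin absorbs all
#' areas `>= max_area`.
#'
#' @param areas Non-negative numeric vector.
#' @param bin_width Bin width in pixels (default 500).
#' @param max_area Upper edge of the regular bins; defaults to `max(areas)`
#'   rounded up to a bin boundary.
#' @return An object of class `tumor_size_histogram` with `bin_edges` and
#'   `counts` (`length(counts) == length(bin_edges) - 1`).
#' @export
build_tumor_histogram <- function(areas, bin_width = 500, max_area = NULL) {
  if (bin_width <= 0) stopf("bin_width must be positive")
  if (any(areas < 0)) stopf("areas must be non-negative")
  if (is.null(max_area))
    max_area <- max(bin_width, ceiling(max(areas, 0) / bin_width) * bin_width)
  edges <- seq(0, max_area, by = bin_width)
  if (length(edges) < 2) edges <- c(0, max_area)
  counts <- tabulate(pmin(findInterval(areas, edges), length(edges) - 1L),
                     nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts),
            class = "tumor_size_histogram")
}

# Bin index of an area under a histogram's edges (last bin absorbs overflow).
hist_bin_of <- function(hist, area) {
  pmin(findInterval(area, hist$bin_edges), length(hist$bin_edges) - 1L)
}

#' Write a tumor-size histogram as CSV
#'
#' @param hist A `tumor_size_histogram`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_tumor_histogram <- function(hist, path) {
  k <- length(hist$counts)
  write.csv(data.frame(bin_lo = hist$bin_edges[seq_len(k)],
                       bin_hi = hist$bin_edges[-1],
                       count = hist$counts),
            path, row.names = FALSE)
  invisible(path)
}

#' Construct an augmentation operation
#'
#' @param kind One of `"horizontal_flip"`, `"vertical_flip"`, `"rotate90k"`,
#'   `"shift"`, `"mirror"`. `"mirror"` is the flip about the main diagonal
#'   (transpose), distinct from the horizontal/vertical flips; `"rotate90k"`
#'   rotates counter-clockwise by `k` quarter turns.
#' @param k Quarter turns (1..3) for `rotate90k`.
#' @param dx,dy Integer column/row shift for `shift` (magnitude below the
#'   patch side; padding uses the image minimum and label 0).
#' @return An object of class `augmentation_op`.
#' @export
augmentation_op <- function(kind = c("horizontal_flip", "vertical_flip",
                                     "rotate90k", "shift", "mirror"),
                            k = 1L, dx = 0L, dy = 0L) {
  kind <- match.arg(kind)
  if (kind == "rotate90k" && !k %in% 1:3) stopf("k must be 1, 2 or 3")
  if (kind == "shift" && (!is_count(dx) || !is_count(dy)))
    stopf("dx and dy must be integers")
  structure(list(kind = kind, k = as.integer(k),
                 dx = as.integer(dx), dy = as.integer(dy)),
            class = "augmentation_op")
}

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

shift_matrix <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  if (abs(dy) >= h || abs(dx) >= w) stopf("shift magnitude must be below the patch side")
  out <- matrix(fill, h, w)
  src_r <- max(1, 1 - dy):min(h, h - dy)
  src_c <- max(1, 1 - dx):min(w, w - dx)
  out[src_r + dy, src_c + dx] <- m[src_r, src_c]
  out
}

#' Apply an augmentation to a slice sample
#'
#' Image and label are transformed by the same spatial map; shifts pad the
#' image with its minimum intensity and the label with background (0).
#'
#' @param sample A [slice_sample()].
#' @param op An [augmentation_op()].
#' @return The augmented [slice_sample()].
#' @export
apply_augmentation <- function(sample, op) {
  if (!inherits(op, "augmentation_op")) stopf("op must be an augmentation_op")
  f <- switch(op$kind,
    horizontal_flip = function(m) m[, ncol(m):1, drop = FALSE],
    vertical_flip   = function(m) m[nrow(m):1, , drop = FALSE],
    mirror          = t,
    rotate90k       = function(m) {
      for (i in seq_len(op$k)) m <- rot90_ccw(m)
      m
    },
    shift           = NULL)
  if (op$kind == "shift") {
    sample$image <- shift_matrix(sample$image, op$dy, op$dx, min(sample$image))
    sample$label <- shift_matrix(sample$label, op$dy, op$dx, 0L)
  } else {
    sample$image <- f(sample$image)
    sample$label <- f(sample$label)
  }
  sample$label <- matrix(as.integer(sample$label), nrow(sample$label))
  sample
}

# Draw one random augmentation op from the uniform op menu.
random_augmentation <- function(max_shift) {
  menu <- c("horizontal_flip", "vertical_flip", "rotate90k", "shift", "mirror")
  kind <- menu[sample.int(5L, 1)]
  switch(kind,
    rotate90k = augmentation_op("rotate90k", k = sample.int(3L, 1)),
    shift = augmentation_op("shift",
                            dx = sample.int(2L * max_shift + 1L, 1) - max_shift - 1L,
                            dy = sample.int(2L * max_shift + 1L, 1) - max_shift - 1L),
    augmentation_op(kind))
}

#' Balance a fine-stage dataset by tumor-size bin
#'
#' Samples are binned by their total tumor pixel count using the histogram's
#' edges; every non-empty bin below the maximum count is topped up with
#' augmented copies of its own samples (source sample and operation drawn
#' uniformly with the seeded generator) until all non-empty bins reach the
#' maximum. Originals are always retained exactly once; shifts that would
#' push tumor pixels off the patch are rejected and resampled. Samples
#' without tumor pass through unchanged.
#'
#' @param samples List of [slice_sample()] objects.
#' @param hist A `tumor_size_histogram` built from these samples.
#' @param rng_seed Integer seed; the result is a pure function of inputs and
#'   seed.
#' @param max_shift Maximum shift magnitude (pixels) for the shift op.
#' @return The balanced sample list (originals first, copies appended). The
#'   attribute `"manifest"` records source index and op for every copy.
#' @export
balance_dataset <- function(samples, hist, rng_seed = 1L, max_shift = 10L) {
  area_of <- vapply(samples, function(s) sum(s$label == 2L), numeric(1))
  bins <- ifelse(area_of > 0, hist_bin_of(hist, area_of), NA_integer_)
  counts <- tabulate(bins[!is.na(bins)], nbins = length(hist$counts))
  target <- max(counts)
  out <- samples
  manifest <- list()
  with_seed(rng_seed, {
    for (b in which(counts > 0 & counts < target)) {
      src_pool <- which(!is.na(bins) & bins == b)
      need <- target - counts[b]
      added <- 0L
      while (added < need) {
        si <- src_pool[sample.int(length(src_pool), 1)]
        op <- random_augmentation(max_shift)
        aug <- apply_augmentation(samples[[si]], op)
        # reject shifts that clip tumor pixels (area would change bins)
        if (sum(aug$label == 2L) != area_of[si]) next
        out[[length(out) + 1L]] <- aug
        manifest[[length(manifest) + 1L]] <-
          list(source = si, kind = op$kind, k = op$k, dx = op$dx, dy = op$dy)
        added <- added + 1L
      }
    }
  })
  attr(out, "manifest") <- manifest
  out
}

#' Write a balancing manifest as JSON
#'
#' @param balanced Result of [balance_dataset()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_balance_manifest <- function(balanced, path) {
  jsonlite::write_json(attr(balanced, "manifest") %||% list(), path,
                       auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
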