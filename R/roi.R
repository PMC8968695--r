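# Coarse-to-fine glue: connected-component ROI seeds from a binary mask, the
# 128/256 window-expansion rule, cropping, rescaling to the fine model's
# input grid, and pasting fine predictions back onto the full-size canvas.

#' 8-connected component labeling
#'
#' @param mask 2D binary (logical or 0/1) matrix.
#' @return Integer matrix of component labels (0 = background), labels
#'   assigned in raster-scan discovery order starting at 1.
#' @export
label_components <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  label_components_cpp(m)
}

#' Tight bounding boxes of mask components
#'
#' One tight box per 8-connected foreground component, ordered by component
#' pixel count, largest first. Bounds are 0-based half-open.
#'
#' @param binary_mask 2D binary matrix.
#' @return A list of tight boxes, each a list with `row0`, `col0`, `row1`,
#'   `col1`, `area`; empty list for an empty mask.
#' @export
mask_to_rois <- function(binary_mask) {
  lab <- label_components(binary_mask)
  n <- max(lab)
  if (n == 0) return(list())
  boxes <- lapply(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    list(row0 = min(idx[, 1]) - 1L, col0 = min(idx[, 2]) - 1L,
         row1 = max(idx[, 1]), col1 = max(idx[, 2]),
         area = nrow(idx))
  })
  boxes[order(vapply(boxes, `[[`, numeric(1), "area"), decreasing = TRUE)]
}

#' Construct an ROI window
#'
#' @param row0,col0,row1,col1 0-based half-open pixel bounds; the window must
#'   be square with side `size_class`.
#' @param size_class Window side in pixels.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(row0, col0, row1, col1, size_class) {
  if (row1 - row0 != size_class || col1 - col0 != size_class)
    stopf("window must be square with side size_class")
  if (row0 < 0 || col0 < 0) stopf("window bounds must be non-negative")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1),
                 size_class = as.integer(size_class)),
            class = "roi_box")
}

#' Expand a tight box to a fixed-size ROI window
#'
#' Implements the two-case rule: a tight box whose sides both fit within
#' `sizes[1]` (default 128) gets a `sizes[1]`-square window; anything larger
#' gets a `sizes[2]`-square (default 256) window. The window is centred on
#' the tight box and translated -- never shrunk -- to fit inside the canvas.
#' On canvases smaller than the nominal window the side is capped at the
#' canvas (full-canvas window).
#'
#' @param tight_box A tight box (list with `row0`, `col0`, `row1`, `col1`),
#'   e.g. from [mask_to_rois()].
#' @param canvas_size Canvas side in pixels (scalar, or c(rows, cols)).
#' @param sizes Two-step window-size ladder, default `c(128, 256)`.
#' @return A [roi_box()] fully containing the tight box whenever the window
#'   size allows it.
#' @export
expand_roi <- function(tight_box, canvas_size, sizes = c(128, 256)) {
  canvas <- rep(as.integer(canvas_size), length.out = 2)
  th <- tight_box$row1 - tight_box$row0
  tw <- tight_box$col1 - tight_box$col0
  size <- if (th <= sizes[1] && tw <= sizes[1]) sizes[1] else sizes[2]
  size <- as.integer(min(size, canvas))
  place <- function(lo, hi, extent) {
    start <- as.integer(floor((lo + hi) / 2) - size %/% 2)
    min(max(start, 0L), extent - size)
  }
  r0 <- place(tight_box$row0, tight_box$row1, canvas[1])
  c0 <- place(tight_box$col0, tight_box$col1, canvas[2])
  roi_box(r0, c0, r0 + size, c0 + size, size)
}

#' Crop a window out of an image or label matrix
#'
#' @param x 2D matrix.
#' @param box A [roi_box()].
#' @return The exact `size_class`-square sub-matrix.
#' @export
crop_patch <- function(x, box) {
  if (box$row1 > nrow(x) || box$col1 > ncol(x))
    stopf("box exceeds canvas bounds")
  x[(box$row0 + 1L):box$row1, (box$col0 + 1L):box$col1, drop = FALSE]
}

#' Rescale a cropped patch onto the fine model's input grid
#'
#' Patches already at `target` pass through unchanged; patches at twice the
#' target are down-scaled by a factor 2 (bilinear for images, nearest for
#' labels); any other side is resampled generically the same way.
#'
#' @param patch Square matrix from [crop_patch()].
#' @param target Fine-stage input side (default 128).
#' @param kind `"image"` or `"label"`.
#' @return A `target`-square matrix; label output keeps values in \{0, 1, 2\}.
#' @export
to_fine_input <- function(patch, target = 128, kind = c("image", "label")) {
  kind <- match.arg(kind)
  side <- nrow(patch)
  if (side != ncol(patch)) stopf("patch must be square")
  if (side == target) return(patch)
  if (kind == "label") {
    out <- resize_nearest(patch, target, target)
    matrix(as.integer(out), target, target)
  } else {
    resize_bilinear(patch, target, target)
  }
}

#' Rescale a fine prediction back to the ROI window size
#'
#' Nearest-neighbour up-scaling (the inverse of [to_fine_input()] on labels).
#'
#' @param pred `target`-square label matrix.
#' @param size_class ROI window side to restore.
#' @return A `size_class`-square integer label matrix.
#' @export
from_fine_output <- function(pred, size_class) {
  if (nrow(pred) == size_class) return(pred)
  out <- resize_nearest(pred, size_class, size_class)
  matrix(as.integer(out), size_class, size_class)
}

#' Paste a predicted patch back onto the full-size canvas
#'
#' Pixels inside the box are replaced by the patch; everything outside is
#' untouched. When ROIs overlap, later pastes win inside the overlap; the
#' cascade pastes in component-size-descending order so smaller ROIs win
#' locally.
#'
#' @param canvas_label Full-size integer label matrix.
#' @param patch_pred Label patch with side `box$size_class`.
#' @param box A [roi_box()].
#' @return The updated canvas.
#' @export
paste_back <- function(canvas_label, patch_pred, box) {
  if (nrow(patch_pred) != box$size_class || ncol(patch_pred) != box$size_class)
    stopf("patch side must equal the box size_class")
  if (box$row1 > nrow(canvas_label) || box$col1 > ncol(canvas_label))
    stopf("box exceeds canvas bounds")
  canvas_label[(box$row0 + 1L):box$row1, (box$col0 + 1L):box$col1] <- patch_pred
  canvas_label
}

#' Serialize ROI boxes to JSON
#'
#' @param boxes List of [roi_box()] objects.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_roi_boxes <- function(boxes, path) {
  jsonlite::write_json(lapply(boxes, unclass), path, auto_unbox = TRUE)
  invisible(path)
}
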