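# End-to-end inference: coarse binary localization, ROI expansion, fuzzy
# enhancement of the crop, fine 3-class segmentation, and paste-back onto
# the full-size canvas.

#' Run the coarse-to-fine cascade on one slice
#'
#' The coarse model produces a binary kidney+tumor mask; each 8-connected
#' component yields an ROI window via the expansion rule; each window is
#' cropped, fuzzy-enhanced through the fixed z-score window
#' ([enhance_windowed()]; slices are expected on the preprocessed, z-scored
#' scale), rescaled to the fine input grid, segmented into 3 classes,
#' rescaled back, and pasted onto a zero canvas (all pixels predicted
#' background stay 0). ROIs are pasted in component-size-descending
#' order, so smaller ROIs win inside overlaps. A slice with no coarse
#' foreground returns an all-background map.
#'
#' @param coarse_model A 2-class `nephroseg_model`, or a function
#'   `f(image)` returning a binary mask (stub/oracle use).
#' @param fine_model A 3-class `nephroseg_model`, or a function
#'   `f(patch, roi)` returning a label patch at the fine input size.
#' @param slice_image 2D image matrix at the coarse model's input size.
#' @param roi_sizes ROI window ladder (default `c(128, 256)`).
#' @param fine_input Fine-stage input side; defaults to the fine model's
#'   configured input size (or `roi_sizes[1]` for function stubs).
#' @param return_rois Also return the ROI boxes used.
#' @return The full-size 3-class label map, or a list `(labels, rois)` when
#'   `return_rois = TRUE`.
#' @export
run_cascade <- function(coarse_model, fine_model, slice_image,
                        roi_sizes = c(128, 256), fine_input = NULL,
                        return_rois = FALSE) {
  if (is.null(fine_input)) {
    fine_input <- if (is.function(fine_model)) roi_sizes[1]
                  else fine_model$config$input_size
  }
  mask <- if (is.function(coarse_model)) coarse_model(slice_image) != 0
          else predict_labels(coarse_model, slice_image) > 0L
  canvas <- matrix(0L, nrow(slice_image), ncol(slice_image))
  boxes <- mask_to_rois(mask)
  rois <- list()
  for (b in boxes) {
    roi <- expand_roi(b, dim(slice_image), sizes = roi_sizes)
    rois[[length(rois) + 1L]] <- roi
    patch <- enhance_windowed(crop_patch(slice_image, roi)) / 255
    fin <- to_fine_input(patch, fine_input, "image")
    pred <- if (is.function(fine_model)) fine_model(fin, roi)
            else predict_labels(fine_model, fin)
    canvas <- paste_back(canvas, from_fine_output(pred, roi$size_class), roi)
  }
  if (return_rois) list(labels = canvas, rois = rois) else canvas
}

#' Evaluate a trained cascade on held-out slices
#'
#' @param models List with `coarse` and `fine` models (e.g. from
#'   [train_cascade()]).
#' @param samples Held-out list of [slice_sample()] objects.
#' @param roi_sizes ROI window ladder.
#' @return A `dice_report` from [evaluate_segmentation()].
#' @export
evaluate_cascade <- function(models, samples, roi_sizes = c(128, 256)) {
  preds <- lapply(samples, function(s)
    run_cascade(models$coarse, models$fine, s$image, roi_sizes = roi_sizes))
  evaluate_segmentation(preds, lapply(samples, `[[`, "label"))
}
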