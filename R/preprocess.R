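# KiTS19-style data preparation: axial slice extraction with discard of
# unlabeled slices, pooled percentile clipping of intensity outliers, and
# z-scoring by foreground (kidney + tumor) statistics. Statistics are fit
# once on the training pool and frozen for later application.

#' Construct a slice sample
#'
#' The pipeline's atomic record: one 2D gray image with its 3-class label
#' mask (0 background, 1 kidney, 2 tumor).
#'
#' @param image 2D numeric matrix.
#' @param label 2D integer matrix, same shape, values in \{0, 1, 2\}.
#' @param case_id Case identifier string.
#' @param slice_index 0-based axial slice index within the case.
#' @return An object of class `slice_sample`.
#' @export
slice_sample <- function(image, label, case_id = "case", slice_index = 0L) {
  if (!is.matrix(image) || !is.matrix(label) || !all(dim(image) == dim(label)))
    stopf("image and label must be matrices of equal shape")
  label <- matrix(as.integer(label), nrow(label), ncol(label))
  if (!all(label %in% 0:2)) stopf("label values must be in {0, 1, 2}")
  if (!is_count(slice_index) || slice_index < 0)
    stopf("slice_index must be an integer >= 0")
  structure(list(image = image, label = label, case_id = as.character(case_id),
                 slice_index = as.integer(slice_index)),
            class = "slice_sample")
}

#' Cut a labeled volume into 2D slice samples
#'
#' One sample per axial slice whose label mask contains at least one nonzero
#' pixel; slices without kidney markers are discarded. Slice order is
#' preserved and `slice_index` records the 0-based position in the original
#' volume.
#'
#' @param image_volume,label_volume Arrays shaped (n_slices, rows, cols).
#' @param case_id Case identifier attached to every sample.
#' @return A list of [slice_sample()] objects (possibly empty).
#' @export
slice_volume <- function(image_volume, label_volume, case_id = "case") {
  if (!all(dim(image_volume) == dim(label_volume)))
    stopf("image and label volumes must have identical shape")
  out <- list()
  for (z in seq_len(dim(image_volume)[1])) {
    lab <- matrix(as.integer(label_volume[z, , ]), dim(label_volume)[2])
    if (!any(lab != 0L)) next
    out[[length(out) + 1L]] <-
      slice_sample(matrix(image_volume[z, , ], dim(image_volume)[2]), lab,
                   case_id = case_id, slice_index = z - 1L)
  }
  out
}

#' Fit preprocessing statistics on a training pool
#'
#' Clip bounds are the `lo` / `hi` percentiles of all intensities pooled over
#' the provided samples (linear interpolation between order statistics);
#' foreground mean and standard deviation are computed over pixels with
#' label > 0 *after* clipping.
#'
#' @param samples Non-empty list of [slice_sample()] objects.
#' @param lo,hi Percentiles in `[0, 100]` (defaults 0.5 and 99.5).
#' @return An object of class `preprocess_stats` with fields `clip_lo`,
#'   `clip_hi`, `fg_mean`, `fg_sd`.
#' @export
fit_preprocess_stats <- function(samples, lo = 0.5, hi = 99.5) {
  if (length(samples) == 0) stopf("samples must be a non-empty list")
  if (!(lo >= 0 && hi <= 100 && lo <= hi)) stopf("need 0 <= lo <= hi <= 100")
  pooled <- unlist(lapply(samples, function(s) as.numeric(s$image)))
  cl <- unname(quantile(pooled, c(lo, hi) / 100, type = 7))
  fg <- unlist(lapply(samples, function(s) {
    pmin(cl[2], pmax(cl[1], s$image[s$label > 0L]))
  }))
  if (length(fg) == 0) stopf("no foreground pixels in the pool")
  fg_sd <- sd(fg)
  if (!is.finite(fg_sd) || fg_sd <= 0)
    stopf("degenerate input: foreground has zero variance")
  structure(list(clip_lo = cl[1], clip_hi = cl[2],
                 fg_mean = mean(fg), fg_sd = fg_sd),
            class = "preprocess_stats")
}

#' Apply frozen preprocessing to one slice sample
#'
#' Clamps intensities to `[clip_lo, clip_hi]`, then z-scores with the frozen
#' foreground statistics. The label is untouched.
#'
#' @param sample A [slice_sample()].
#' @param stats A `preprocess_stats` object from [fit_preprocess_stats()].
#' @return The transformed [slice_sample()].
#' @export
apply_preprocess <- function(sample, stats) {
  if (!inherits(stats, "preprocess_stats")) stopf("stats must be preprocess_stats")
  # pmin/pmax take attributes from their first argument: keep the matrix first
  x <- pmax(pmin(sample$image, stats$clip_hi), stats$clip_lo)
  sample$image <- (x - stats$fg_mean) / stats$fg_sd
  sample
}

#' Save / load preprocessing statistics as JSON
#'
#' @param stats A `preprocess_stats` object.
#' @param path JSON file path.
#' @return `write_preprocess_stats` returns `path` invisibly;
#'   `read_preprocess_stats` returns the `preprocess_stats` object.
#' @export
write_preprocess_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess_stats
#' @export
read_preprocess_stats <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "preprocess_stats")
}

#' Read a KiTS19-style case directory
#'
#' Expects `imaging.nii.gz` (or `.nii`) and `segmentation.nii.gz` under
#' `case_dir`, shaped (n_slices, rows, cols).
#'
#' @param case_dir Path to the case directory.
#' @return A list with `image` and `label` arrays.
#' @export
read_phantom_case <- function(case_dir) {
  find1 <- function(stem) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(case_dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    stopf("no %s volume under %s", stem, case_dir)
  }
  img <- RNifti::readNifti(find1("imaging"))
  seg <- RNifti::readNifti(find1("segmentation"))
  list(image = array(as.numeric(img), dim = dim(img)),
       label = array(as.integer(round(seg)), dim = dim(seg)))
}
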