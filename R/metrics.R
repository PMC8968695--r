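# Smoothed Dice evaluation. The per-image Dice adds 1 to both numerator and
# denominator so that an image where a class is absent from prediction and
# reference alike scores 1 instead of 0/0. The composite score is the
# arithmetic mean of the kidney and tumor class means, the KiTS19
# leaderboard convention.

#' Smoothed Dice coefficient of two binary masks
#'
#' Computes `(2|A intersect B| + 1) / (|A| + |B| + 1)`. Two empty masks score
#' exactly 1.
#'
#' @param pred_mask,true_mask Binary (logical or 0/1) matrices of equal shape.
#' @return A value in `[0, 1]`; 1 if and only if the masks are identical.
#' @export
dice_smoothed <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask)))
    stopf("masks must have equal shape")
  a <- pred_mask != 0
  b <- true_mask != 0
  (2 * sum(a & b) + 1) / (sum(a) + sum(b) + 1)
}

#' Evaluate 3-class predictions against reference labels
#'
#' Per image, the kidney Dice compares the masks `label == 1` (strict mode;
#' tumor pixels do not count as kidney) or `label >= 1` (union mode), and the
#' tumor Dice compares `label == 2`. Class means are unweighted averages over
#' images; the composite is the mean of the two class means.
#'
#' @param pred_labels,true_labels Equal-length lists of integer label
#'   matrices with values in \{0, 1, 2\}.
#' @param kidney_mode `"strict"` (default) or `"union"`.
#' @return An object of class `dice_report`: list with `per_image` (data frame
#'   of kidney/tumor Dice per image), `kidney_dice_mean`, `tumor_dice_mean`,
#'   `composite` (unrounded), and `n`.
#' @export
evaluate_segmentation <- function(pred_labels, true_labels,
                                  kidney_mode = c("strict", "union")) {
  kidney_mode <- match.arg(kidney_mode)
  if (length(pred_labels) == 0 || length(pred_labels) != length(true_labels))
    stopf("need equal-length, non-empty prediction and reference lists")
  kd <- td <- numeric(length(pred_labels))
  for (i in seq_along(pred_labels)) {
    p <- pred_labels[[i]]; t <- true_labels[[i]]
    kmask <- function(l) if (kidney_mode == "strict") l == 1L else l >= 1L
    kd[i] <- dice_smoothed(kmask(p), kmask(t))
    td[i] <- dice_smoothed(p == 2L, t == 2L)
  }
  km <- mean(kd); tm <- mean(td)
  structure(list(per_image = data.frame(kidney_dice = kd, tumor_dice = td),
                 kidney_dice_mean = km, tumor_dice_mean = tm,
                 composite = (km + tm) / 2, n = length(pred_labels)),
            class = "dice_report")
}

#' Composite score from class-mean Dice values
#'
#' Arithmetic mean of the kidney and tumor Dice, rounded to 3 decimals (half
#' away from zero on the decimal value, matching reporting precision).
#'
#' @param kidney_dice,tumor_dice Values in `[0, 1]`.
#' @return The rounded composite score.
#' @export
composite_score <- function(kidney_dice, tumor_dice) {
  if (any(kidney_dice < 0 | kidney_dice > 1 | tumor_dice < 0 | tumor_dice > 1))
    stopf("Dice values must lie in [0, 1]")
  round_decimal((kidney_dice + tumor_dice) / 2, 3)
}

#' Write a Dice report as CSV
#'
#' One row per image plus a final average row, with columns kidney_dice,
#' tumor_dice and composite.
#'
#' @param report A `dice_report` from [evaluate_segmentation()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_dice_report <- function(report, path) {
  df <- report$per_image
  df$composite <- (df$kidney_dice + df$tumor_dice) / 2
  df <- rbind(df, data.frame(kidney_dice = report$kidney_dice_mean,
                             tumor_dice = report$tumor_dice_mean,
                             composite = report$composite))
  df$image <- c(seq_len(report$n), NA)
  write.csv(df[, c("image", "kidney_dice", "tumor_dice", "composite")],
            path, row.names = FALSE)
  invisible(path)
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice report over %d images\n", x$n))
  cat(sprintf("  kidney Dice mean: %.3f\n", x$kidney_dice_mean))
  cat(sprintf("  tumor Dice mean:  %.3f\n", x$tumor_dice_mean))
  cat(sprintf("  composite score:  %.3f\n",
              composite_score(x$kidney_dice_mean, x$tumor_dice_mean)))
  invisible(x)
}
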