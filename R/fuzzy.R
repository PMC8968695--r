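# Fuzzy-set gray-level enhancement.
#
# Every pixel (normalized gray m in [0,1]) is fuzzified into three rule
# memberships -- dark, gray, bright -- and the rule consequents push dark
# pixels darker, keep gray pixels gray, and push bright pixels brighter.
# Collapsing the memberships by the center-of-gravity method with output
# singletons (v_d, v_g, v_b) yields the enhanced gray level. The published
# closed-form transform is a literal piecewise function with breakpoints
# 0.15 / 0.43 / 0.71 and an 0.45 offset in its third branch that makes it
# discontinuous at 0.43 and 0.71; both forms are provided.

#' Fuzzy enhancement parameters
#'
#' Breakpoints partition the normalized gray axis into dark / gray / bright
#' regions; singletons are the crisp output levels of the three rules used by
#' the center-of-gravity defuzzifier.
#'
#' @param b1,b2,b3 Strictly increasing breakpoints in (0, 1]. The dark
#'   membership is 1 below `b1` and falls linearly to 0 at `b2`; the bright
#'   membership rises linearly from 0 at `b2` to 1 at `b3`; the gray
#'   membership is the triangular complement peaking at `b2`.
#' @param v_d,v_g,v_b Output singletons (gray levels in `[0, 255]`) for the
#'   dark / gray / bright rules.
#' @return An object of class `membership_params`.
#' @export
membership_params <- function(b1 = 0.15, b2 = 0.43, b3 = 0.71,
                              v_d = 0, v_g = 127, v_b = 255) {
  if (!(0 < b1 && b1 < b2 && b2 < b3 && b3 <= 1))
    stopf("breakpoints must satisfy 0 < b1 < b2 < b3 <= 1")
  if (!(0 <= v_d && v_d <= v_g && v_g <= v_b && v_b <= 255))
    stopf("singletons must satisfy 0 <= v_d <= v_g <= v_b <= 255")
  structure(list(b1 = b1, b2 = b2, b3 = b3, v_d = v_d, v_g = v_g, v_b = v_b),
            class = "membership_params")
}

#' Fuzzify a normalized gray level
#'
#' @param m Normalized gray level(s) in `[0, 1]` (vectorized).
#' @param params A [membership_params()] object.
#' @return A list with numeric components `mu_dark`, `mu_gray`, `mu_bright`,
#'   each in `[0, 1]`; they are never simultaneously zero for in-range `m`.
#' @export
membership <- function(m, params = membership_params()) {
  if (any(!is.finite(m)) || any(m < 0 | m > 1))
    stopf("m must lie in [0, 1]")
  b1 <- params$b1; b2 <- params$b2; b3 <- params$b3
  mu_dark <- ifelse(m <= b1, 1, ifelse(m >= b2, 0, (b2 - m) / (b2 - b1)))
  mu_bright <- ifelse(m <= b2, 0, ifelse(m >= b3, 1, (m - b2) / (b3 - b2)))
  mu_gray <- ifelse(m <= b1 | m >= b3, 0,
                    ifelse(m <= b2, (m - b1) / (b2 - b1), (b3 - m) / (b3 - b2)))
  list(mu_dark = mu_dark, mu_gray = mu_gray, mu_bright = mu_bright)
}

#' Center-of-gravity defuzzification
#'
#' Collapses the three rule memberships onto one output gray level:
#' the membership-weighted mean of the output singletons.
#'
#' @param mu A list with `mu_dark`, `mu_gray`, `mu_bright` (as returned by
#'   [membership()]).
#' @param params A [membership_params()] object.
#' @return Output gray level(s) in `[v_d, v_b]`.
#' @export
defuzzify_cog <- function(mu, params = membership_params()) {
  tot <- mu$mu_dark + mu$mu_gray + mu$mu_bright
  if (any(tot <= 0))
    stopf("degenerate input: all memberships are zero")
  (mu$mu_dark * params$v_d + mu$mu_gray * params$v_g +
     mu$mu_bright * params$v_b) / tot
}

#' Piecewise fuzzy gray-level transform
#'
#' The literal published piecewise transform mapping normalized gray
#' `m` in `[0,1]` to an output level in `[0, 255]`:
#' \deqn{f(m) = 0 \textrm{ on } [0, 0.15);\quad (m-0.15)/0.28 \times 127
#'   \textrm{ on } [0.15, 0.43);}
#' \deqn{(m-0.45)/0.28 \times 255 + (0.71-m)/0.28 \times 127
#'   \textrm{ on } [0.43, 0.71);\quad 255 \textrm{ otherwise.}}
#' The third branch's 0.45 offset (rather than 0.43) makes the transform
#' discontinuous at 0.43 and 0.71; it is reproduced verbatim by default.
#' `continuous = TRUE` substitutes 0.43 and rescales the branch to reach 255
#' at 0.71, giving a continuous variant.
#'
#' @param m Normalized gray level(s) in `[0, 1]` (vectorized).
#' @param continuous Replace the discontinuous third branch with a continuous
#'   interpolation (default `FALSE`: evaluate the transform exactly as
#'   printed).
#' @return Output gray level(s) in `[0, 255]` (real-valued; no integer
#'   rounding).
#' @export
enhance_pixel <- function(m, continuous = FALSE) {
  if (any(!is.finite(m)) || any(m < 0 | m > 1))
    stopf("m must lie in [0, 1]")
  lo <- if (continuous) 0.43 else 0.45
  scale3 <- if (continuous) 255 * 0.28 / (0.71 - 0.43) else 255
  out <- ifelse(m < 0.15, 0,
         ifelse(m < 0.43, (m - 0.15) / 0.28 * 127,
         ifelse(m < 0.71, (m - lo) / 0.28 * scale3 + (0.71 - m) / 0.28 * 127,
                255)))
  pmin(255, pmax(0, out))
}

#' Fuzzy enhancement under a fixed intensity window
#'
#' Applies the piecewise fuzzy transform after mapping intensities through a
#' fixed window (the window/level convention of CT display): values at
#' `center - width/2` and below map to m = 0, values at `center + width/2`
#' and above to m = 1. With foreground-z-scored inputs the default window
#' `[-3, 3]` places typical kidney tissue on the transform's gray plateau
#' while dark and bright lesions saturate, matching the dark/gray/bright rule
#' semantics. Unlike per-image min-max normalization, the mapping does not
#' depend on the patch content, so the same tissue always lands on the same
#' branch.
#'
#' @param image 2D numeric matrix (any real scale; typically z-scored).
#' @param center,width Window centre and full width on the input scale.
#' @param continuous Passed to [enhance_pixel()].
#' @return Enhanced image matrix with values in `[0, 255]`.
#' @export
enhance_windowed <- function(image, center = 0, width = 6, continuous = FALSE) {
  if (!(width > 0)) stopf("width must be positive")
  m <- pmin(1, pmax(0, (image - center) / width + 0.5))
  out <- enhance_pixel(m, continuous = continuous)
  dim(out) <- dim(image)
  out
}

#' Fuzzy-set enhancement of a gray image
#'
#' Min-max normalizes the image to `[0, 1]` and applies [enhance_pixel()] to
#' every pixel via a lookup table over the input bit depth. Input values are
#' expected to be whole numbers on the `0..2^bit_depth - 1` scale (the usual
#' case for CT slices already windowed to integers); other numeric input is
#' quantized onto that grid first.
#'
#' @param image 2D numeric matrix, finite-valued.
#' @param bit_depth Input bit depth (8 or 16); fixes the lookup-table size.
#' @param integer_output Round results to integers (round-half-to-even, then
#'   clamp to `[0, 255]`). Default `TRUE`.
#' @param continuous Passed to [enhance_pixel()].
#' @return Enhanced image matrix with values in `[0, 255]`. A constant image
#'   (undefined normalization) is returned unchanged with a warning.
#' @export
enhance_image <- function(image, bit_depth = 8, integer_output = TRUE,
                          continuous = FALSE) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stopf("image must be a finite-valued numeric matrix")
  if (!bit_depth %in% c(8, 16)) stopf("bit_depth must be 8 or 16")
  n_levels <- 2L^bit_depth
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: min-max normalization undefined, passing through")
    return(image)
  }
  if (any(image != round(image)) || rng[1] < 0 || rng[2] > n_levels - 1) {
    # quantize arbitrary numeric input onto the bit-depth grid
    image <- round((image - rng[1]) / (rng[2] - rng[1]) * (n_levels - 1))
    rng <- range(image)
  }
  # LUT over raw levels: each observed level v maps through the same min-max
  # normalization a per-pixel loop would use, so LUT == naive loop bitwise.
  levels_present <- rng[1]:rng[2]
  lut <- enhance_pixel((levels_present - rng[1]) / (rng[2] - rng[1]),
                       continuous = continuous)
  if (integer_output) lut <- pmin(255, pmax(0, round(lut)))
  out <- lut[image - rng[1] + 1L]
  dim(out) <- dim(image)
  out
}
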