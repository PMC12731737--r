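#' @keywords internal
.check_masks <- function(gt, pred) {
  if (!is.logical(gt) || !is.logical(pred)) stop("masks must be logical matrices")
  if (!identical(dim(gt), dim(pred))) stop("mask shapes must match")
  invisible(NULL)
}

#' Misclassification error
#'
#' Fraction of pixels whose binary label disagrees with the ground truth:
#' `ME = 1 - (|B_GT n B_T| + |F_GT n F_T|) / (|B_GT| + |F_GT|)`. 0 for a
#' perfect segmentation, 1 for a totally wrong one.
#'
#' @param gt,pred logical masks (`TRUE` = foreground) of equal shape.
#' @return list with `ME` and `misclassified` (pixel count).
#' @export
misclassification_error <- function(gt, pred) {
  .check_masks(gt, pred)
  wrong <- sum(gt != pred)
  list(ME = wrong / length(gt), misclassified = wrong)
}

#' Jaccard similarity of the foregrounds, in percent
#'
#' `100 |F_GT n F_T| / |F_GT u F_T|`; 100 for a correct segmentation. When
#' both foregrounds are empty the intersection equals the union, so the
#' continuity limit 100 is returned.
#'
#' @inheritParams misclassification_error
#' @export
jaccard_similarity <- function(gt, pred) {
  .check_masks(gt, pred)
  uni <- sum(gt | pred)
  if (uni == 0L) return(100)
  100 * sum(gt & pred) / uni
}

#' Relative foreground area error
#'
#' `||F_GT| - |F_T|| / max(|F_GT|, |F_T|)`; 0 when the areas agree (both
#' empty included, as the continuity limit).
#'
#' @inheritParams misclassification_error
#' @export
relative_area_error <- function(gt, pred) {
  .check_masks(gt, pred)
  a <- sum(gt); b <- sum(pred)
  m <- max(a, b)
  if (m == 0L) return(0)
  abs(a - b) / m
}

#' Weighted F-measure with precision and recall
#'
#' `P = |F_GT n F_T| / |F_T|`, `R = |F_GT n F_T| / |F_GT|`,
#' `F = (1 + alpha) P R / (alpha P + R)`. A segmentation that matches the
#' ground truth scores 1 for any `alpha`. With an empty predicted foreground
#' precision is undefined and `F` is defined as 0 (flagged via
#' `precision = NA`).
#'
#' @inheritParams misclassification_error
#' @param alpha harmonic weight, default 0.5.
#' @return list with `precision`, `recall`, `F`.
#' @export
f_measure <- function(gt, pred, alpha = 0.5) {
  .check_masks(gt, pred)
  inter <- sum(gt & pred)
  nt <- sum(pred); ngt <- sum(gt)
  if (nt == 0L) {
    return(list(precision = NA_real_, recall = if (ngt > 0L) 0 else NA_real_, F = 0))
  }
  P <- inter / nt
  R <- if (ngt > 0L) inter / ngt else NA_real_
  F <- if (is.na(R) || (alpha * P + R) == 0) 0 else (1 + alpha) * P * R / (alpha * P + R)
  list(precision = P, recall = R, F = F)
}

#' Uniformity measure of a segmentation (ground-truth free)
#'
#' `UM = 1 - 2 (s1 + s2) / (N M (I_max - I_min)^2)` where `s_i` is the sum of
#' squared deviations of region `i`'s intensities from the region mean and
#' `I_max`, `I_min` are the global intensity extremes. Bounded above by 1;
#' equal to 1 iff both regions are internally constant. A constant image
#' (`I_max = I_min`) scores 1 by convention. `literal_variance = TRUE` uses
#' the per-region mean squared deviation instead of the sum (an alternative
#' reading of the definition; it double-normalizes and is not the default).
#'
#' @inheritParams as_gray_image
#' @param pred logical mask defining the two regions.
#' @param literal_variance use region variance instead of the deviation sum.
#' @export
uniformity <- function(img, pred, L = 255L, literal_variance = FALSE) {
  img <- as_gray_image(img, L)
  if (!is.logical(pred) || !identical(dim(pred), dim(img))) {
    stop("mask must be a logical matrix with the image's shape")
  }
  rng <- range(img)
  if (rng[1] == rng[2]) return(1)
  ssd <- function(v) {
    if (length(v) == 0L) return(0)
    s <- sum((v - mean(v))^2)
    if (literal_variance) s / length(v) else s
  }
  1 - 2 * (ssd(img[pred]) + ssd(img[!pred])) / (length(img) * (rng[2] - rng[1])^2)
}

#' Full metrics report for one segmentation
#'
#' Bundles ME, Jaccard similarity (percent), RAE, precision/recall/F and
#' (when the source image is supplied) the uniformity measure into a one-row
#' data frame, the shape used for batch evaluation tables.
#'
#' @inheritParams misclassification_error
#' @param img optional source gray image for the uniformity measure.
#' @param alpha F-measure weight.
#' @param L maximum gray level.
#' @export
metrics_report <- function(gt, pred, img = NULL, alpha = 0.5, L = 255L) {
  me <- misclassification_error(gt, pred)
  fm <- f_measure(gt, pred, alpha)
  data.frame(
    ME = me$ME,
    misclassified = me$misclassified,
    JS = jaccard_similarity(gt, pred),
    RAE = relative_area_error(gt, pred),
    precision = fm$precision,
    recall = fm$recall,
    F_alpha = fm$F,
    alpha = alpha,
    UM = if (is.null(img)) NA_real_ else uniformity(img, pred, L)
  )
}
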