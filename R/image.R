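#' Validate a grayscale image matrix
#'
#' Images are plain integer matrices with values in `[0, L]`. `L` defaults to
#' 255 (8-bit) but is carried as an argument everywhere so deeper images are
#' admissible.
#'
#' @param img numeric matrix of integer gray levels.
#' @param L maximum representable gray level.
#' @return the validated matrix (invisibly usable), values coerced to integer
#'   storage.
#' @export
as_gray_image <- function(img, L = 255L) {
  if (!is.matrix(img)) stop("image must be a matrix of gray levels")
  if (nrow(img) < 1L || ncol(img) < 1L) stop("image must have at least one pixel")
  if (anyNA(img)) stop("image contains missing values")
  v <- as.vector(img)
  if (any(v != floor(v))) stop("gray levels must be integers")
  if (any(v < 0) || any(v > L)) {
    stop(sprintf("gray levels outside [0, %d]", as.integer(L)))
  }
  storage.mode(img) <- "integer"
  img
}

#' Gray-level histogram of an image
#'
#' Tallies pixel counts per gray level `0..L` and normalizes to probabilities.
#' The histogram is the sole statistic all threshold criteria consume.
#'
#' @inheritParams as_gray_image
#' @return object of class `"gl_histogram"`: list with `counts` and `probs`
#'   (length `L + 1`, level `v` at index `v + 1`), `total_pixels` and `L`.
#' @examples
#' img <- matrix(c(0L, 0L, 255L, 255L), 2, 2)
#' h <- gray_histogram(img)
#' h$probs[c(1, 256)]  # 0.5 0.5
#' @export
gray_histogram <- function(img, L = 255L) {
  img <- as_gray_image(img, L)
  counts <- tabulate(as.vector(img) + 1L, nbins = L + 1L)
  total <- length(img)
  structure(
    list(counts = counts, probs = counts / total,
         total_pixels = total, L = as.integer(L)),
    class = "gl_histogram"
  )
}

#' @export
print.gl_histogram <- function(x, ...) {
  occ <- which(x$counts > 0L) - 1L
  cat(sprintf("gray-level histogram: %d pixels, L = %d, %d occupied levels (%d..%d)\n",
              x$total_pixels, x$L, length(occ), min(occ), max(occ)))
  invisible(x)
}

#' Split a histogram into background/foreground class distributions
#'
#' For threshold `t`, class A (background) holds levels `0..t` with total mass
#' `P_A`, class B (foreground) holds levels `t+1..L` with mass `P_B`; each
#' class distribution is renormalized by its mass.
#'
#' @param h a `gl_histogram`.
#' @param t integer threshold, `0 <= t < L`.
#' @return list with `t`, `P_A`, `P_B`, `dist_A` (levels `0..t`) and `dist_B`
#'   (levels `t+1..L`).
#' @export
split_classes <- function(h, t) {
  stopifnot(inherits(h, "gl_histogram"))
  t <- as.integer(t)
  if (t < 0L || t >= h$L) stop("threshold t must satisfy 0 <= t < L")
  P_A <- sum(h$probs[seq_len(t + 1L)])
  P_B <- sum(h$probs[(t + 2L):(h$L + 1L)])
  if (P_A <= 0 || P_B <= 0) {
    stop(structure(
      class = c("entroseg_degenerate_split", "error", "condition"),
      list(message = sprintf("degenerate split at t = %d (one class is empty)", t),
           call = sys.call(-1))
    ))
  }
  list(t = t,
       P_A = P_A, P_B = P_B,
       dist_A = h$probs[seq_len(t + 1L)] / P_A,
       dist_B = h$probs[(t + 2L):(h$L + 1L)] / P_B)
}

#' Binarize an image at a threshold
#'
#' Pixels with value `<= t` are background, pixels strictly above `t` are
#' foreground (the bright-object convention); `invert = TRUE` swaps the
#' labels for dark-object images.
#'
#' @inheritParams as_gray_image
#' @param t integer threshold in `[0, L]`.
#' @param invert logical, swap foreground/background.
#' @return logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(img, t, L = 255L, invert = FALSE) {
  img <- as_gray_image(img, L)
  t <- as.integer(t)
  if (t < 0L || t > L) stop("threshold t must be in [0, L]")
  mask <- img > t
  if (invert) mask <- !mask
  mask
}

#' Convert an RGB array to a grayscale image
#'
#' BT.601 luma combination `0.299 R + 0.587 G + 0.114 B`, rounded half-up and
#' clamped to `[0, L]`.
#'
#' @param rgb numeric array `nrow x ncol x 3` with channel values in `[0, L]`.
#' @param L maximum gray level.
#' @return integer gray-level matrix.
#' @export
to_grayscale <- function(rgb, L = 255L) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L) {
    stop("expected a 3-channel array (rows x cols x 3)")
  }
  y <- 0.299 * rgb[, , 1, drop = TRUE] + 0.587 * rgb[, , 2, drop = TRUE] +
    0.114 * rgb[, , 3, drop = TRUE]
  g <- matrix(floor(y + 0.5), dim(rgb)[1], dim(rgb)[2])  # round half-up
  g[g < 0] <- 0
  g[g > L] <- L
  storage.mode(g) <- "integer"
  g
}
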