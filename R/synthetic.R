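#' Specification of a synthetic bimodal test image
#'
#' Defaults are the package's standard study conditions: a 128 x 128 image,
#' background intensities N(60, 15), foreground N(190, 15), a centered
#' rectangular object covering a quarter of the image, no extra noise,
#' seed 42.
#'
#' @param shape integer c(rows, cols).
#' @param bg_mean,bg_sd background intensity mean and standard deviation.
#' @param fg_mean,fg_sd foreground intensity mean and standard deviation.
#' @param geometry `"rectangle"`, `"disk"` or `"half_plane"` foreground shape.
#' @param area_fraction foreground area as a fraction of the image, in (0, 1).
#' @param noise_sigma extra Gaussian noise on the `[0, 1]` intensity scale.
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @param L maximum gray level.
#' @return list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(shape = c(128L, 128L), bg_mean = 60, bg_sd = 15,
                         fg_mean = 190, fg_sd = 15,
                         geometry = c("rectangle", "disk", "half_plane"),
                         area_fraction = 0.25, noise_sigma = 0,
                         seed = 42L, L = 255L) {
  geometry <- match.arg(geometry)
  stopifnot(length(shape) == 2L, all(shape >= 1L),
            bg_mean >= 0, bg_mean <= L, fg_mean >= 0, fg_mean <= L,
            bg_sd >= 0, fg_sd >= 0,
            area_fraction > 0, area_fraction < 1, noise_sigma >= 0)
  structure(
    list(shape = as.integer(shape), bg_mean = bg_mean, bg_sd = bg_sd,
         fg_mean = fg_mean, fg_sd = fg_sd, geometry = geometry,
         area_fraction = area_fraction, noise_sigma = noise_sigma,
         seed = as.integer(seed), L = as.integer(L)),
    class = "fixture_spec"
  )
}

#' @keywords internal
.fixture_mask <- function(shape, geometry, area_fraction) {
  n <- shape[1]; m <- shape[2]
  mask <- matrix(FALSE, n, m)
  if (geometry == "half_plane") {
    k <- max(1L, round(m * area_fraction))
    mask[, (m - k + 1L):m] <- TRUE
  } else if (geometry == "rectangle") {
    side <- sqrt(area_fraction)
    hn <- max(1L, round(n * side)); hm <- max(1L, round(m * side))
    r0 <- floor((n - hn) / 2) + 1L; c0 <- floor((m - hm) / 2) + 1L
    mask[r0:(r0 + hn - 1L), c0:(c0 + hm - 1L)] <- TRUE
  } else { # disk
    rad <- sqrt(area_fraction * n * m / pi)
    cy <- (n + 1) / 2; cx <- (m + 1) / 2
    yy <- matrix(seq_len(n), n, m)
    xx <- matrix(seq_len(m), n, m, byrow = TRUE)
    mask <- (yy - cy)^2 + (xx - cx)^2 <= rad^2
  }
  mask
}

#' Two constant regions with exact ground truth
#'
#' A left/right split at the stated column fraction: background value `v0`,
#' foreground (right block) value `v1 > v0`. Every sensible criterion must
#' threshold in `[v0, v1 - 1]` and recover the mask exactly; the histogram
#' has exactly two spikes.
#'
#' @param shape integer c(rows, cols).
#' @param v0,v1 background and foreground gray levels, `v0 < v1`.
#' @param fg_fraction fraction of columns assigned to the foreground block.
#' @param L maximum gray level.
#' @return list with `image` (integer matrix) and `mask` (logical matrix,
#'   `TRUE` = foreground).
#' @export
make_two_region_constant <- function(shape = c(4L, 4L), v0 = 50L, v1 = 200L,
                                     fg_fraction = 0.5, L = 255L) {
  if (v0 >= v1) stop("v0 must be strictly less than v1")
  if (v0 < 0 || v1 > L) stop("region values must lie in [0, L]")
  mask <- .fixture_mask(as.integer(shape), "half_plane", fg_fraction)
  img <- matrix(as.integer(v0), shape[1], shape[2])
  img[mask] <- as.integer(v1)
  list(image = img, mask = mask)
}

#' Seedable bimodal image with exact ground truth
#'
#' Draws each pixel from its region's normal law, rounds and clamps to
#' `[0, L]`, and optionally adds Gaussian noise on the unit intensity scale
#' (with a sub-seed derived from the spec's). Identical spec implies
#' identical output.
#'
#' @param spec a [fixture_spec()].
#' @return list with `image`, `mask`, and the `spec` used.
#' @export
make_bimodal <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  mask <- .fixture_mask(spec$shape, spec$geometry, spec$area_fraction)
  n <- prod(spec$shape)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  v <- numeric(n)
  fg <- as.vector(mask)
  v[!fg] <- stats::rnorm(sum(!fg), spec$bg_mean, spec$bg_sd)
  v[fg] <- stats::rnorm(sum(fg), spec$fg_mean, spec$fg_sd)
  img <- matrix(pmin(pmax(round(v), 0), spec$L), spec$shape[1], spec$shape[2])
  storage.mode(img) <- "integer"
  if (spec$noise_sigma > 0) {
    img <- add_gaussian_noise(img, spec$noise_sigma, seed = spec$seed + 1L,
                              L = spec$L)
  }
  list(image = img, mask = mask, spec = spec)
}

#' Add Gaussian noise to an image on the unit intensity scale
#'
#' Intensities are rescaled to `[0, 1]`, perturbed by `N(0, sigma)`, rescaled
#' back, rounded and clamped. `sigma = 0` returns the input bit-identically;
#' identical seeds give identical output.
#'
#' @inheritParams as_gray_image
#' @param sigma noise standard deviation on the `[0, 1]` scale.
#' @param seed integer seed for the noise draw.
#' @export
add_gaussian_noise <- function(img, sigma, seed = 1L, L = 255L) {
  img <- as_gray_image(img, L)
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(img)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  u <- img / L + stats::rnorm(length(img), 0, sigma)
  out <- matrix(pmin(pmax(round(u * L), 0), L), nrow(img), ncol(img))
  storage.mode(out) <- "integer"
  out
}
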