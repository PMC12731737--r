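#' Build the 4-connected pixel graph with normalized Gaussian affinities
#'
#' Vertices are pixels, edges link 4-adjacent pixels, and each edge carries
#' the weight `exp(-beta (I_i - I_j)^2)` on intensities rescaled to `[0, 1]`,
#' normalized so all edge weights sum to 1. The rescaling gives `beta` an
#' image-size- and bit-depth-independent meaning; the default `beta = 10`
#' makes a full-range intensity step cost `e^{-10}` relative to a flat edge.
#'
#' @inheritParams as_gray_image
#' @param beta positive affinity decay rate.
#' @return list of class `"pixel_graph"`: integer edge endpoints `ei`, `ej`
#'   (column-major pixel indices), normalized `weights`, per-vertex `degrees`,
#'   `beta`, and the image `dim`.
#' @export
pixel_graph <- function(img, beta = 10, L = 255L) {
  img <- as_gray_image(img, L)
  if (length(img) < 2L) stop("graph needs at least two pixels (one edge)")
  if (beta <= 0) stop("beta must be positive")
  n <- nrow(img); m <- ncol(img)
  idx <- matrix(seq_len(n * m), n, m)
  # vertical edges (within columns) and horizontal edges (within rows)
  ei <- c(if (n > 1L) as.vector(idx[-n, , drop = FALSE]),
          if (m > 1L) as.vector(idx[, -m, drop = FALSE]))
  ej <- c(if (n > 1L) as.vector(idx[-1, , drop = FALSE]),
          if (m > 1L) as.vector(idx[, -1, drop = FALSE]))
  u <- as.vector(img) / L
  w <- exp(-beta * (u[ei] - u[ej])^2)
  w <- w / sum(w)
  acc <- rowsum(c(w, w), group = c(ei, ej))
  degrees <- numeric(n * m)
  degrees[as.integer(rownames(acc))] <- acc[, 1]
  structure(
    list(ei = ei, ej = ej, weights = w, degrees = degrees,
         beta = beta, dim = dim(img)),
    class = "pixel_graph"
  )
}

#' Cut, volumes and isoperimetric ratio of a threshold partition
#'
#' `S_t` is the set of pixels with value `<= t` (the background class). The
#' cut is the summed weight of edges straddling the partition, the volume of
#' a side is the sum of its vertex degrees, and the isoperimetric ratio is
#' `cut / min(vol_S, vol_S_complement)`.
#'
#' @param g a [pixel_graph()].
#' @inheritParams binarize
#' @return list with `t`, `cut`, `vol_S`, `vol_S_complement`, `ratio` and
#'   `valid` (`FALSE` with `ratio = NA` when one side is empty).
#' @export
partition_stats <- function(g, img, t, L = 255L) {
  stopifnot(inherits(g, "pixel_graph"))
  img <- as_gray_image(img, L)
  if (!identical(dim(img), g$dim)) stop("image shape does not match graph")
  inS <- as.vector(img) <= t
  if (!any(inS) || all(inS)) {
    return(list(t = as.integer(t), cut = NA_real_, vol_S = NA_real_,
                vol_S_complement = NA_real_, ratio = NA_real_, valid = FALSE))
  }
  cut <- sum(g$weights[inS[g$ei] != inS[g$ej]])
  vol_S <- sum(g$degrees[inS])
  vol_Sc <- sum(g$degrees[!inS])
  list(t = as.integer(t), cut = cut, vol_S = vol_S, vol_S_complement = vol_Sc,
       ratio = cut / min(vol_S, vol_Sc), valid = TRUE)
}

#' Check the entropy-substituted isoperimetric bound over all thresholds
#'
#' Replacing the side volumes by the class entropies turns the isoperimetric
#' constant into `min_t cut(S_t) / min(S(A), S_r(B))`; since the edge weights
#' are normalized, `cut <= 1` and the ratio is bounded by
#' `1 / min(S(A), S_r(B))` at every `t`. Minimizing that bound over `t` is
#' the same as maximizing `min(S(A), S_r(B))` — the max-min criterion. The
#' report verifies the bound at every valid threshold and returns both the
#' bound-maximizing threshold and the minimum-ratio threshold.
#'
#' @inheritParams partition_stats
#' @inheritParams masi_entropy
#' @return list with a per-threshold data frame `table` (columns `t`, `cut`,
#'   `min_entropy`, `ratio`, `bound`, `bound_holds`, `valid`), the argmax
#'   threshold `t_maxmin` of `min(S(A), S_r(B))`, and `t_min_ratio`.
#' @export
check_maxmin_bound <- function(g, img, r, L = 255L, near_one_tol = 1e-6) {
  stopifnot(inherits(g, "pixel_graph"))
  img <- as_gray_image(img, L)
  h <- gray_histogram(img, L)
  tab <- .class_table(h)
  S_rB <- if (abs(r - 1) < near_one_tol) tab$S_B else .masi_of_shannon(tab$S_B, r)
  mins <- pmin(tab$S_A, S_rB)
  ts <- tab$t
  cuts <- rep(NA_real_, length(ts))
  for (k in seq_along(ts)) {
    ps <- partition_stats(g, img, ts[k], L)
    if (ps$valid) cuts[k] <- ps$cut
  }
  candidate <- tab$nondegenerate & !is.na(mins) & !is.na(cuts)
  valid <- candidate & mins > 0  # the ratio and its bound need min > 0
  ratio <- ifelse(valid, cuts / mins, NA_real_)
  bound <- ifelse(valid, 1 / mins, NA_real_)
  holds <- ifelse(valid, ratio <= bound, NA)
  out <- data.frame(t = ts, cut = cuts, min_entropy = mins, ratio = ratio,
                    bound = bound, bound_holds = holds, valid = valid)
  if (!any(candidate)) .no_valid_threshold("no valid threshold partition for this r")
  t_maxmin <- ts[candidate][which.max(mins[candidate])]
  t_min_ratio <- if (any(valid)) ts[valid][which.min(ratio[valid])] else NA_integer_
  list(table = out, t_maxmin = as.integer(t_maxmin),
       t_min_ratio = as.integer(t_min_ratio), r = r, beta = g$beta)
}
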