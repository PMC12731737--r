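#' @keywords internal
.check_probs <- function(p, tol = 1e-9) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > tol) stop("probabilities must sum to 1")
  invisible(p)
}

#' Shannon entropy of a probability distribution
#'
#' `S = -sum(p_i * log(p_i))` in nats, with the `0 * log(0) = 0` convention.
#'
#' @param p non-negative numeric vector summing to 1 (within 1e-9).
#' @return entropy in nats (always finite and >= 0).
#' @examples
#' shannon_entropy(c(0.5, 0.5))  # log(2)
#' @export
shannon_entropy <- function(p) {
  .check_probs(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Tsallis entropy
#'
#' `S_q = (sum(p_i^q) - 1) / (1 - q)`; recovers Shannon entropy as `q -> 1`.
#' Values of `q` within `near_one_tol` of 1 are routed to [shannon_entropy()]
#' to avoid the `1/(1-q)` cancellation. Zero-probability levels are dropped
#' before exponentiation so `q <= 0` is safe.
#'
#' @inheritParams shannon_entropy
#' @param q real entropic parameter.
#' @param near_one_tol route to the Shannon limit when `|q - 1|` is below this.
#' @export
tsallis_entropy <- function(p, q, near_one_tol = 1e-6) {
  .check_probs(p)
  if (abs(q - 1) < near_one_tol) return(shannon_entropy(p))
  p <- p[p > 0]
  (sum(p^q) - 1) / (1 - q)
}

#' Masi entropy
#'
#' `S_r = log(1 + (1 - r) * S) / (1 - r)` where `S` is the Shannon entropy of
#' `p`. Defined only while the log argument `1 + (1 - r) * S` is positive; for
#' `r > 1` and high-entropy distributions the argument can turn negative, in
#' which case `NA_real_` is returned rather than an error so that threshold
#' search can silently skip invalid candidates. `r` near 1 routes to the
#' Shannon limit.
#'
#' @inheritParams tsallis_entropy
#' @param r real entropic parameter, `r > 0`, `r != 1`.
#' @return entropy in nats, or `NA_real_` when undefined at this `r`.
#' @export
masi_entropy <- function(p, r, near_one_tol = 1e-6) {
  .check_probs(p)
  if (r <= 0) stop("Masi parameter r must be positive")
  if (abs(r - 1) < near_one_tol) return(shannon_entropy(p))
  s <- shannon_entropy(p)
  arg <- 1 + (1 - r) * s
  if (arg <= 0) return(NA_real_)
  log(arg) / (1 - r)
}

#' Kapur objective: summed Shannon entropy of the two classes
#'
#' @param split a class split from [split_classes()].
#' @return `S(A) + S(B)`.
#' @export
combined_shannon <- function(split) {
  shannon_entropy(split$dist_A) + shannon_entropy(split$dist_B)
}

#' Tsallis two-class objective with pseudo-additive coupling
#'
#' `S_q(A) + S_q(B) + (1 - q) S_q(A) S_q(B)`, the information measure between
#' classes whose maximizer is the Tsallis threshold.
#'
#' @inheritParams combined_shannon
#' @inheritParams tsallis_entropy
#' @export
combined_tsallis <- function(split, q, near_one_tol = 1e-6) {
  sa <- tsallis_entropy(split$dist_A, q, near_one_tol)
  sb <- tsallis_entropy(split$dist_B, q, near_one_tol)
  if (abs(q - 1) < near_one_tol) return(sa + sb)
  sa + sb + (1 - q) * sa * sb
}

#' Masi two-class objective
#'
#' `S_r(A) + S_r(B)`; `NA_real_` if either class entropy is undefined at this
#' `r`.
#'
#' @inheritParams combined_shannon
#' @inheritParams masi_entropy
#' @export
combined_masi <- function(split, r, near_one_tol = 1e-6) {
  sa <- masi_entropy(split$dist_A, r, near_one_tol)
  sb <- masi_entropy(split$dist_B, r, near_one_tol)
  if (is.na(sa) || is.na(sb)) return(NA_real_)
  sa + sb
}
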