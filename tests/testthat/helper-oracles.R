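# Shared fixtures and independent brute-force oracles for the threshold
# criteria. The oracles deliberately take the slow route (split_classes +
# scalar entropy calls per candidate t) so they share no code path with the
# vectorized cumulative-sum implementation they check.

# random histogram with every level occupied (unique-argmax regime)
rand_hist <- function(seed, L = 63L) {
  set.seed(seed)
  counts <- stats::rpois(L + 1L, lambda = stats::runif(1, 2, 30)) + 1L
  img <- matrix(rep.int(0:L, counts), nrow = 1L)
  gray_histogram(img, L)
}

rand_probs <- function(seed, n = 8L) {
  set.seed(seed)
  x <- stats::rexp(n)
  x / sum(x)
}

# threshold of a criterion call, NA when the criterion has no valid candidate
# (e.g. Masi-sum at large r on a high-entropy histogram)
safe_t <- function(expr) {
  tryCatch(expr$t_opt, entroseg_no_valid_threshold = function(e) NA_integer_)
}

# brute-force min-tie argmax of an objective over all candidate thresholds
oracle_argmax <- function(h, objective) {
  vals <- rep(NA_real_, h$L)
  for (t in 0:(h$L - 1L)) {
    split <- tryCatch(split_classes(h, t),
                      entroseg_degenerate_split = function(e) NULL)
    if (is.null(split)) next
    vals[t + 1L] <- objective(split)
  }
  ok <- !is.na(vals)
  if (!any(ok)) return(NA_integer_)
  m <- max(vals[ok])
  min(which(ok & vals == m)) - 1L
}

oracle_shannon_obj <- function(split) {
  shannon_entropy(split$dist_A) + shannon_entropy(split$dist_B)
}

oracle_tsallis_obj <- function(q) function(split) {
  sa <- tsallis_entropy(split$dist_A, q)
  sb <- tsallis_entropy(split$dist_B, q)
  sa + sb + (1 - q) * sa * sb
}

oracle_masi_obj <- function(r) function(split) {
  sa <- masi_entropy(split$dist_A, r)
  sb <- masi_entropy(split$dist_B, r)
  if (is.na(sa) || is.na(sb)) NA_real_ else sa + sb
}

oracle_linou_obj <- function(q, form) function(split) {
  if (form == 1L) min(shannon_entropy(split$dist_A), tsallis_entropy(split$dist_B, q))
  else min(tsallis_entropy(split$dist_A, q), shannon_entropy(split$dist_B))
}

oracle_maxmin_masi_obj <- function(r, form) function(split) {
  if (form == 1L) {
    sb <- masi_entropy(split$dist_B, r)
    if (is.na(sb)) NA_real_ else min(shannon_entropy(split$dist_A), sb)
  } else {
    sa <- masi_entropy(split$dist_A, r)
    if (is.na(sa)) NA_real_ else min(sa, shannon_entropy(split$dist_B))
  }
}

# run the installed CLI in a fresh R process; returns exit status
run_cli <- function(args, dir) {
  script <- system.file("cli", "entroseg.R", package = "entroseg")
  withr::with_dir(dir, {
    system2("Rscript", c(shQuote(script), args),
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)),
            stdout = TRUE, stderr = TRUE)
  })
}
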