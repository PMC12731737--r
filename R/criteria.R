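#' Per-threshold class entropies, vectorized over all candidate thresholds
#'
#' For every candidate `t` in `0..L-1` computes the class masses and the
#' Shannon entropy of each normalized class distribution via cumulative sums:
#' `S(A) = -sum_A(p log p)/P_A + log(P_A)` and analogously for B. Degenerate
#' candidates (one class empty) get `NA` entropies.
#'
#' @param h a `gl_histogram`.
#' @return list with vectors `t`, `P_A`, `P_B`, `S_A`, `S_B` (Shannon, nats)
#'   and the cumulative `sum p^q` helper closure `pow_cums`.
#' @keywords internal
.class_table <- function(h) {
  p <- h$probs
  L <- h$L
  plogp <- ifelse(p > 0, p * log(p), 0)
  cP <- cumsum(p)
  cS <- cumsum(plogp)
  k <- seq_len(L)            # candidate t = 0..L-1 -> cumulative index t+1
  P_A <- cP[k]
  P_B <- cP[L + 1L] - cP[k]
  sum_A <- cS[k]
  sum_B <- cS[L + 1L] - cS[k]
  ok <- P_A > 0 & P_B > 0
  S_A <- ifelse(ok, -sum_A / P_A + log(ifelse(ok, P_A, 1)), NA_real_)
  S_B <- ifelse(ok, -sum_B / P_B + log(ifelse(ok, P_B, 1)), NA_real_)
  list(t = 0:(L - 1L), P_A = P_A, P_B = P_B, S_A = S_A, S_B = S_B,
       nondegenerate = ok, p = p, L = L)
}

#' @keywords internal
.class_tsallis <- function(tab, q) {
  pq <- ifelse(tab$p > 0, tab$p^q, 0)
  cQ <- cumsum(pq)
  k <- seq_len(tab$L)
  qa <- cQ[k]
  qb <- cQ[tab$L + 1L] - cQ[k]
  Sq_A <- ifelse(tab$nondegenerate,
                 (qa / ifelse(tab$nondegenerate, tab$P_A, 1)^q - 1) / (1 - q),
                 NA_real_)
  Sq_B <- ifelse(tab$nondegenerate,
                 (qb / ifelse(tab$nondegenerate, tab$P_B, 1)^q - 1) / (1 - q),
                 NA_real_)
  list(S_A = Sq_A, S_B = Sq_B)
}

#' Masi transform of a vector of Shannon entropies; NA where undefined
#' @keywords internal
.masi_of_shannon <- function(s, r) {
  arg <- 1 + (1 - r) * s
  out <- rep(NA_real_, length(s))
  ok <- !is.na(arg) & arg > 0
  out[ok] <- log(arg[ok]) / (1 - r)
  out
}

#' @keywords internal
.no_valid_threshold <- function(msg) {
  stop(structure(
    class = c("entroseg_no_valid_threshold", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Assemble a threshold_result from a per-t objective vector
#' @keywords internal
.make_result <- function(tab, objective, method, param, form = NA_integer_) {
  valid <- tab$nondegenerate & !is.na(objective)
  if (!any(valid)) {
    .no_valid_threshold(sprintf("no valid threshold for method '%s'", method))
  }
  m <- max(objective[valid])
  ties <- tab$t[valid & objective == m]
  structure(
    list(t_opt = min(ties), method = method, param = param, form = form,
         ties = ties,
         trace = data.frame(t = tab$t, objective = objective, valid = valid)),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold_result: method = %s%s%s, t_opt = %d (%d valid candidates)\n",
              x$method,
              if (!is.null(x$param) && !is.na(x$param)) sprintf(", param = %g", x$param) else "",
              if (!is.na(x$form)) sprintf(", form = %d", x$form) else "",
              x$t_opt, sum(x$trace$valid)))
  invisible(x)
}

#' Kapur threshold: maximize summed Shannon class entropy
#'
#' Selects `t` maximizing `S(A) + S(B)` over all non-degenerate candidates;
#' the smallest maximizing `t` is returned on ties.
#'
#' @param h a `gl_histogram` with at least two occupied levels.
#' @return object of class `"threshold_result"`: `t_opt`, `method`, `param`,
#'   `form`, `ties`, and a per-candidate `trace` data frame with columns
#'   `t`, `objective`, `valid`.
#' @export
threshold_shannon <- function(h) {
  tab <- .class_table(h)
  .make_result(tab, tab$S_A + tab$S_B, "shannon", NA_real_)
}

#' Tsallis threshold: maximize the pseudo-additive two-class measure
#'
#' Maximizes `S_q(A) + S_q(B) + (1-q) S_q(A) S_q(B)` over `t`.
#'
#' @inheritParams threshold_shannon
#' @inheritParams tsallis_entropy
#' @export
threshold_tsallis <- function(h, q, near_one_tol = 1e-6) {
  tab <- .class_table(h)
  if (abs(q - 1) < near_one_tol) {
    obj <- tab$S_A + tab$S_B
  } else {
    sq <- .class_tsallis(tab, q)
    obj <- sq$S_A + sq$S_B + (1 - q) * sq$S_A * sq$S_B
  }
  .make_result(tab, obj, "tsallis", q)
}

#' Masi threshold: maximize summed Masi class entropy
#'
#' Maximizes `S_r(A) + S_r(B)`; candidates where either class Masi entropy is
#' undefined at this `r` are excluded from the argmax.
#'
#' @inheritParams threshold_shannon
#' @inheritParams masi_entropy
#' @export
threshold_masi <- function(h, r, near_one_tol = 1e-6) {
  if (r <= 0) stop("Masi parameter r must be positive")
  tab <- .class_table(h)
  if (abs(r - 1) < near_one_tol) {
    obj <- tab$S_A + tab$S_B
  } else {
    obj <- .masi_of_shannon(tab$S_A, r) + .masi_of_shannon(tab$S_B, r)
  }
  .make_result(tab, obj, "masi", r)
}

#' Tsallis/Shannon max-min threshold
#'
#' Form 1 maximizes `min(S(A), S_q(B))` (Shannon on the background, Tsallis on
#' the object); form 2 interleaves the entropies and maximizes
#' `min(S_q(A), S(B))`, for images whose background carries the stronger
#' long-range correlation.
#'
#' @inheritParams threshold_tsallis
#' @param form 1 or 2.
#' @export
threshold_linou <- function(h, q, form = 1L, near_one_tol = 1e-6) {
  form <- match.arg(as.character(form), c("1", "2"))
  tab <- .class_table(h)
  if (abs(q - 1) < near_one_tol) {
    sq <- list(S_A = tab$S_A, S_B = tab$S_B)
  } else {
    sq <- .class_tsallis(tab, q)
  }
  obj <- if (form == "1") pmin(tab$S_A, sq$S_B) else pmin(sq$S_A, tab$S_B)
  .make_result(tab, obj, "linou", q, as.integer(form))
}

#' Masi/Shannon max-min threshold
#'
#' The package's central criterion. Form 1 maximizes `min(S(A), S_r(B))`
#' (Shannon entropy of the background, Masi entropy of the object); form 2
#' maximizes `min(S_r(A), S(B))`. Candidates whose Masi term is undefined at
#' this `r` are excluded.
#'
#' @inheritParams threshold_masi
#' @param form 1 or 2.
#' @export
threshold_maxmin_masi <- function(h, r, form = 1L, near_one_tol = 1e-6) {
  if (r <= 0) stop("Masi parameter r must be positive")
  form <- match.arg(as.character(form), c("1", "2"))
  tab <- .class_table(h)
  if (abs(r - 1) < near_one_tol) {
    sr <- list(S_A = tab$S_A, S_B = tab$S_B)
  } else {
    sr <- list(S_A = .masi_of_shannon(tab$S_A, r),
               S_B = .masi_of_shannon(tab$S_B, r))
  }
  obj <- if (form == "1") pmin(tab$S_A, sr$S_B) else pmin(sr$S_A, tab$S_B)
  .make_result(tab, obj, "maxmin_masi", r, as.integer(form))
}

#' Dispatch a threshold criterion by name
#'
#' @inheritParams threshold_shannon
#' @param method one of `"shannon"`, `"tsallis"`, `"masi"`, `"linou"`,
#'   `"maxmin_masi"`.
#' @param param entropic parameter (`q` or `r`); ignored for `"shannon"`.
#' @param form 1 or 2 for the max-min methods.
#' @export
select_threshold <- function(h, method, param = NULL, form = 1L) {
  method <- match.arg(method, c("shannon", "tsallis", "masi", "linou", "maxmin_masi"))
  if (method != "shannon" && is.null(param)) {
    stop(sprintf("method '%s' requires an entropic parameter", method))
  }
  switch(method,
    shannon     = threshold_shannon(h),
    tsallis     = threshold_tsallis(h, param),
    masi        = threshold_masi(h, param),
    linou       = threshold_linou(h, param, form),
    maxmin_masi = threshold_maxmin_masi(h, param, form)
  )
}

#' Grid search for the entropic parameter against ground truth
#'
#' Runs the chosen criterion at every grid value and keeps the one minimizing
#' the misclassification error of the resulting binarization against the
#' ground-truth mask. Grid values at which the criterion has no valid
#' threshold are skipped; ties go to the smaller parameter. The standard
#' grids are `seq(0.1, 0.9, by = 0.1)` for `q` and `seq(0.7, 1.7, by = 0.1)`
#' for `r`. With `refine = TRUE` one recursive bisection pass re-samples the
#' two coarse cells around the best value at half the spacing (a systematic
#' stand-in for manual oversampling; the simulated-annealing optimizer in
#' [run_algorithm1()] supersedes both).
#'
#' @inheritParams as_gray_image
#' @param gt logical ground-truth mask, same shape as `img`.
#' @param method criterion name, see [select_threshold()].
#' @param grid numeric vector of candidate parameters.
#' @param form 1 or 2 for the max-min methods.
#' @param invert passed to [binarize()].
#' @param refine logical, add one bisection refinement pass.
#' @return list with `best_param`, `best_t`, `best_score`, `grid` and `score`
#'   (ME per grid value, `NA` where skipped), class `"grid_search_result"`.
#' @export
grid_search_param <- function(img, gt, method, grid, form = 1L, L = 255L,
                              invert = FALSE, refine = FALSE) {
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (!identical(dim(gt), dim(img))) stop("ground-truth shape must match image")
  h <- gray_histogram(img, L)
  eval_one <- function(par) {
    res <- tryCatch(select_threshold(h, method, par, form),
                    entroseg_no_valid_threshold = function(e) NULL,
                    entroseg_degenerate_split = function(e) NULL)
    if (is.null(res)) return(c(NA_real_, NA_real_))
    pred <- binarize(img, res$t_opt, L, invert)
    c(misclassification_error(gt, pred)$ME, res$t_opt)
  }
  grid <- sort(grid)
  sc <- vapply(grid, eval_one, numeric(2))
  score <- sc[1, ]
  tvals <- sc[2, ]
  if (all(is.na(score))) .no_valid_threshold("no grid value yields a valid threshold")
  pick <- function(g, s) g[which(s == min(s, na.rm = TRUE))][1L]  # smallest on ties
  best <- pick(grid, score)
  if (refine) {
    step <- if (length(grid) > 1L) min(diff(grid)) else 0.1
    extra <- unique(c(best - step / 2, best + step / 2))
    extra <- extra[extra > 0 & !(extra %in% grid)]
    if (length(extra)) {
      sc2 <- vapply(extra, eval_one, numeric(2))
      grid <- c(grid, extra); score <- c(score, sc2[1, ]); tvals <- c(tvals, sc2[2, ])
      o <- order(grid)
      grid <- grid[o]; score <- score[o]; tvals <- tvals[o]
      best <- pick(grid, score)
    }
  }
  i <- match(best, grid)
  structure(
    list(best_param = best, best_t = as.integer(tvals[i]),
         best_score = score[i], grid = grid, score = score,
         method = method, form = as.integer(form)),
    class = "grid_search_result"
  )
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid_search_result: method = %s, best param = %g (ME = %g, t = %d)\n",
              x$method, x$best_param, x$best_score, x$best_t))
  invisible(x)
}
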