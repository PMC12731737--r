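#' Simulated-annealing configuration
#'
#' All inputs of the annealing threshold optimizer with their standard
#' defaults: initial Masi parameter `r_init = 1.5`, perturbation half-width
#' `d = 0.1`, `T_initial = 100`, `T_min = 1e-3`, geometric cooling factor
#' `cooling = 0.99`, `markov_length = 20` (the inner loop performs
#' `markov_length - 1` candidate evaluations per temperature, the literal
#' `j < markov_length` bound), `max_iter = 100` outer iterations, reference
#' error `E_ref = 0` and reference uniformity `UM_ref = 1`. `fix_par = 0`
#' skips the annealing entirely and thresholds at `r_init`.
#'
#' @param r_init initial guess for the Masi entropic parameter.
#' @param d half-width of the uniform perturbation `r_j = r_hat + U(-d, d)`.
#' @param T_initial,T_min initial and minimum temperature.
#' @param cooling geometric cooling factor in (0, 1).
#' @param markov_length inner-loop bound per temperature level.
#' @param max_iter maximum outer iterations.
#' @param E_ref stop as soon as the misclassification error drops to this.
#' @param UM_ref stop as soon as the uniformity measure reaches this
#'   (ground-truth-free mode).
#' @param fix_par 0 = threshold at `r_init` without optimizing, 1 = optimize.
#' @param seed integer seed for the run's pseudo-random stream.
#' @param variant `"proposed"` (max-min Masi/Shannon objective, with the
#'   form-2 fallback) or `"masi_only"` (Masi-sum objective, the ablation
#'   variant).
#' @param strict_paper if `TRUE`, the acceptance test compares each candidate
#'   to the previous candidate's score (even if that candidate was rejected)
#'   instead of to the currently accepted state.
#' @return list of class `"sa_config"`.
#' @export
sa_config <- function(r_init = 1.5, d = 0.1, T_initial = 100, T_min = 1e-3,
                      cooling = 0.99, markov_length = 20L, max_iter = 100L,
                      E_ref = 0, UM_ref = 1, fix_par = 1L, seed = 1L,
                      variant = c("proposed", "masi_only"),
                      strict_paper = FALSE) {
  variant <- match.arg(variant)
  stopifnot(T_initial > T_min, T_min > 0, cooling > 0, cooling < 1,
            markov_length >= 1, max_iter >= 1, d > 0, r_init > 0,
            fix_par %in% c(0L, 1L))
  structure(
    list(r_init = r_init, d = d, T_initial = T_initial, T_min = T_min,
         cooling = cooling, markov_length = as.integer(markov_length),
         max_iter = as.integer(max_iter), E_ref = E_ref, UM_ref = UM_ref,
         fix_par = as.integer(fix_par), seed = as.integer(seed),
         variant = variant, strict_paper = isTRUE(strict_paper)),
    class = "sa_config"
  )
}

#' Threshold at a given r under the configured objective; NULL if no valid t
#' @keywords internal
.sa_select <- function(h, r, variant, form) {
  tryCatch(
    if (variant == "masi_only") threshold_masi(h, r)
    else threshold_maxmin_masi(h, r, form),
    entroseg_no_valid_threshold = function(e) NULL
  )
}

#' Score a threshold: ME (minimized) with ground truth, UM (maximized) without
#' @keywords internal
.sa_score <- function(img, t, gt, L, invert) {
  pred <- binarize(img, t, L, invert)
  if (!is.null(gt)) misclassification_error(gt, pred)$ME
  else uniformity(img, pred, L)
}

#' One annealing pass over a single objective form
#' @keywords internal
.sa_pass <- function(h, img, cfg, gt, form, L, invert) {
  minimize <- !is.null(gt)
  better <- function(a, b) if (minimize) a < b else a > b
  met_ref <- function(s) if (minimize) s <= cfg$E_ref else s >= cfg$UM_ref

  rows <- list()
  log_eval <- function(iter, r, t, score, accepted, temp) {
    rows[[length(rows) + 1L]] <<- data.frame(
      iteration = iter, r = r, t = if (is.null(t)) NA_integer_ else t,
      score = score, accepted = accepted, temperature = temp, form = form)
  }

  r_hat <- cfg$r_init
  res0 <- .sa_select(h, r_hat, cfg$variant, form)
  if (is.null(res0)) {
    return(list(failed = TRUE, trace = data.frame()))
  }
  score0 <- .sa_score(img, res0$t_opt, gt, L, invert)
  log_eval(0L, r_hat, res0$t_opt, score0, TRUE, cfg$T_initial)
  best <- list(r = r_hat, t = res0$t_opt, score = score0)

  finish <- function(termination) {
    list(failed = FALSE, r_hat = best$r, t_opt = best$t, best_score = best$score,
         termination = termination, trace = do.call(rbind, rows))
  }

  if (cfg$fix_par == 0L) return(finish("fix_par_bypass"))
  if (met_ref(score0)) {
    return(finish(if (minimize) "reached_E_ref" else "reached_UM_ref"))
  }

  temp <- cfg$T_initial
  cur_score <- score0
  prev_candidate <- score0
  i <- 0L
  while (temp > cfg$T_min && i < cfg$max_iter) {
    j <- 1L
    while (j < cfg$markov_length) {
      r_j <- r_hat + stats::runif(1, -cfg$d, cfg$d)
      draws <- 0L
      while (r_j <= 0 && draws < 100L) {
        r_j <- r_hat + stats::runif(1, -cfg$d, cfg$d)
        draws <- draws + 1L
      }
      if (r_j <= 0) { j <- j + 1L; next }
      res_j <- .sa_select(h, r_j, cfg$variant, form)
      if (is.null(res_j)) {
        log_eval(i + 1L, r_j, NULL, NA_real_, FALSE, temp)
        j <- j + 1L
        next
      }
      score_j <- .sa_score(img, res_j$t_opt, gt, L, invert)
      if (better(score_j, best$score)) {
        best <- list(r = r_j, t = res_j$t_opt, score = score_j)
      }
      baseline <- if (cfg$strict_paper) prev_candidate else cur_score
      delta <- score_j - baseline
      accept <-
        if (minimize) delta <= 0 || stats::runif(1) < exp(-delta / temp)
        else          delta >= 0 || stats::runif(1) < exp(delta / temp)
      log_eval(i + 1L, r_j, res_j$t_opt, score_j, accept, temp)
      if (accept) {
        r_hat <- r_j
        cur_score <- score_j
      }
      prev_candidate <- score_j
      if (met_ref(score_j)) {
        return(finish(if (minimize) "reached_E_ref" else "reached_UM_ref"))
      }
      j <- j + 1L
    }
    i <- i + 1L
    temp <- temp * cfg$cooling
  }
  finish(if (temp <= cfg$T_min) "cooled" else "max_iter")
}

#' Annealing search for the Masi entropic parameter (the full algorithm)
#'
#' Computes the histogram once, thresholds at the initial `r` under the
#' max-min Masi/Shannon objective (form 1), and then anneals `r` by uniform
#' perturbation with Metropolis acceptance and geometric cooling. With a
#' ground-truth mask the score is the misclassification error (minimized,
#' early exit at `E_ref`); without one it is the uniformity measure
#' (maximized, early exit at `UM_ref`). If form 1 terminates without meeting
#' the reference criterion, the whole schedule is repeated with the form-2
#' objective and the better of the two passes is returned. The best-so-far
#' `(r, t, score)` over all evaluations is returned, and the full evaluation
#' trace is kept for auditing. Candidate `r` values at which no valid
#' threshold exists are rejected and logged; the run fails only if no valid
#' candidate is ever found under either form.
#'
#' @inheritParams as_gray_image
#' @param cfg an [sa_config()].
#' @param gt optional logical ground-truth mask.
#' @param invert passed to [binarize()].
#' @return list of class `"sa_result"`: `t_opt`, `r_hat`, `best_score`,
#'   `score_type` (`"ME"` or `"UM"`), `termination`, `form_used`, `seed`,
#'   `variant`, and the evaluation `trace`.
#' @export
run_algorithm1 <- function(img, cfg = sa_config(), gt = NULL, L = 255L,
                           invert = FALSE) {
  stopifnot(inherits(cfg, "sa_config"))
  img <- as_gray_image(img, L)
  if (!is.null(gt) && !identical(dim(gt), dim(img))) {
    stop("ground-truth shape must match image")
  }
  h <- gray_histogram(img, L)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  pass1 <- .sa_pass(h, img, cfg, gt, 1L, L, invert)
  done <- !pass1$failed &&
    pass1$termination %in% c("fix_par_bypass", "reached_E_ref", "reached_UM_ref")
  single_form <- cfg$variant == "masi_only"

  if (done || single_form) {
    if (pass1$failed) .no_valid_threshold("no valid threshold at any candidate r")
    chosen <- pass1; form_used <- if (single_form) NA_integer_ else 1L
    trace <- pass1$trace
  } else {
    pass2 <- .sa_pass(h, img, cfg, gt, 2L, L, invert)
    trace <- rbind(pass1$trace, pass2$trace)
    if (pass1$failed && pass2$failed) {
      .no_valid_threshold("no valid threshold at any candidate r under either form")
    }
    minimize <- !is.null(gt)
    pick2 <- pass1$failed ||
      (!pass2$failed &&
         (if (minimize) pass2$best_score < pass1$best_score
          else pass2$best_score > pass1$best_score))
    chosen <- if (pick2) pass2 else pass1
    form_used <- if (pick2) 2L else 1L
  }

  structure(
    list(t_opt = chosen$t_opt, r_hat = chosen$r_hat,
         best_score = chosen$best_score,
         score_type = if (is.null(gt)) "UM" else "ME",
         termination = chosen$termination, form_used = form_used,
         seed = cfg$seed, variant = cfg$variant, trace = trace),
    class = "sa_result"
  )
}

#' Masi-only annealing variant (ablation)
#'
#' Identical annealing shell to [run_algorithm1()] but the inner threshold
#' selection maximizes the plain Masi-sum criterion `S_r(A) + S_r(B)` rather
#' than the max-min objective; there is no alternative form.
#'
#' @inheritParams run_algorithm1
#' @export
run_algorithm_a1 <- function(img, cfg = sa_config(), gt = NULL, L = 255L,
                             invert = FALSE) {
  cfg$variant <- "masi_only"
  run_algorithm1(img, cfg, gt, L, invert)
}

#' @export
print.sa_result <- function(x, ...) {
  cat(sprintf("sa_result (%s): t_opt = %d, r_hat = %.6g, %s = %.6g, %s%s, %d evaluations\n",
              x$variant, x$t_opt, x$r_hat, x$score_type, x$best_score,
              x$termination,
              if (!is.na(x$form_used)) sprintf(", form %d", x$form_used) else "",
              nrow(x$trace)))
  invisible(x)
}
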