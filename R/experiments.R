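#' Sensitivity of the segmentation error to the Masi parameter
#'
#' Perturbs a reference `r_hat` along the sequence `r_k = r_hat + k * delta_r`
#' and, for each `k`, thresholds with the max-min Masi/Shannon criterion at
#' the fixed `r_k` (no annealing) and records the misclassification error and
#' its deviation `|ME(k) - ME(0)|` from the unperturbed run.
#'
#' @inheritParams grid_search_param
#' @param r_hat reference Masi parameter (e.g. the annealing output).
#' @param delta_r perturbation step, default 0.01.
#' @param k_range integer offsets, default `-3:3`.
#' @param form max-min objective form, 1 or 2.
#' @return data frame with columns `k`, `r`, `t`, `ME`, `delta_ME`, `valid`.
#' @export
sensitivity_sweep <- function(img, gt, r_hat, delta_r = 0.01, k_range = -3:3,
                              form = 1L, L = 255L, invert = FALSE) {
  stopifnot(delta_r > 0, 0L %in% k_range)
  h <- gray_histogram(img, L)
  one <- function(k) {
    r_k <- r_hat + k * delta_r
    if (r_k <= 0) return(c(NA_real_, NA_real_))
    res <- tryCatch(threshold_maxmin_masi(h, r_k, form),
                    entroseg_no_valid_threshold = function(e) NULL)
    if (is.null(res)) return(c(NA_real_, NA_real_))
    me <- misclassification_error(gt, binarize(img, res$t_opt, L, invert))$ME
    c(res$t_opt, me)
  }
  k_range <- sort(unique(as.integer(k_range)))
  sc <- vapply(k_range, one, numeric(2))
  me0 <- sc[2, match(0L, k_range)]
  data.frame(k = k_range, r = r_hat + k_range * delta_r,
             t = as.integer(sc[1, ]), ME = sc[2, ],
             delta_ME = abs(sc[2, ] - me0), valid = !is.na(sc[2, ]))
}

#' Chained-restart convergence test of the annealing optimizer
#'
#' Runs the annealing optimizer repeatedly, feeding each run's returned
#' `r_hat` back as the next run's initial guess (each restart uses its own
#' sub-seed so the chains differ). Stops after `n_restarts` runs or as soon
#' as the misclassification error reaches 0.
#'
#' @inheritParams run_algorithm1
#' @param n_restarts maximum number of chained runs.
#' @return data frame with one row per execution: `run`, `seed`, `r_init`,
#'   `r_hat`, `t`, `ME`, `termination`, plus the cumulative `best_ME`.
#' @export
convergence_test <- function(img, gt, cfg = sa_config(), n_restarts = 5L,
                             L = 255L, invert = FALSE) {
  stopifnot(n_restarts >= 1L)
  rows <- vector("list", n_restarts)
  r_cur <- cfg$r_init
  for (i in seq_len(n_restarts)) {
    cfg_i <- cfg
    cfg_i$r_init <- r_cur
    cfg_i$seed <- cfg$seed + i - 1L
    res <- run_algorithm1(img, cfg_i, gt, L, invert)
    rows[[i]] <- data.frame(run = i, seed = cfg_i$seed, r_init = r_cur,
                            r_hat = res$r_hat, t = res$t_opt,
                            ME = res$best_score, termination = res$termination)
    r_cur <- res$r_hat
    if (res$best_score == 0) { rows <- rows[seq_len(i)]; break }
  }
  out <- do.call(rbind, rows)
  out$best_ME <- cummin(out$ME)
  out
}

#' Noise-robustness sweep on a synthetic fixture
#'
#' For each noise level sigma, generates `replicates` corrupted copies of the
#' fixture (distinct sub-seeds), runs the annealing optimizer on each against
#' the exact ground truth, and averages the resulting misclassification
#' errors.
#'
#' @param spec a [fixture_spec()] describing the clean image.
#' @param sigma_list noise standard deviations on the `[0, 1]` scale.
#' @param replicates noisy copies per level.
#' @param cfg an [sa_config()].
#' @return list with `summary` (data frame `sigma`, `mean_ME`) and `runs`
#'   (per-replicate data frame `sigma`, `replicate`, `seed`, `r_hat`, `t`,
#'   `ME`).
#' @export
noise_sweep <- function(spec = fixture_spec(), sigma_list = c(0, 0.05, 0.1),
                        replicates = 3L, cfg = sa_config()) {
  stopifnot(replicates >= 1L, all(sigma_list >= 0))
  fix <- make_bimodal(spec)
  rows <- list()
  for (si in seq_along(sigma_list)) {
    s <- sigma_list[si]
    for (rep in seq_len(replicates)) {
      sub_seed <- spec$seed + 1000L * si + rep
      noisy <- if (s == 0) fix$image else
        add_gaussian_noise(fix$image, s, seed = sub_seed, L = spec$L)
      cfg_i <- cfg
      cfg_i$seed <- sub_seed
      res <- run_algorithm1(noisy, cfg_i, fix$mask, L = spec$L)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = s, replicate = rep, seed = sub_seed,
        r_hat = res$r_hat, t = res$t_opt, ME = res$best_score)
    }
  }
  runs <- do.call(rbind, rows)
  summary <- stats::aggregate(ME ~ sigma, runs, mean)
  names(summary)[2] <- "mean_ME"
  list(summary = summary, runs = runs)
}

#' Repeated-run ablation of the annealing optimizer
#'
#' Executes the optimizer `n_runs` times with distinct seeds (or a supplied
#' seed vector) under either the max-min variant or the Masi-only ablation
#' variant, and reports the returned parameter, threshold, ME and UM per run
#' together with the `r_hat` envelope across runs.
#'
#' @inheritParams run_algorithm1
#' @param n_runs number of executions.
#' @param variant `"proposed"` or `"masi_only"`.
#' @param seeds optional integer vector of length `n_runs`; defaults to
#'   `cfg$seed + 0:(n_runs - 1)`.
#' @return data frame with columns `run`, `seed`, `r_hat`, `t`, `ME`, `UM`,
#'   `termination`; the `r_hat` range is attached as attribute `"r_envelope"`.
#' @export
repeated_run_ablation <- function(img, gt, cfg = sa_config(), n_runs = 20L,
                                  variant = c("proposed", "masi_only"),
                                  seeds = NULL, L = 255L, invert = FALSE) {
  variant <- match.arg(variant)
  if (is.null(seeds)) seeds <- cfg$seed + seq_len(n_runs) - 1L
  stopifnot(length(seeds) == n_runs)
  cfg$variant <- variant
  rows <- lapply(seq_len(n_runs), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seeds[i])
    res <- run_algorithm1(img, cfg_i, gt, L, invert)
    pred <- binarize(img, res$t_opt, L, invert)
    data.frame(run = i, seed = cfg_i$seed, r_hat = res$r_hat, t = res$t_opt,
               ME = misclassification_error(gt, pred)$ME,
               UM = uniformity(img, pred, L),
               termination = res$termination)
  })
  out <- do.call(rbind, rows)
  attr(out, "r_envelope") <- range(out$r_hat)
  out
}
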