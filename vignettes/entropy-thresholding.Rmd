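---
title: "Entropy-based bi-level thresholding: models, criteria and the annealed Masi parameter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based bi-level thresholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroseg)
```

## The problem

Bi-level thresholding segments a grayscale image into background and
foreground by a single gray-level cutoff `t`: pixels at or below `t` are
background (class A), pixels above it are foreground (class B; `invert`
flips the convention for dark objects). All criteria in this package operate
on the gray-level histogram alone. Writing `p_0 .. p_L` for the level
probabilities, a threshold `t` induces class masses `P_A = sum(p_0..p_t)`,
`P_B = 1 - P_A` and renormalized class distributions, and a criterion scores
every candidate `t` by an entropy functional of those two distributions.

Entropy-maximization criteria rest on the intuition that a good threshold
produces two classes that are each internally "as uniform as possible" in
their gray-level usage. The choice of entropy encodes an assumption about
pixel correlation structure: Shannon entropy models short-range correlation,
while the nonextensive Tsallis and Masi families — each with a real entropic
parameter that recovers Shannon in the limit toward 1 — can represent
long-range correlation, which dominates in infrared (IR) and nondestructive
testing (NDT) imagery where objects are smooth, high-contrast thermal or
radiographic blobs.

## Entropies and criteria

For a probability vector `p` the package computes (natural logarithms
throughout; the Masi formula nests an inner and an outer logarithm, so the
base must be fixed once, and nats keep all identities clean):

* Shannon: `S = -sum(p_i log p_i)`, with `0 log 0 := 0`.
* Tsallis with parameter `q`: `S_q = (sum(p_i^q) - 1) / (1 - q)`.
  Zero-probability levels are dropped before exponentiation so `q <= 0` is
  defensive-safe, although practical use stays in `[0.1, 0.9]`.
* Masi with parameter `r > 0`: `S_r = log(1 + (1 - r) S) / (1 - r)`.
  For `r > 1` the logarithm's argument turns non-positive once
  `S >= 1/(r - 1)`; the value is then *undefined*. `masi_entropy()` returns
  `NA` rather than raising, because threshold search must skip invalid
  `(t, r)` candidates silently. Invalidity is monotone in `r` above 1: once
  a distribution is too entropic for some `r`, it is too entropic for every
  larger `r`.

Both parametric families route `|param - 1| < 1e-6` to the Shannon limit
instead of evaluating the `1/(1-r)` form, which would amplify cancellation
error near 1.

Five threshold criteria are built on these:

| function | objective maximized over `t` |
|---|---|
| `threshold_shannon()` | `S(A) + S(B)` |
| `threshold_tsallis(q)` | `S_q(A) + S_q(B) + (1-q) S_q(A) S_q(B)` |
| `threshold_masi(r)` | `S_r(A) + S_r(B)` |
| `threshold_linou(q, form)` | `min(S(A), S_q(B))` or `min(S_q(A), S(B))` |
| `threshold_maxmin_masi(r, form)` | `min(S(A), S_r(B))` or `min(S_r(A), S(B))` |

The max–min criteria trade off background and object information: rather
than maximizing total class entropy, they raise the *weaker* of the two
class entropies, which resists the failure mode where one enormous
low-information class dominates the sum. The Masi/Shannon max–min
(`threshold_maxmin_masi`, form 1) applies Shannon entropy to the background
and Masi entropy to the object; form 2 interleaves them for images whose
*background* carries the stronger long-range correlation (typically visible
as a sharp histogram peak on the background side). The form-selection
protocol mirrored by the CLI's `--form auto` runs form 1 and switches to
form 2 when the misclassification error against ground truth exceeds 0.1.

Implementation notes that matter for exact reproducibility:

* Candidates are `t in 0..L-1` with both classes non-empty. Degenerate and
  Masi-invalid candidates are *excluded* (a validity flag in the exported
  trace), never scored as `-Inf`, so objective landscapes stay honest and
  plottable.
* Ties take the smallest maximizing `t`. Two-spike histograms make the
  objective exactly flat across the inter-mode gap, so a deterministic rule
  is mandatory.
* The per-`t` class entropies are computed from cumulative sums
  (`S(A) = -c_t/P_A + log P_A` with `c_t = sum_{i<=t} p_i log p_i`), which
  is O(L) per criterion evaluation. The test suite checks every criterion
  against a brute-force per-threshold recomputation through
  `split_classes()` — an independent code path.

## Choosing the entropic parameter

`grid_search_param()` implements the classical protocol: score each
parameter on a grid (`q` in `[0.1, 0.9]` step 0.1; `r` in `[0.7, 1.7]` step
0.1) by the misclassification error against ground truth, smallest parameter
on ties, with an optional single bisection refinement pass around the best
coarse cell replacing ad-hoc manual oversampling.

`run_algorithm1()` replaces the grid with simulated annealing over `r`:

1. Threshold at the initial `r` under the max–min Masi/Shannon objective
   (form 1) and binarize.
2. `fix_par = 0` returns immediately (pure fixed-parameter thresholding).
3. With a ground-truth mask the score is the misclassification error ME
   (minimized; early exit at `E_ref`); without one it is the uniformity
   measure UM (maximized; early exit at `UM_ref`).
4. Otherwise anneal: perturb `r_j = r_hat + U(-d, d)` (resampled while
   non-positive, up to 100 draws), threshold, score, and accept by
   Metropolis. The inner loop runs `markov_length - 1` candidates per
   temperature (the literal `j < markov_length` bound); the outer loop cools
   geometrically `T <- T * cooling` while `T > T_min` and fewer than
   `max_iter` iterations have run.
5. If form 1 terminates without meeting the reference score, the entire
   schedule is repeated with the form-2 objective and the better pass wins;
   `form_used` records which.

Defaults (`sa_config()`): `r_init = 1.5`, `d = 0.1`, `T_initial = 100`,
`T_min = 1e-3`, `cooling = 0.99`, `markov_length = 20`, `max_iter = 100`,
`E_ref = 0`, `UM_ref = 1`. Note that at `cooling = 0.99` the temperature
cannot reach `T_min` within 100 iterations, so the schedule normally ends by
the iteration cap with the temperature still high; the returned optimum is
meaningful because the *best-so-far* `(r, t, score)` over all evaluations is
tracked and returned, not the final accepted state. The full evaluation
trace (iteration, candidate `r`, threshold, score, acceptance flag,
temperature, form) is kept on the result for auditing.

Two design points were genuinely open and are settled as follows:

* **Acceptance rule.** For ME minimization a worsening move (`dE > 0`) is
  accepted with probability `exp(-dE/T)` — the standard Metropolis form. (A
  positive exponent would exceed 1 and accept every worsening move, making
  the annealing a pure random walk.) For UM maximization the worsening move
  has `dUM < 0` and is accepted with probability `exp(dUM/T)`.
* **Acceptance baseline.** By default a candidate is compared to the score
  of the *currently accepted* `r_hat` — standard simulated annealing, where
  acceptance depends only on the chain's state. `strict_paper = TRUE`
  switches the baseline to the previous candidate's score even if that
  candidate was rejected, an alternative bookkeeping convention retained for
  auditability; it changes trajectories, not the interface.

`run_algorithm_a1()` is the ablation variant: the identical annealing shell
driving the plain Masi-sum criterion. Its objective requires *both* class
entropies to be Masi-valid, so its practical `r` domain is narrower; on
high-entropy inputs (e.g. heavily noisy synthetics with class entropies
around 4 nats) `r_init` must sit below `1 + 1/S ~ 1.25`, whereas the max–min
objective only needs one class valid and tolerates `r_init = 1.5`.

## Accuracy and quality measures

With ground truth: misclassification error `ME` (disagreeing-pixel
fraction), Jaccard similarity of the foregrounds in percent, relative
foreground area error `RAE`, and the weighted F-measure
`F = (1+a) P R / (a P + R)` with `a = 0.5` by default. Without ground truth:
the uniformity measure

`UM = 1 - 2 (s_1 + s_2) / (N M (I_max - I_min)^2)`,

where `s_i` is the **sum** of squared deviations from region `i`'s mean
intensity. With the sum, the `N*M` denominator normalizes UM into `(-1, 1]`
with equality at 1 iff both regions are internally constant; reading `s_i`
as a variance would double-normalize (the measure would then be ~1 for
almost any segmentation). The literal-variance reading remains available as
`uniformity(..., literal_variance = TRUE)`. Empty-set conventions are the
continuity limits and are documented on each function: Jaccard of two empty
foregrounds is 100, RAE of two empty foregrounds is 0, F with an empty
predicted foreground is 0 with `precision = NA` as the flag.

## Why max–min? The isoperimetric view

Model the image as a 4-connected pixel graph with edge weights
`w_ij = exp(-beta (I_i - I_j)^2)` on unit-rescaled intensities, normalized
to sum to 1 (`pixel_graph()`; rescaling gives `beta` a bit-depth-independent
meaning, default `beta = 10`). A threshold partition `S_t` (pixels `<= t`,
matching the background class) has a cut weight, side volumes, and
isoperimetric ratio `cut / min(vol, vol_complement)`; minimizing that ratio
over partitions is a classical segmentation criterion that prefers
high-contrast boundaries around internally homogeneous regions. Because
homogeneous regions have *low* class entropy, substituting the class
entropies for the volumes links the two views: with normalized weights
`cut <= 1`, so

`cut(S_t) / min(S(A), S_r(B)) <= 1 / min(S(A), S_r(B))`,

and minimizing the right side over `t` is precisely maximizing
`min(S(A), S_r(B))` — the max–min criterion. `check_maxmin_bound()` verifies
the inequality at every valid threshold and reports both the
bound-maximizing and the minimum-ratio thresholds. The entropy-for-volume
substitution is a heuristic argument, not a theorem; the package tests only
the literal inequalities that follow from normalization. The per-threshold
ratio requires `min(S_A, S_rB) > 0`, so thresholds with a zero class entropy
appear in the report as argmax candidates but carry no ratio.

## The synthetic generator

`make_bimodal()` draws each pixel from its region's normal law, rounds and
clamps to `[0, L]`. Defaults — 128 x 128, background `N(60, 15)`, object
`N(190, 15)`, a centered rectangle covering 25 % of the image, seed 42 —
are the package's standard study conditions: mode separation of 130 gray
levels at sd 15 puts the optimal threshold ~4 sigma from either mean, so a
correct criterion should reach ME near 0 while noise keeps the problem
non-trivial. The 25 % area fraction is a typical object/background
proportion for single-object IR scenes; none of the criteria depend on it
structurally. `add_gaussian_noise()` perturbs on the `[0, 1]` intensity
scale (so `sigma = 0.5` means half the full dynamic range), which keeps
noise levels comparable across bit depths.

What the generator emulates: bimodal gray-level populations with exact
ground truth, Gaussian sensor-style corruption, seedable reproducibility
(all generators are pure functions of their spec). What it does not emulate:
spatially correlated texture, illumination gradients, sensor fixed-pattern
noise, or natural-scene clutter. Passing the recovery tests therefore shows
the criteria and the optimizer work where their histogram-separability
assumption holds; it does not certify performance on natural images, where
histograms can be unimodal or heavily skewed.

## Experiment protocols and problem sizes

`sensitivity_sweep()` perturbs a reference `r` by `k * delta_r`
(`k = -3..3`, `delta_r = 0.01`) and reports `|ME(k) - ME(0)|`;
`convergence_test()` chains annealing runs, feeding each returned `r_hat`
back as the next initial guess; `noise_sweep()` averages ME over seeded
noisy replicates per sigma; `repeated_run_ablation()` contrasts the max–min
and Masi-only variants across seeds and reports the `r_hat` envelope. Every
experiment result is regenerable bit-identically from its recorded seeds.

The shipped test suite runs the full default annealing schedule on the
128 x 128 standard fixture (three seeds) and scales everything else down —
random histograms at `L = 63` with all levels occupied (which keeps
brute-force argmax comparisons unique-maximum), 8 x 8 graphs, 32 x 32
fixtures with shortened schedules — sizes chosen so the whole suite
completes in well under a minute while still exercising every code path.

## Known limitations

* Bi-level only; no multilevel extension.
* Criteria consume the histogram only: two images with identical histograms
  threshold identically regardless of spatial layout.
* The Masi validity domain shrinks as class entropy grows; at `r = 1.7`
  most mid-range thresholds of a near-uniform 256-level histogram are
  invalid. The search machinery handles this (invalid candidates are
  skipped, an all-invalid parameter raises a typed condition), but users
  tuning `r` by hand should stay near 1 for entropy-rich images.
* The annealing cost is `O(max_iter * markov_length * max(N, L^2))` per
  form; with defaults that is ~3,800 criterion evaluations and a few
  seconds on a 128 x 128 image in pure R.
* `pixel_graph()` materializes every edge; `isocheck` is intended for small
  audit images, not production segmentation.

## A worked example

```{r example}
fix <- make_bimodal(fixture_spec())
res <- run_algorithm1(fix$image, sa_config(seed = 1), fix$mask)
res
metrics_report(fix$mask, binarize(fix$image, res$t_opt), fix$image)
```
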