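---
title: "Hierarchical logistic regression decoding: model, estimation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical logistic regression decoding: model, estimation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlrdecode)
```

## The model

Let `S_i(t) ∈ {0,1}` indicate whether category `i` is present in the
stimulus at TR `t`, with the categories arranged in a hypernym → hyponym
directed acyclic graph, and let `R_t` be the vector of (preprocessed) voxel
responses at TRs `t+2`, `t+3`, `t+4`. The decoder models, for each category,
the *conditional* probability that it is present given that all of its
hypernyms are present:

`P(S_i = 1 | parents(i) all present, R) = σ(w_i · R + b_i)`.

Marginal probabilities follow from the Bayesian-network factorization over
the ancestor closure `A(i)` (the category and all of its hypernyms):

`θ_i(t) = ∏_{v ∈ A(i)} P*(S_v = 1 | parents(v), R_t)`.

The factorization is exact for trees. For DAG taxonomies (a node with
several hypernyms) we define "hypernyms present" as the conjunction of
*all* parents and take the product over the union of ancestors, each counted
once; this is our generalization of the chain semantics and it preserves the
defining constraint, `θ_child ≤ θ_parent` for every edge, at every TR
(checked to 1e-12 in the test suite, and against exhaustive joint
enumeration on small hierarchies).

Each TR is decoded independently; the model has no temporal coupling across
decoded time points. That is a deliberate non-goal: lagged features
compensate for the hemodynamic response, but scene-to-scene temporal
dependencies are not modeled.

### Assumptions worth stating

- Categories are conditionally independent of everything else given their
  hypernyms. This is false for semantically distant but co-occurring
  categories (*car* and *road*), and the per-edge consistency test below
  exists precisely to find taxonomy edges the data contradict.
- All hyponyms of a category are assumed to elicit similar responses; where
  this fails, the conditional AUC will exceed the overall AUC.
- Voxel noise is approximately Gaussian after detrending and z-scoring,
  which makes the logistic form natural.

## Preprocessing

Each run (scan) is processed separately, never concatenated:

1. **Detrending.** A running median with a 120-s window (the window length
   in TRs is `round(window/TR)` forced odd; 61 TRs at TR = 2 s) is
   subtracted per voxel. Edges are handled by reflection, which avoids the
   bias of shrinking windows at run boundaries. A caveat measured during
   development: a sinusoidal drift whose period (134 s) is close to the
   window length is only mildly attenuated (~1.6× in low-frequency power),
   because the median over ~0.9 of a period tracks little of the
   oscillation; genuinely slow drift (a ramp, or periods ≥ 4× the window)
   is suppressed by two orders of magnitude. The simulator's default drift
   period of 67 TRs therefore survives detrending partially — harmless
   here, since the decoder's performance is unaffected, but worth knowing
   when interpreting the filter.
2. **Standardization.** Per-voxel z-scoring within run; constant voxels map
   to zero with a warning. Whether to z-score per run or per session is an
   open choice; per run was chosen because it also removes slow cross-run
   offset differences, and the KS-test property check confirms white noise
   passes through the detrend + z-score chain distributionally unchanged.
3. **Repeat averaging.** Validation presentations of the same stimulus are
   averaged after preprocessing; i.i.d. noise shrinks as `1/√n` (verified by
   simulation).
4. **Lagged features.** Row `t` of the feature matrix holds the responses at
   `t+2`, `t+3`, `t+4` (delay-major, voxel-minor layout). Rows whose largest
   lag would cross the run end are masked invalid and excluded from fitting
   and evaluation rather than zero-padded — fabricating responses seemed
   worse than losing < 1% of rows at realistic run lengths.

## Voxel selection

An encoding model (the reverse regression: lagged binary labels → voxel
response, same 2/3/4-TR delays) is fit per voxel by ridge regression, with
contiguous-segment cross-validation (50 folds by default; folds are
contiguous to respect temporal autocorrelation). The per-fold score is the
Pearson correlation between predicted and observed held-out responses — the
field-standard encoding metric — and the per-voxel ridge penalty is chosen
on an inner contiguous split of each training fold. The `k` best-scoring
voxels (5000 by default, matching the scale of the original design; tests
use smaller worlds) become the decoder's inputs. Selection is invariant to
voxel ordering, with ties broken by voxel id for reproducibility.

## Conditional model estimation

For category `i`, the estimation rows are the TRs where all parents of `i`
are present (for roots: all TRs), minus the smoothing hold-out (below). If
fewer than 10 conditioned TRs or fewer than 3 positives remain, the category
gets a *degenerate* model: zero weights and a bias equal to the logit of the
Laplace-smoothed rate `(n₊ + 1)/(n + 2)` — the same `+1/+2` smoothing used
for every empirical prior, so probabilities never reach 0 or 1.

**Gradient descent with early stopping** (default). The conditioned rows are
split 90/10 in blocks of 4 TRs (blocks, not single TRs, so that the
early-stopping set is not temporally interleaved with training data).
Full-batch gradient descent on the mean logistic log-loss starts from
`w = 0`, `b = logit(p0)`; the step size is 0.1 on the mean-gradient scale
(equivalently `0.1/n` on the summed gradient), capped at 500 iterations, and
descent stops when the early-stopping loss has not improved for 10
consecutive evaluations (evaluated every iteration), returning the
best-validation iterate. The fit is repeated with 3 disjoint early-stopping
blocks-groups and the three weight vectors and biases are averaged —
averaging in weight space, before the sigmoid, which is the stated
interpretation of averaging "the resulting weights"; averaging probabilities
instead is possible but not the default.

**L2-penalized alternative.** The penalized objective is
`Σ log-loss + λ/2 ‖w‖²` with the intercept unpenalized, optimized by
L-BFGS-B, with `λ` searched over `10^-6 … 10^4`. For each of three
block-wise 90/10 splits the best `λ` by held-out log-loss is recorded; the
median of the three is used to refit on all conditioned rows. On held-out
toy data the two fitters' predictions correlate above 0.95; early stopping
is kept as the default.

**Label-noise-robust variant.** Observed labels may be wrong. The noisy
likelihood `P(ỹ=1|x) = Γ₀₁(1−σ) + Γ₁₁σ` couples the logistic output to a
2×2 row-stochastic flipping matrix `Γ` (row = true label, column = observed
label). Estimation alternates L-BFGS-B steps on `(w, b)` under the current
`Γ` with expected-count (EM) updates of `Γ` from the posterior over true
labels, until `Γ` moves less than 1e-6 or 200 rounds elapse. Off-diagonals
start at 0.1; the weights start at zero or, optionally, warm-start from a
plain fit. On clean data `Γ` converges to the identity; a planted 10% flip
rate is recovered to within ±0.03 (averaged over seeds) at n = 2000.

**Prior smoothing.** To limit overconfidence the raw output is shrunk toward
the conditional prior, `P* = (P + η·p0)/(1 + η)` — the posterior-mean form
of a beta prior centered at `p0`. `η` is chosen per category (the formula
indexes the prior by category; a global `η` would be possible but the
per-category choice is strictly more expressive) by maximizing the Bernoulli
log-likelihood of a held-out contiguous segment: the final 30 TRs of the
estimation set (one minute at TR = 2 s), excluded from every conditional
fit, restricted to the category's conditioning mask. The grid is
`{0} ∪ logspace(-3, 3, 25)`; an empty conditioned hold-out yields `η = 0`
with a warning.

## Evaluation

**ROC/AUC with a block-shuffle null.** The AUC is computed by the
rank-statistic (Mann–Whitney) form with ties counting one half; constant
scores therefore give 0.5. Chance level respects the strong temporal
autocorrelation of natural-movie labels: the label series is shuffled in
blocks of 4 TRs (1000 shuffles), preserving the positive count exactly and
most of the within-block autocorrelation. The null AUC sample is summarized
by a beta distribution constrained symmetric (`α = β`, mean exactly 0.5,
honoring a chance distribution centered at one half) with the shape matched
to the null variance, `α = 1/(8·var) − ½`, clipped below at 1; the fitting
method for this constrained beta is our choice, as only the constraint was
specified. P-values are upper-tail probabilities under the fitted beta, and
Benjamini–Hochberg controls the FDR at q = 0.01 across categories. Only
categories present in at least 3 validation TRs are evaluated.

**Conditional AUC and edge consistency.** The cAUC is the AUC restricted to
TRs where all hypernyms of the category are present, measuring separability
from siblings; it is reported as undefined when the conditioned subset has
fewer than 3 positives or 3 negatives (too little conditional entropy). If a
category's cAUC is significantly *higher* than its overall AUC, the grouping
imposed by the taxonomy is not reflected in the responses. The original
account does not specify the significance procedure for this comparison; we
use a moving-block bootstrap (blocks of 4 TRs, resampled with replacement,
shared draws across edges), recompute `cAUC − AUC` per resample, take
`p = P(Δ ≤ 0)` and apply BH across edges — a defensible, reproducible
stand-in, documented as such.

**Per-timepoint likelihood ratios.** Per TR, the log likelihood (natural
log) of the actual binary label vector under the decoded probabilities,
minus its log likelihood under the constant training priors, with
probabilities clipped to `[1e-6, 1−1e-6]`. Significance comes from
independently permuting each category's decoded time course (10,000 shuffles
by default — a desk-scale default; the procedure it emulates used 100,000)
and flagging TRs with `p < 0.01`, uncorrected.

## The synthetic-data generator

The simulator exists so the full pipeline can be exercised, with known
ground truth, in seconds. Its defaults are the reference study conditions
used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| taxonomy | depth 3, branching 2 (7 nodes) | balanced tree |
| `T_train` / `T_val` | 600 / 270 TRs | estimation / validation lengths |
| `n_repeats` | 10 | validation repeats, averaged |
| `n_voxels` / `n_signal_voxels` | 256 / 64 | total / category-tuned voxels |
| `persistence` | 0.9 | Markov stay probability of leaf labels |
| `gain` / `noise_sd` | 1 / 0.3 | response gain / measurement noise |
| kernel | (0.5, 1.0, 0.5) at lags 2/3/4 | crude HRF stand-in |
| drift | amplitude 0.5, period 67 TRs | slow sinusoid |

Labels are generated at the leaves by independent two-state Markov chains
(mean presence-run length `1/(1−persistence)` TRs, emulating scene
persistence — the reason block shuffling is the right null) and closed
upward by entailment; internal-node-only events are not generated by
default. Signal voxels are tuned round-robin to categories with weights
`~N(1, 0.2)` plus occasional weak secondary tunings; the stimulus at `t`
drives the response at `t+2/3/4` through the fixed kernel. The decoder is
never told the kernel — it must learn per-delay weights, which is the point
of the lagged-feature design. Repeats share signal and drift; only noise is
redrawn.

What the simulator does *not* emulate: hemodynamic nonlinearity and
saturation, spatially correlated and physiological noise, motion, session
effects, the 1705-category scale of real labels, and correlated occurrence
of semantically distant categories. Passing tests on simulated data
therefore demonstrate correctness of the machinery and recoverability under
the stated assumptions, not performance on real recordings.

## Numerical choices and degenerate inputs

- Probabilities are clipped at `1e-12` in log-losses and `1e-6` in LLRs.
- Topological order uses Kahn's algorithm with lexicographic tie-breaking,
  so serialized models and column layouts are reproducible across runs.
- Ties in AUC count one half everywhere (scores and shuffles); single-class
  label vectors raise an error rather than returning a convention.
- A zero-variance null sample falls back to a point null at 0.5 with an
  indicator p-value.
- Degenerate conditional models (insufficient conditioned data) predict
  their Laplace-smoothed prior everywhere and are flagged in `tidy()`.
- Model serialization writes full-precision JSON; a round trip reproduces
  decoded probabilities to 1e-12.
- All stochastic steps (splits, shuffles, bootstraps, simulations) are
  seeded through function arguments; a pipeline run is bit-for-bit
  reproducible from its config and seed.

## Problem sizes in the test suite

The suite runs the reference simulation (600 + 270×10 TRs, 256 voxels) for
the end-to-end checks, 20 seeds of the n = 2000 label-noise recovery, and a
50-replicate zero-gain negative control at a reduced size (300 training TRs,
60 voxels, one averaged validation pass) — sizes chosen so the whole suite
completes in about a minute while keeping every statistical check
well-powered. At zero gain the per-category AUC scatter is wide (the null
beta's α is ~30–90 at these lengths, i.e. a null sd of ~0.06): the
negative-control assertion is therefore about the *center* of that
distribution (within 0.5 ± 0.05) and the false-flag rate (≤ 2% at q = 0.01),
not about individual AUCs.

## Known limitations

- The DAG semantics (conjunction over multiple parents) is a generalization;
  with real WordNet labels, multi-parent categories were not characterized.
- The edge-consistency bootstrap is approximate: block resampling changes
  conditional sample sizes per resample, and edges with rarely-present
  parents lose resamples (dropped when more than half are degenerate).
- Per-category `η` smoothing uses a single trailing minute of estimation
  data; categories whose conditioning mask misses that minute fall back to
  `η = 0`.
- The decoder is linear in (lagged) voxel space; category representations
  requiring nonlinear readout are out of scope.
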