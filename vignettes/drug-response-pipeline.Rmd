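---
title: "Predicting drug response with cascaded feature selection and a gamma GLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug response with cascaded feature selection and a gamma GLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell-line pharmacogenomic panels pair tens of thousands of genomic features
(continuous transcript abundances, continuous copy-number values, binary
mutation indicators) with a strictly positive drug-response label, the IC50,
for a few dozen cell lines per drug. Two things make this setting awkward for
off-the-shelf regression. First, the feature space is three orders of
magnitude wider than the sample count, so model fitting must be preceded by
aggressive, structured feature selection. Second, IC50 is positive and
right-skewed with variance growing with the mean, so a Gaussian error model
is misspecified and a point prediction alone hides how unstable the response
may be; clinicians comparing candidate drugs benefit from a predictive
*distribution*, summarized as a prediction interval.

`drpred` implements a complete pipeline for this setting: a three-layer
feature-selection cascade, a gamma-family GLM head producing point
predictions and plug-in prediction intervals, an alternative feed-forward
network head, cross-validated evaluation (R², RMSE, interval coverage), and
an interval-based rule for recommending among candidate drugs.

## The selection cascade

**Layer 1 — connection-weight screening.** One single-hidden-layer tanh
autoencoder is trained per continuous feature kind (RNA, CNV) to reconstruct
its standardized block. Feature relevance is scored by propagating
normalized absolute connection weights through the hidden layer: with
`P_in[i,k] = |W_in[i,k]| / Σ_i |W_in[i,k]|` and `P_out[k,j]` defined
analogously, the input-to-output contribution matrix is
`Q = P_in · P_out` and the total contribution of input *i* is
`q_i = Σ_j Q_ij / Σ_i Q_ij`. Both `P` matrices are column-stochastic, so
`Σ_i q_i = G` holds exactly — an identity the tests assert to 1e-8.
Features are ranked by `q` and the top `ceiling(0.5·G)` are kept; surviving
features whose pairwise |Pearson r| exceeds 0.8 are grouped into connected
components and only the highest-contribution member of each survives.
Binary mutation features bypass this layer entirely and are merged back
afterwards.

Two conventions deserve comment.

*Absolute weights.* Raw signed weights can cancel in the normalizing
denominator and make a feature's contribution non-monotone in its weight
magnitude; magnitude-based propagation is the standard convention for
connection-weight importance and keeps every contribution non-negative.

*The bottleneck width.* The hidden width defaults to
`min(32, ceiling(G/8))`. This is deliberately much tighter than the usual
"quarter of the inputs" rule: with spare hidden capacity the autoencoder
spends units reconstructing per-feature noise, and the contribution scores
of co-varying feature modules are *diluted* across the hidden units they
share, to the point where isolated noise features can out-rank structured
biology. Empirically (and reproducibly in the test suite), with K near G/4
the top half of the contribution ranking excludes correlated modules, while
with K ≤ G/8 the top half contains them across seeds and epochs. A screen
whose purpose is to retain co-regulated, signal-bearing structure needs a
real bottleneck, so that is the default; both the width and the cut
direction remain configurable.

**Layer 2 — mRMR.** Minimum-redundancy–maximum-relevance greedy selection:
the first feature maximizes relevance `I(Y, X_i)`; each subsequent step adds
the candidate maximizing `I(Y, X_i) − (1/|S|) Σ_{s∈S} I(X_s, X_i)`. The
redundancy term is defined as zero while `S` is empty (the criterion
divides by `|S|`, which is undefined at the first step). Mutual information
is the plug-in estimate on equal-frequency bins — 10 bins by default,
dropping to 5 below 100 samples so expected cell counts stay usable; binary
features keep their two levels. Nats are used throughout; the unit cancels
in the argmax. Each pair's MI is computed once and accumulated in a running
redundancy sum, so a selection of *m* features costs `O(m·p)` MI
evaluations rather than `O(m²·p)`. Ties break to the lowest original
column index, and the default *m* is 500.

**Layer 3 — second-order boosted trees.** A from-scratch gradient-boosted
regression-tree ensemble under squared-error loss (per-sample gradient
`g_i = F(x_i) − y_i`, hessian `h_i = 1`), with the classic second-order
split gain

> gain = ½ [ G_L²/(H_L+λ) + G_R²/(H_R+λ) − (G_L+G_R)²/(H_L+H_R+λ) ] − γ

and optimal leaf weights `−G/(H+λ)`. Splits are found by exact greedy
enumeration over sorted unique values — no histogram approximation — so
every split decision can be (and is) verified against brute-force
enumeration on small instances. Samples with a missing feature value are
tried on both sides of each candidate split and the higher-gain side is
stored as that node's default direction; this is what lets the merged
multi-drug feature matrix, which necessarily contains missing values, flow
through without imputation at this stage. Defaults are 50 rounds, depth 4,
λ = 1, γ = 0, shrinkage 0.3 — ordinary boosted-tree settings at desk scale.
Selection keeps features with positive total split gain, capped at the top
40 by gain. Ties anywhere break to the lowest feature index, then the
lowest threshold, then the left direction.

## The GLM head

The response is modelled as gamma with shape *k* and mean
`μ = g⁻¹(Xβ)`; the log link is the default because it keeps μ positive for
any coefficient vector (the canonical inverse link is available).
Coefficients come from IRLS — `stats::glm.fit`, with a damped step-halving
IRLS taking over on the rare skewed, high-leverage designs where unguarded
steps overflow `exp(η)`; the log-link gamma likelihood is concave in β, so
damping restores convergence rather than changing the answer. The shape is
then estimated by Newton iteration on the profile log-likelihood (using
digamma/trigamma), *not* by moment matching, so that log-likelihoods and
AICs are coherent across the three candidate families: exponential (gamma
with k fixed at 1 — identical β, one fewer parameter), gamma, and inverse
Gaussian (closed-form ML dispersion). `select_family_by_aic()` fits all
candidates and keeps the minimal-AIC fit, which on gamma-generated data is
the gamma family in the large majority of replicates.

Prediction intervals are **plug-in central quantile intervals** of the
fitted predictive distribution: `[Q(α/2; k̂, μ̂/k̂), Q(1−α/2; k̂, μ̂/k̂)]`.
Uncertainty in β̂ and k̂ is deliberately not propagated; this is a
documented contract, adequate when the training set is large relative to
the model and exactly the construction whose coverage the acceptance
simulation verifies (PICP within three binomial standard errors of the
nominal 95% on held-out data from a correctly specified model). Near-
saturated fits — the per-drug regime of ~40 selected features on ~50 cell
lines — underestimate predictive spread, and coverage there should be read
qualitatively.

Because a GLM cannot route missing values the way the trees do, any
feature values still missing at this stage are median-imputed per column,
with the medians stored in the fit and reused at prediction time.

On label transforms: per-drug modelling uses raw positive IC50. The
combined multi-drug path log-transforms labels; since log(IC50) is negative
whenever IC50 < 1, which breaks gamma support, the default there is
`log1p`, which preserves positivity. Raw `log` remains available for the
network head, which has no support constraint.

## The network head

The alternative head is a feed-forward tanh network with dropout (four
hidden layers of 1000/800/500/100 units by default, scaled down in tests),
trained by seeded mini-batch gradient descent with momentum on RMSE loss,
with inputs and target standardized internally. Dropout is inverted and
active only during training; inference is deterministic. This head
produces point predictions only — interval estimation is the GLM head's
contract. It consumes the layer-1 + layer-2 output (two selection layers),
since tree-based selection and tree-friendly missing-value routing buy it
nothing.

## Evaluation and recommendation

`kfold_cv()` draws a seeded near-equal partition (220 samples at k = 10
give folds of exactly 22), refits the configured pipeline per fold, and
computes metrics on the pooled out-of-fold predictions — not the mean of
per-fold metrics, which is noisier at these sample sizes. By default the
selection layers are refit inside every training fold so the test fold
cannot leak into selection; on pure-noise data this keeps pooled R² at or
below chance, a property the suite checks. A `selection = "global"` switch
reproduces the common published workflow (select once on all data, then
cross-validate) with a logged leakage warning.

`variance_homogeneity_test()` compares the spread of two samples by
Levene's test with median centering (robust for skewed IC50-like data;
Bartlett available). To compare two fitted predictive *distributions*,
`predictive_stability_test()` draws seeded Monte-Carlo samples from each
plug-in predictive (gamma predictive variance μ̂²/k̂) and applies Levene to
the draws.

`recommend_drug()` encodes the interval-reading rule: rank candidates by
point prediction ascending (lower predicted IC50 = more potent); if the
leaders' points are comparable — within a 20% relative margin, an
operationalization of "little difference in point prediction" that is
configurable — prefer the shorter interval, since at a fixed level a
shorter interval means less predicted fluctuation in response. A candidate
whose lower *and* upper bounds exceed every competitor's is flagged
aggressive/high-risk. The result is invariant to candidate ordering.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the pipeline
assumes: RNA/CNV features drawn from equicorrelated Gaussian blocks
(default within-block correlation 0.7, block size 5), sparse Bernoulli MUT
bits (rate 0.1), Bernoulli fingerprint bits (rate 0.3), and a gamma
response `y ~ Gamma(k, μ/k)` with `μ = exp(β₀ + Σ β_j x_j)` over a small
informative set placed preferentially at the heads of correlated blocks
(mimicking co-expressed driver modules). Effect magnitudes default to
|β| ∈ [0.3, 1] with random signs — detectable but not trivial at the
sample sizes of per-drug panels (tens of cell lines). All randomness flows
from one integer seed; `inject_missing()` adds seeded missingness
restricted to chosen feature kinds, emulating block-merge artifacts.

What the generator does *not* emulate: real marginal expression
distributions, batch structure, drug chemistry, or measurement error in
IC50 itself. Passing tests on this generator demonstrate that the
algorithms do what they claim under their own assumptions — calibrated
intervals under a correctly specified model, recovery of planted signal —
not that those assumptions hold on any particular public panel.

## Problem sizes and numerical choices

The checked configurations are chosen to finish comfortably on one CPU:
interval calibration at n = 500 train / 500 test; the contribution screen
at 100 × 200; mRMR at 60 × 2000 emitting 500 features; the full per-drug
cascade at 50 × 2000 → ~1000 → 500 → ≤ 40. IRLS runs to a 1e-8 relative
deviance tolerance with a 200-iteration cap (near-saturated fits need
~120–150 damped iterations). Equal-frequency bin edges collapse ties via
`unique()`; constant features have undefined correlations and are kept as
singleton components with a warning; a hidden unit with all-zero incoming
weights contributes zero without renormalization, also with a warning.

## Known limitations

- Plug-in intervals ignore parameter uncertainty; coverage is nominal only
  when n is large relative to the selected feature count.
- The boosted trees implement exact greedy search only — fine at desk
  scale, quadratic-ish on very wide nodes.
- The mutual-information estimator is the histogram plug-in; continuous
  (k-NN) estimators are out of scope.
- The recommendation rule outputs ranked hypotheses with statistics
  attached; it is not clinical decision support.
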