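---
title: "Comparing brain-wide projection fractions between groups: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing brain-wide projection fractions between groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoproj)
```

## The measurement and its nuisances

Each animal contributes one row of projection fractions: per brain region,
the fraction of voxels carrying detected axonal signal from a viral tracer
injected into one cortical source area. Values live in [0, 1] and span
several orders of magnitude across regions. Three nuisances dominate any
group comparison:

* **Injection volume.** More tracer labels more axons. Total signal does
  not grow linearly with volume but as a power law,
  $\sum_j PF_{ij} = A \cdot V_i^{\,n}$, with no additive constant (zero
  injection produces zero fluorescence). Dividing by $V_i$ itself
  over-corrects — it induces a negative correlation between total signal and
  volume — so the pipeline fits $n$ by ordinary least squares on
  $\log \sum PF = n \log V + \log A$ (natural logs; the base cancels in
  $n$) and divides by $V_i^{\,n}$.
* **Injection placement.** Millimetre-scale shifts of the injection
  centroid along the medial–lateral, anterior–posterior and depth axes
  change the projection profile appreciably. The per-region GLM carries
  the three centroid distances (µm, centred to mean zero over the fitted
  animals) as covariates; `injection_distance_correlations()` visualizes
  the dependence directly by correlating every animal's profile against
  the most extremely placed animal.
* **Scale heterogeneity across regions.** A fixed fractional condition
  effect is invisible in a strong region and enormous in a weak one unless
  regions are first made comparable; hence unit-mean normalization of
  every region column before the GLM.

Regions whose mean projection fraction falls below $10^{-3}$ are removed
first: signal that weak is unreliable across animals. The boundary value
itself is retained (removal is for means strictly below threshold). The
stage tags on the cohort container (`raw` → `thresholded` →
`volume_normalized` → `unit_mean`) make the chain order explicit; calling a
step out of order is an error rather than a silent misanalysis.

## The per-region GLM and the bootstrap

For region $j$:

$$PF_{ij} = \beta_j + k_{x,j}\tilde x_i + k_{y,j}\tilde y_i
  + k_{z,j}\tilde z_i + k_{c,j} c_i$$

with $c_i = +1$ for controls and $-1$ for the restricted group. Under the
Gaussian identity-link likelihood implied by this linear equation, maximum
likelihood is ordinary least squares. All regions share one design matrix,
so one QR factorization fits every region simultaneously; the test suite
verifies this equals region-by-region `lm()` to $10^{-12}$. A positive
$k_{c,j}$ means controls project more strongly to region $j$. No per-region
significance is attached — with 28 animals and hundreds of regions,
individual coefficients are noise-dominated. The global summary is the
unweighted mean $\mu_{kc}$.

The bootstrap treats whole animals as the resampling unit (rows with their
metadata; never regions). Each group is resampled with replacement $R$
times preserving its size, and every one of the $R^2$ cross pairings is
reanalysed: covariates re-centred on the resampled animals (the resampled
set *is* the fitted set), a fresh GLM per region, a fresh $\mu_{kc}$.
Testing $\mu_{kc} > 0$, the p value is the fraction of pairings with
$\mu_{kc} < 0$, floored at $1/R^2$ — the smallest claimable value with
this design ($R = 50$ gives 2500 comparisons and a floor of 0.0004).
Numerical choices:

* Exact zeros of $\mu_{kc}$ count against rejection (strict inequality) —
  conservative, and measure-zero with continuous data.
* A resampled design that loses rank (e.g. one animal drawn an entire
  group's worth of times, collapsing a centred covariate) is re-drawn and
  counted; it is never silently skipped.
* Groups are resampled in order of first appearance in the animal table,
  not by condition sign. This makes "swap the labels, flip the tail" an
  exact identity for a fixed seed, which the tests assert bitwise.
* Thresholding and volume normalization are fixed upstream; only the GLMs
  are refit inside resamples. Re-estimating the volume exponent per
  pairing would conflate normalization uncertainty with the condition
  test, and only the GLM step is defined per comparison.

For a female-only (or male-only) reanalysis, `subset_cohort()` restricts
the cohort and the opposite tail can be requested when the observed
$\mu_{kc}$ changes sign.

## Multiscale clustering by Markov stability

Individual regions rarely separate two subtly different groups; summed
signal over coherent groups of regions can. Region–region Pearson
correlations across animals, thresholded at zero and with zero diagonal,
define a weighted similarity graph. Partitions are scored by
continuous-time Markov stability,

$$ r(t, H) \;=\; \sum_{C \in H}\ \sum_{i, j \in C}
   \Big[ \big(\Pi\, e^{-tL}\big)_{ij} - \pi_i \pi_j \Big], $$

with $L = I - D^{-1}W$ the random-walk Laplacian, $\pi = d / \sum d$, and
$\Pi = \mathrm{diag}(\pi)$: the summed autocovariance of a random walk at
lag $t$, which resolves fine communities at small $t$ (all singletons in
the limit) and coarse ones at large $t$. The all-in-one partition scores
exactly zero at every $t$, a useful invariant the tests check numerically.

Design choices, where the method family leaves them open:

* **Exact exponential, not the linearized approximation.** The graphs here
  have a few hundred nodes, so $e^{-tL}$ is computed exactly from one
  eigendecomposition of the symmetrized Laplacian
  $D^{-1/2}(D-W)D^{-1/2}$ — which is reused across the whole time grid,
  since only the eigenvalue exponentials depend on $t$. Exactness beats
  speed at this size.
* **Optimization** is Louvain-style greedy node moving with aggregation,
  restarted from `n_restarts` random node orders (default 20) per time
  point. On a suite of graphs small enough for exhaustive enumeration of
  all partitions (up to 7 nodes, 877 partitions), the optimizer attains
  the global optimum on every graph and time tested.
* **Ties** between equally stable partitions break towards fewer
  clusters, then lexicographically smaller canonical labels — determinism
  over aesthetics.
* **Zero-degree nodes** (regions with no positive correlation surviving
  the threshold) are permanent singletons. Disconnected graphs are
  handled by the same algebra blockwise; the degree-proportional $\pi$
  remains the natural weight.
* Default time grid: 20 points log-spaced on $[10^{-2}, 10^2]$, covering
  the singleton-to-whole-graph sweep for correlation graphs of this size.

`merge_by_partition()` sums features within clusters, conserving each
animal's total signal exactly; at the all-singleton scale it is the
identity, so classification with and without the hierarchy agree there (a
configuration identity the tests exploit).

## Classification and its significance

Leave-one-out: for each animal, the injection-geometry dependence is
re-estimated on the other $N-1$ animals only (condition-free GLM;
covariate contributions subtracted from *all* rows using the training
fold's centring constants) and a logit-boost ensemble is trained on those
$N-1$ residualized rows. This per-fold residualization is deliberate: a
fit on all $N$ animals would leak the held-out animal into the features.
The fit-on-everyone reading remains available (`residualize_once = TRUE`)
for comparison.

The learner is classical LogitBoost: Newton steps on the binomial
deviance, each step fitting a small regression tree to the working
responses $z_i = (y^*_i - p_i)/w_i$ with weights $w_i = p_i(1-p_i)$,
adding half its prediction to the score. Responses are clamped to
$[-4, 4]$ and weights floored at $2\times10^{-8}$, the customary
safeguards. Depth-1 stumps (the default) use an exact vectorized split
search with presorted features; deeper base learners use weighted
recursive partitioning. Training has no internal randomness: ties break
towards the first feature and earliest split, and an exactly zero
ensemble score predicts the majority training class. Defaults
(100 rounds, stumps) favour stability at cohort sizes around $N = 28$.

With a partition hierarchy, the feature scale can be chosen three ways:
`"inner"` (default) picks each fold's scale by nested leave-one-out on its
training animals — unbiased but quadratic in $N$; `"fixed"` uses one given
scale; `"per-scale"` reports every scale's accuracy and takes the best as
the headline, which is optimistic and flagged as such in the report.

Significance of an error count $E$ out of $N$ is the exact binomial tail
$P(X \le E)$, $X \sim \mathrm{Binomial}(N, 1/2)$, summed on the log scale —
no normal approximation. Two caveats are inherited from the procedure
itself and documented rather than hidden: LOO predictions are correlated
across folds, so the binomial reference is mildly anti-conservative (the
measured null rejection rate at $\alpha = 0.05$ runs closer to 0.1 than
0.05 in the calibration tests), and accuracy is reported both as a
fraction and as a nearest-integer percent.

## The synthetic cohort generator

No imaging-derived matrices ship with this package; the generator stands
in for them with the statistical structure the analysis assumes:

$$ PF_{ij} = \mathrm{clip}_{[0,1]}\!\Big( b_j\, V_i^{\,n}\,
   \big(1 + s_{x,j}\tilde x_i + s_{y,j}\tilde y_i + s_{z,j}\tilde z_i
   + k_{c,j} c_i\big)\, e^{\sigma \varepsilon_{ij}} \Big). $$

Effects enter multiplicatively on the baseline with additive structure
inside the parenthesis, and covariates are centred exactly as the GLM
centres them. Consequence: with $\sigma = 0$, unit-mean normalization maps
each column to $1 + s_x\tilde x + s_y\tilde y + s_z\tilde z + k_c c$
(balanced groups), so the downstream GLM is *correctly specified* and
recovers every generative coefficient to machine precision — exact
inversion is a meaningful acceptance test, not a tautology.

Defaults emulate the study conditions this pipeline targets: 14 + 14
animals (14 males, 8 of them controls), 293 regions in 11 macro-categories
mixed in realistic proportion, log-normal baselines (median 0.002, one
decade of log10 spread — so a realistic share of regions falls below the
0.1% threshold), true exponent 0.216, centroid distances
$\mathcal N(826, 140^2)$, $\mathcal N(1771, 262^2)$,
$\mathcal N(636, 60^2)$ µm truncated at zero, and multiplicative log-noise
$\sigma = 0.1$. Quantities the source setting does not pin down were fixed
once as plausible values and documented: injection volumes are log-normal
(sdlog 0.35, arbitrary units — only ratios matter); covariate slope SDs
($4, 2, 8 \times 10^{-4}$ per µm) put each axis's contribution near 5% of
baseline, large enough to need correcting, small enough that the
multiplicative factor stays positive; the heterogeneous condition scheme
touches 25% of regions at magnitude 0.08, signed 80/20 positive — region
effects individually lost in noise but positively biased in the mean. The
projection-fraction *distributional family* is itself a modelling choice
(nothing in the motivating setting states one); log-normal baselines are
assumed and that assumption is not testable from within the package.

Two refusal rules protect the generative truth: configurations whose
systematic factor goes non-positive error out, and so do draws where
clipping at 1 would touch ≥ 1% of entries. Ensemble generation skips
refused seeds deterministically. What the generator does *not* emulate:
spatial voxel structure, registration error beyond the centroid
covariates, correlated per-region noise, and hemispheric asymmetries — so
passing tests validate the statistics, not the imaging pipeline.

## Problem sizes and numerics

Monte-Carlo checks run at sizes chosen to keep the full suite quick while
leaving the estimates informative: bootstrap type-I calibration uses 200
null cohorts at full cohort size with $R = 50$; classifier calibration
uses 100 null cohorts with 25 boosting rounds; exponent recovery uses 50
cohorts; exhaustive-search equivalence uses 20 random graphs of 4–7 nodes
at three Markov times. The noisy-exponent check asserts bias and mean
absolute error (both well under 0.05): the per-seed spread of the OLS
slope is governed by the injection-volume spread and the concentration of
the baseline distribution, and a 50-seed maximum necessarily strays
beyond two standard errors.

All randomness is seeded; package functions restore the caller's RNG
state. One master seed fans out to stage seeds through a fixed derivation
(`derive_seeds`), so a pipeline config plus seed reproduces every number
bit for bit, which the pipeline tests assert on the written JSON reports.

## Known limitations

* The bootstrap tail test is one-sided by design and inherits the usual
  caveat of resampling 14-animal groups: discreteness of the resampling
  distribution is visible at small $R$ (hence the $1/R^2$ floor).
* The binomial significance of LOO accuracy ignores fold correlation
  (see above) — its p values are honest descriptions of the procedure,
  not exact test sizes.
* Markov stability is run on the positive part of the correlation matrix;
  negative correlations are discarded, not modelled as signed edges.
* The region ontology is flat: no parent/child aggregation across the
  anatomical hierarchy is attempted.
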