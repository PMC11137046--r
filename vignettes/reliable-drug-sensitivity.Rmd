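---
title: "Reliable drug-sensitivity prediction and prioritization with sauronCP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliable drug-sensitivity prediction and prioritization with sauronCP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Models that predict how strongly a cancer cell line responds to a drug are
usually judged by their average error on held-out data. In a deployment
setting — choosing a drug for a sample whose true response nobody knows —
an average error says nothing about *this* prediction. sauronCP addresses
that gap in three layers:

1. a forest model (SAURON-RF) that predicts a continuous drug response and
   a sensitivity class *simultaneously*, and exposes a notion of
   uncertainty for both tasks;
2. a split conformal-prediction (CP) layer that converts those
   uncertainties into prediction sets and intervals with a user-specified
   certainty level;
3. a drug-sensitivity measure (CMax viability) that is comparable across
   drugs, so that the per-drug predictions for one cell line can be
   combined into a ranked list of recommendable drugs.

# The model

## Simultaneous regression and classification forests

Let $X \in \mathbb{R}^{N \times P}$ be the feature matrix (gene-expression
style), $y \in \mathbb{R}^N$ the continuous response and $d$ a discrete
response obtained by thresholding the continuous one (binary:
resistant = 0 / sensitive = 1; ternary: sensitive = 1, ambiguous = 2,
resistant = 3). Drug-response data are heavily class-imbalanced, so each
sample receives a weight $w_i^\*$:

* **simple**: 1 for the modal (relative-majority) class,
  $N_{\text{mode}} / N_{c}$ for every other class $c$;
* **linear** / **quadratic**: proportional to the distance
  $|y_i - t|^g$ ($g = 1, 2$) from the discretization threshold(s),
  normalized within each class so that every class carries total weight
  $1/k$; interior classes of a ternary scheme average the distances to
  their two bounding thresholds. A sample sitting exactly on its only
  threshold gets weight 0 (with a warning) — it carries no information
  about which side it belongs to.

The weights are propagated through the entire training procedure: trees
are grown on bootstrap samples of size $N$, and each split is chosen among
`mtry` candidate features to maximize the improvement in *weighted* MSE.
We deliberately use the weights inside the split criterion and not only in
the leaf averages — weights that only reweight leaf means cannot change
which regions of feature space the trees resolve. Each leaf $\mu$ stores

* normalized weights $w_n^\mu = w_n^\* / \sum_{i \in \delta(\mu)} w_i^\*$
  over its bootstrap members $\delta(\mu)$, giving the tree prediction
  $\hat f_b(x) = \sum_{n \in \delta(\mu)} w_n^\mu y_n$, and
* the mode of its members' class labels, which turns every tree into a
  classifier.

The forest classifies by plurality vote over the per-tree leaf modes, and
the vote proportions serve as class probabilities. The regression
aggregate is class-aware: if the predicted class is the training modal
class, every tree contributes $1/B$; otherwise only the trees that agree
with the forest vote contribute, with equal weight. This suppresses trees
that route a predicted-minority sample into majority-dominated leaves.

## Quantile regression

Collapsing the per-tree leaf weights onto original sample ids (bootstrap
duplicates are summed) and averaging with the class-aware tree weights
yields one weight $w_i(x)$ per training sample with $\sum_i w_i(x) = 1$
and $\sum_i w_i(x)\, y_i$ exactly equal to the tree-weighted prediction —
the package asserts this identity to $10^{-8}$ and the three
normalizations (leaf, tree, forest-wide) to $10^{-10}$ in its test suite.
The weighted empirical distribution
$\hat F(y \mid x) = \sum_i w_i(x)\, \mathbf{1}(y_i \le y)$ estimates the
conditional response distribution, and its inversion
$\hat Q_\alpha(x) = \min\{y : \hat F(y \mid x) \ge \alpha\}$ gives
conditional quantiles, in the spirit of quantile regression forests but
with the class-aware weighting. With uniform weights and single-class
labels the construction reduces exactly to a standard quantile regression
forest, which is how it is cross-checked against a brute-force
reimplementation.

## Split conformal prediction

Split CP needs three disjoint sets: training, calibration, test (default
70/15/15). A nonconformity score $s$ (high = uncertain) is evaluated on
the calibration set and the threshold $\hat q$ is its
$\lceil (N_{\text{cal}}+1)(1-\alpha) \rceil$-th smallest value — the
finite-sample inflation of the $(1-\alpha)$-quantile that makes the
marginal coverage guarantee
$1-\alpha \le P(\text{truth} \in \mathcal{C}(x)) \le
1-\alpha + \tfrac{1}{N_{\text{cal}}+1}$ hold under exchangeability,
regardless of how good the model is. Implemented scores:

* **True-class (TC)**: $1 - P(d \mid x)$; the prediction set contains all
  classes with score $\le \hat q$. Sets may be empty (we report them as
  such; efficiency only counts singletons).
* **Summation**: cumulative vote mass down the descending-sorted class
  list up to the true class; sets always contain at least the top class.
  On binary tasks its sets are frequently both classes, which trivially
  covers but is uninformative — visible in the efficiency diagnostic.
* **Mondrian**: TC calibrated separately per true class, giving the
  per-class coverage guarantee that matters under heavy imbalance.
* **Quantile**: for regression, the signed distance
  $\max(\hat f_{\alpha/2}(x) - y,\; y - \hat f_{1-\alpha/2}(x))$ to the
  base quantile interval; the test-time interval is widened (or narrowed)
  by $\hat q$, i.e. conformalized quantile regression.

Numerical conventions, chosen once and documented: when
$\lceil (N_{\text{cal}}+1)(1-\alpha) \rceil$ exceeds $N_{\text{cal}}$ the
threshold is $+\infty$ (full sets, unbounded intervals); when it is
$\le 0$, $-\infty$. Comparisons of scores against $\hat q$ use an absolute
slack of $10^{-9}$ because both sides are computed from floating-point
vote fractions; descending sorts break vote ties by ascending class code;
a calibration class that is absent gets the $+\infty$ sentinel with a
warning. Intervals narrowed past zero width are flagged `degenerate`
rather than silently swapped.

## CMax viability

IC50-style measures are comparable across cell lines but not across drugs,
because therapeutic concentration ranges differ by orders of magnitude.
The CMax viability is the fraction of viable cells at the drug's *CMax
concentration* — the peak plasma concentration at the highest clinically
recommended dose — read off the fitted dose-response curve; it lives on
$[0,1]$ for every drug. The curve model is a two-parameter logistic on
log-concentration, $v(c) = 1/(1 + e^{s(\log c - m)})$ with $s \ge 0$,
fitted per drug/cell-line combination by Levenberg–Marquardt least squares
from a small start grid; it is monotone nonincreasing by construction,
evaluations are clipped to $[0,1]$, and a CMax outside the tested
concentration range is extrapolated *and flagged*. Constant-viability
input (an inactive drug) is represented by a flat curve, which the
logistic cannot express.

Discretization pools the CMax viabilities of *all* drugs and runs 1-D
k-medoids (PAM, `cluster::pam`, $k = 2$ or 3). Thresholds are the
midpoints between the boundary points of adjacent clusters (the midpoint
between adjacent *medoids* is available as an option; for well-separated
clusters both could be defended, and the boundary midpoint is the one that
respects the observed gap). The lowest-viability cluster is the sensitive
class, and values exactly on a threshold go to the more sensitive side — a
deterministic tie rule that errs towards follow-up rather than dismissal.
Drugs whose discretized labels are a single class, or have fewer than
`min_per_class` (default 3) samples of a present class in any split part,
are dropped with an audited reason: one-class drugs cannot be learned and
near-empty calibration classes make per-class thresholds meaningless.

## Prioritization

For one test cell line — shared by all per-drug models, so it is unseen by
every one of them — a drug is *effective* when its CP class set is exactly
{sensitive}: the model is then wrong with probability at most $\alpha$.
Effective drugs are ranked ascendingly by the upper limit of their CP
regression interval, a viability that will not be exceeded with high
probability (ties: point prediction, then drug id). Evaluation reports the
precision of the list, whether the truly most efficient drug is in it, the
rank of the predicted first drug in the true viability ordering, whether
that drug is a true positive, and its viability gap to the true best drug.
Cell lines with an empty effective list yield *undefined* (not zero)
measures and are aggregated separately, so medians are not biased
downwards by them.

# Defaults and tunable parameters

| parameter | default | why |
|---|---|---|
| `num_trees` (B) | 100 | regression-forest convention; coverage is guaranteed by CP regardless, B mainly affects efficiency |
| `mtry` | $\lceil P/3 \rceil$ | regression-forest convention |
| `min_node_size` | 5 | regression-forest convention; a node splits only if both children keep ≥ 5 bootstrap members |
| stopping | < 2·`min_node_size` members, zero response spread, or no admissible split | keeps every leaf ≥ `min_node_size` |
| `alpha` | 0.1 | 90% certainty, the level used throughout the evaluation |
| split | 70/15/15 | training/calibration/test convention of the drug-centric analysis |
| `min_per_class` | 3 | smallest count at which a per-class calibration quantile is meaningful |
| weight scheme | simple | the least parameterized imbalance correction |

Tree growth is deterministic given the master seed: the seed derives one
32-bit substream per tree (bootstrap + feature sampling, via per-tree
Mersenne Twister streams in compiled code), so fits and predictions are
bit-reproducible across runs and platforms, and serialization
(`write_sauron()` / `read_sauron()`, a plain-text format with `%.17g`
doubles) round-trips them bit-exactly. Vote ties and leaf-mode ties go to
the lowest class code.

# What the synthetic generators emulate — and what they do not

`simulate_expression_response()` produces standard-normal features with a
sparse linear signal (10 informative features by default), Gaussian
response noise, and labels obtained by thresholding the *noiseless* signal
at quantiles matching the requested class fractions. This mirrors the
structure the method assumes — a continuous response with class structure
and imbalance — and makes the truth (coefficients, signal, thresholds)
available to every downstream test. Labels defined on the noiseless signal
are deliberately not a deterministic function of the noisy response; when
labels must be exactly thresholded responses (as the distance-based weight
schemes require), threshold the response directly and pass `thresholds`.

`simulate_dose_response_panel()` draws a logistic curve per drug/cell-line
pair (log-midpoint uniform over the tested range, slope in $[0.5, 2]$),
nine half-log concentrations from 0.001 to 10 µM with two replicates, and
adds Gaussian viability noise with standard deviation 0.03 — the order of
technical replicate scatter in luminescence viability assays, and a level
at which a per-curve least-squares fit of ~18 points recovers CMax
viabilities to within ±0.05 even in the worst case. A configurable
fraction of drugs (default 10%) gets a CMax below the lowest tested dose
to exercise the extrapolation flag. `simulate_shared_panel()` squashes
per-drug linear signals through a logistic onto the $[0,1]$ viability
scale and gives all drugs one shared 70/15/15 cell-line partition.

None of the generators emulate assay batch effects, plate artifacts,
correlated gene modules, or distribution shift between calibration and
test data. Passing tests therefore demonstrate the *mathematical*
properties — coverage under exchangeability, parameter recovery, ranking
behaviour — not performance on real pharmacogenomic screens; coverage
guarantees in particular are only as good as the exchangeability
assumption.

# Problem sizes used by the checks

The coverage experiments (`cp_coverage_experiment()`, also driven by
`scripts/acceptance.R`) use 50 independent synthetic data sets of
N = 2000, P = 20 with a 70/15/15 split and B = 100 trees; the Mondrian
class-conditional check uses 40 data sets of N = 1000 at a 1:9 class
ratio. These sizes put the calibration sets at 300 (150) samples, large
enough that the theoretical coverage band
$[1-\alpha,\; 1-\alpha + 1/(N_{\text{cal}}+1)]$ is ~0.3 (0.7) percentage
points wide. The band bounds the *expected* coverage; a finite seed
average scatters around it with a standard error of the same order, so the
test-suite assertions allow the band plus two standard errors of the
seed-to-seed mean — a Monte-Carlo tolerance, not a relaxation of the
guarantee. Oracle-equivalence checks (brute-force quantile-regression
forest, weighted-leaf arithmetic, k-medoids enumeration) run on instances
small enough (N ≤ 50, B ≤ 10) for exhaustive recomputation.

# Known limitations

* The class-aware tree weighting assumes at least one tree agrees with
  the forest vote — true by construction of the plurality — but with very
  few trees the minority-vote average can rest on a handful of leaves.
* Conformal intervals from quantile forests can be wide when the forest
  cannot resolve the conditional spread; the coverage guarantee holds
  regardless, the efficiency diagnostics make the width visible.
* The two-parameter logistic fixes asymptotes at 1 and 0; partial
  responders (plateaus above 0) bias the CMax viability near the high end
  of the tested range. The curve model is pluggable by design.
* Exchangeability is assumed between calibration and test data; coverage
  under distribution shift is out of scope.
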