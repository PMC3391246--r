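---
title: "Clearness-based feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clearness-based feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfs)
```

## The problem

Filter feature selection scores each feature of a labeled `n x m` matrix
independently of any classifier and keeps the top-ranked subset. In
transcriptomics, `m` (genes) is typically in the thousands while `n`
(samples) is tens to hundreds, so per-feature statistics that are cheap,
deterministic and robust to garbage features matter more than elaborate
multivariate searches.

This package is built around *clearness*: how separable the classes are
within one feature considered alone.

## CScore

For feature $f_j$ with class centroids $\mathrm{Med}(f_j, t)$ — arithmetic
means of the class's values in that feature — each sample value $x_{ij}$ is
assigned the label of the nearest centroid by one-dimensional absolute
distance:

$$M_1(i,j) = \arg\min_t \; |x_{ij} - \mathrm{Med}(f_j, t)|, \qquad
M_2(i,j) = \mathbf{1}[M_1(i,j) = c_i],$$

$$\mathrm{CScore}(f_j) = \frac{1}{n}\sum_i M_2(i,j) \in [0, 1].$$

Properties the test suite asserts:

* **Affine invariance.** Rescaling a feature rescales centroids and
  distances together, so no standardization is needed or applied.
* **Tie-breaking.** When a value is equidistant from several centroids the
  smallest class label wins. The rule is arbitrary but must be fixed:
  without it a constant feature would have an undefined score, and exact
  oracle tests would be impossible. Under it a constant feature scores the
  class-0 fraction.
* **Degenerate classes.** A singleton class is legal; its centroid is the
  sample itself, which can inflate that feature's score. Documented, not
  blocked.
* **Cost.** One pass for centroids, one per class for assignment, one for
  matching: $O((2+p)\,m\,n)$. The implementation processes features in
  256-column blocks so the working set stays cache-resident on wide
  matrices; the measured wall-time growth per doubling of $m \cdot n$ is
  close to 2 (linear).

CScore is not a perfect clearness oracle. Two geometries fool it:

1. a tight class nested inside the value range of a wide class — wide-class
   samples near the tight cluster are assigned to the wrong centroid even
   though the classes barely overlap;
2. two heavily overlapping classes, where many samples near the midpoint
   land on the wrong side.

## R-value

The partner score replaces centroid distance with neighborhood composition:
sample $i$ is *congested* in feature $j$ if at least $\theta$ of its $k$
nearest other samples (by $|x_{ij} - x_{i'j}|$; distance ties broken by
ascending sample index) carry a different label, and

$$R(f_j) = \frac{\#\{\text{congested samples}\}}{n}, \qquad \text{lower is
clearer}.$$

The binary congestion count with defaults $k = 7$, $\theta = \lceil k/2
\rceil$ (an other-class majority) is this package's normative definition of
the R-value; it is monotone in $\theta$, affine-invariant, and verified
against an exhaustive $O(n^2)$ neighbor oracle. In the nested-class geometry
above it stays near zero while CScore is visibly deflated — the asymmetry
that motivates combining the two schemes.

## Combining rankings

`cbfs_intersection(cs, rs, m, n)` intersects the top-$n$ sets of the two
rankings and returns the first $m$ intersection members by CScore rank. The
intersection size cannot be predicted from $n$, so the result may fall short
of $m$.

`cbfs_exact(cs, rs, m)` repairs that: starting at $n = m$, each round
intersects the two top-$n$ lists and appends unseen members to an extract
list, incrementing $n$ until the list reaches $m$; the first $m$ insertions
are returned. Design choices that the underlying procedure leaves open, fixed
here:

* insertions within a round follow CScore rank (CScore is the primary
  scheme);
* when the final round overshoots, the list is truncated to the first $m$ by
  insertion order rather than re-ranked across rounds;
* "top-$n$ by R-value" means the $n$ lowest (clearest) scores.

By construction the first round of `cbfs_exact` equals
`cbfs_intersection` at $n = m$; the suite checks this on random score pairs,
plus exact agreement with a literal step-by-step transcription of the loop.

## Baselines

**FSDD** scores feature $j$ as $d_b - \beta\,d_w$ with
$d_b = \sum_t p_t (\mu_{jt} - \mu_j)^2$ and
$d_w = \sum_t p_t \sigma^2_{jt}$, where $p_t$ is the class prior (sample
fraction), $\mu_{jt}$ the class centroid, $\mu_j$ the grand mean, and
$\sigma^2_{jt}$ the within-class mean squared deviation (denominator $n_t$,
so singleton classes are defined and contribute zero spread). Default
$\beta = 3$. FSDD is translation-invariant but scales by $c^2$ under feature
rescaling by $c$ — unlike CScore, absolute scale matters. Per-feature scoring
is implemented; subset-level normalization over the selected set is not.

**ReliefF** weights features by their ability to separate neighboring
samples: for each visited sample, the $k$ nearest same-class hits pull the
weight down by their mean per-feature difference and each other class's $k$
nearest misses push it up, weighted by $P(C)/(1 - P(\mathrm{class}(i)))$.
Differences are range-normalized; neighbor search uses the range-normalized
Manhattan distance over all features, ties by ascending index; $k = 7$ by
default, clipped per class when a class is small. Classical Relief visits
random instances, which makes results run-dependent; the default here is a
deterministic full pass visiting every sample once (random sampling remains
available via `iterations` + `seed`). The full pass is verified against a
brute-force hit/miss transcription.

## Evaluation harness

`cv_accuracy()` reports stratified k-fold (default 5) cross-validated
accuracy of KNN ($k = 5$, Euclidean, majority vote, deterministic
smallest-label tie-break) or a linear-kernel SVM (`e1071`/LIBSVM defaults,
no internal rescaling) on a given feature subset. Stratification is the
default because small classes are common at these sample sizes;
non-stratified folds are a flag away. Folds are a deterministic function of
the seed.

Selection is deliberately *outside* `cv_accuracy()`: benchmark protocols in
this field conventionally select once on the full dataset and sweep subset
sizes, which leaks test information into selection and biases accuracy
upward. `cv_accuracy_nested()` provides the leakage-free alternative
(re-selecting inside each training fold) and is the recommended choice when
the accuracy estimate itself is the scientific claim.

`feature_auc()` scores a single feature as a ranking statistic for one class
via the tie-corrected Mann–Whitney AUC, folded to $\max(A, 1-A)$ because a
feature's direction is arbitrary. It is invariant under strictly monotone
transforms and cross-checked against `pROC`.

## Synthetic data

`make_dataset()` generates the study conditions used throughout the tests:

* `gaussian` — informative features draw class $t$ from
  $N(t\cdot\delta,\,1)$; within-class SD is fixed at 1 because CScore's
  affine invariance makes absolute scale irrelevant, and multi-class means
  sit on a line at spacing $\delta$ (the simplest monotone geometry).
  Noise features are $N(0,1)$ regardless of label.
* `fig4_case1` — the nested-class pathology: class A $\sim N(0, 3)$ wide,
  class B $\sim N(2, 0.1)$ tight inside A's span.
* `fig4_case2` — heavy overlap: $N(0, 1.5)$ versus $N(1, 1.5)$.

Class sizes are as equal as integer division allows; everything is
reproducible under a seed, and the planted informative indices are returned
for recovery tests.

What the generator does *not* emulate: probe-level noise, batch structure,
heavy-tailed or correlated features. Passing the synthetic benchmarks
demonstrates the algorithms' contracts (recovery, monotonicity, the
CScore/R-value asymmetry), not performance on any particular real microarray
study.

## Problem sizes and statistical checks

The simulated benchmarks in tests and in `scripts/acceptance.R` use
100 samples × 500 features (10 informative at $\delta = 2$) over 20 seeds for
recovery and classification comparisons, 200 features per level for the
separation-monotonicity curve, and $n = 500$ over 10 seeds for the
nested-class rank asymmetry — the last because the expected CScore gap
between the pathological feature (≈ 0.815) and a $\delta = 2$ control
(≈ 0.841) is small, so the assertion compares mean ranks across seeds rather
than a single draw. Timing uses feature counts 1000–8000 at $n = 200$ with
the minimum over repeated, garbage-collected runs.

## Known limitations

* All scores are strictly univariate: a feature pair that separates classes
  jointly but not marginally is invisible to every scheme here.
* CScore's value distribution under the null (pure noise) is biased slightly
  above $1/p$ because centroids are fit to the same samples being matched;
  rankings are unaffected, but raw scores should not be read as accuracies.
* `cbfs_intersection` can return fewer features than requested; callers
  needing a fixed-size subset should use `cbfs_exact`.
* The R-value here is a documented neighbor-count definition chosen for its
  contract (congestion-sensitivity, [0,1] range, lower-better orientation),
  not a reproduction of any external implementation.
* FSDD's score scale is unit-dependent; compare FSDD scores only within a
  feature set measured on a common scale.
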