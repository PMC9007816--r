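---
title: "Low-precision mutual information feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-precision mutual information feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowmi)
```

## The problem

Gene-expression (microarray) classification works in an awkward regime:
tens to low hundreds of samples against thousands of gene features, most
of which are irrelevant to the phenotype. Filter feature selection based
on mutual information (MI) is a standard first step, and the popular
filters — MIM, mRMR, JMI — spend essentially all of their time estimating
MI between discretized features and the class label.

On low-power hardware (edge and embedded devices), double-precision
floating point is expensive. The question this package makes measurable
is: *how few bits does the MI arithmetic actually need before feature
rankings, and the classification built on them, degrade?* Everything
needed to answer it is in the package: a fixed-point MI estimator with a
tunable bit budget, the three filters parameterized by that estimator, a
ranking-similarity metric, a cross-validated classification harness, and
a synthetic generator of microarray-like data so the whole experiment is
reproducible offline.

## Estimating mutual information

For discrete variables $X, Y$ the MI is

$$ I(X;Y) = \sum_{x}\sum_{y} p(x,y)\,\ln\frac{p(x,y)}{p(x)\,p(y)}, $$

in nats. The full-precision baseline (`plugin_mi()`) is the plug-in
maximum-likelihood estimator: empirical frequencies $\hat p = c/C$
(counts over the population total) substituted into the sum, evaluated
in ordinary double precision. "64-bit" throughout the package means this
estimator, not a 64-bit fixed-point format.

### The fixed-point estimator

A fixed-point format is specified by `fixed_point_spec(bi, bf)`: `bi`
integer bits, `bf` fractional bits, quantization interval $q = 2^{-bf}$,
and maximum counter value $M = 2^{bi+bf}-1$. A total budget of $b$ bits
is split evenly, $bi = bf = b/2$ (`depth_spec(b)`); the split is a knob
(`bi=`, `bf=`) but the even default is used everywhere.

Two things are quantized:

1. **Counters.** Event occurrences and the population count $C$ are held
   in counters bounded by $M$ (`accumulate_counts()`). Observations are
   streamed in input order; whenever the next increment would push $C$
   past $M$, every joint counter is halved with integer floor division
   and $C$ recomputed as the sum of the halved counters. At 4 total bits
   ($M = 15$) this fires constantly on 100-sample data and is the main
   source of the 4-bit collapse seen below; at 16 bits ($M = 65535$) it
   never fires at microarray sample sizes.
2. **Logarithms.** Log-probabilities come from a lookup table
   (`build_lut()`), $L(i,j) = [\ln(i/j)/q]_R \cdot q$, rounding to the
   nearest grid multiple, so every unclamped entry is within $q/2$ of
   the exact log-ratio. The low-precision estimate (`lowprec_mi()`) is
   $\sum (c_{xy}/C)\,[L(c_{xy},C) - L(c_x,C) - L(c_y,C)]$ over nonzero
   joint cells.

From the $q/2$ entry bound, each cell's bracket is off by at most
$3q/2$, so $|{\hat I}_{low} - \hat I| \le (3q/2)\sum_{cells} c_{xy}/C =
3q/2$ absent saturation — the estimator converges to the plug-in value
geometrically in `bf`. The test suite asserts the per-cell bound on 200
random contingency tables at 4 bit depths and checks the maximum
deviation strictly shrinks as `bf` grows.

### Numerical choices

Decisions the underlying description leaves open, fixed here once:

* **Probability weights stay in full precision.** Only the three log
  terms are quantized; the weights $c_{xy}/C$ and the accumulating sum
  are double precision. This isolates the quantization under study to
  the logarithm (the quantity the lookup table stores).
* **Rounding at exact halves** is half-away-from-zero (the behaviour of
  C++ `std::round`), which is directionally symmetric; the R-side table
  builder reproduces it bit for bit.
* **Clamping.** Log magnitudes outside the representable range saturate
  at $\pm(2^{bi}-q)$, as fixed-point hardware does.
* **Zero counts.** A zero joint cell contributes exactly 0 (the
  $0\ln 0 = 0$ convention); looking up a log against an empty population
  ($j=0$) is a domain error; a zero occurrence count maps to a `-Inf`
  sentinel that the estimators never consume.
* **Halving** recomputes $C$ as the sum of the halved joint counters
  rather than halving $C$ independently, which keeps the
  marginal-consistency invariant checkable (marginals are always derived
  from the joint table).
* **LUT storage.** The full $(M-1)^2$ table is materialized only when
  $M \le 4096$; beyond that (16 total bits would already need a
  $\sim 4\times10^9$-entry table) entries are evaluated on demand by the
  identical formula, so the two modes are bit-identical (tested).
* Low-precision estimates may be slightly negative (bounded below by
  $-(3q/2)\times$ the number of nonzero cells); the plug-in estimate is
  never negative.

## Discretization

Continuous expression values are discretized per feature with an
equal-width strategy into `n_bins = 10` bins (`equal_width_discretize()`):
$\lfloor (v - \min)/\text{width} \rfloor$, the maximum closed into the
top bin, constant features to bin 0. Inside cross-validation the edges
are fitted on the training fold only and applied to the test fold with
out-of-range values clipped to the extreme bins
(`apply_discretization()`), so no information leaks from test samples
into selection. Discretization is invariant to positive affine rescaling
of a feature.

## The three filters

`lowmi_rank(x, y, method, k, bits)` is the fitting function; every MI
term inside it is evaluated at the requested depth.

* **MIM** ranks features by $I(X_f;Y)$ — relevance only;
  $m$ MI evaluations.
* **mRMR** greedily maximizes $I(X_f;Y) - \frac{1}{|S|}\sum_{s\in S}
  I(X_f;X_s)$ — the canonical *mean*-redundancy difference form.
* **JMI** greedily maximizes $\sum_{s\in S} I((X_f,X_s);Y)$ with the
  candidate/selected pair encoded over the product alphabet — sensitive
  to complementarity (features useless alone, decisive together).

The first selection of mRMR and JMI is the maximum-relevance feature
(their criteria are undefined for an empty $S$). All ties break by
ascending feature index, making rankings bit-reproducible. Pairwise
terms are computed once per step for all remaining candidates and
accumulated, so mRMR/JMI cost at most $k \cdot m$ MI evaluations — under
the conventional $O(k^2 m)$ bound, which the tests verify by counting
evaluations (`$n_evals`). The chosen precision applies to *every* MI
evaluation in a run, feature–class and feature–feature alike.

## Evaluation machinery

* `tpr_top_k()` — the top-$k$ true positive rate between a candidate
  ranking and the full-precision reference: the fraction of the
  reference's top-$k$ set present in the candidate's top-$k$. Set-based,
  symmetric, blind to order within the top-$k$.
* `compare_rankings()` — the method × depth × $k$ TPR grid
  ($k \in \{5,10,20,30,40,50\}$, depths 4/8/16/32 vs the baseline).
* `run_cv()` — repeated stratified cross-validation (default 3×5-fold)
  with selection *inside* the loop: per fold, discretize the training
  fold, rank at the requested depth, then classify the original
  undiscretized data restricted to the top-$k$ features. Accuracy is
  reported in percent at fold granularity. Stratification deals samples
  of each class round-robin across folds after a seeded shuffle; each
  repetition derives its shuffle seed deterministically from the master
  seed.
* `reference_knn()` — Euclidean 3-NN majority vote, included so the
  harness needs no external learner. Tied votes go to the class with
  the nearest voting neighbour, then the smallest label (a pure
  smallest-label rule would misclassify a point sitting on a class
  centroid whenever fewer training samples than neighbours are
  available). Any classifier can be plugged in as a function
  `f(train, labels, test)`.

## The synthetic generator

`synth_microarray()` emulates the microarray regime — small $n$, large
$m$, few informative genes — with analytically controlled ground truth:

* *relevant* features: unit-variance Gaussians, class-shifted by
  `effect_size` within-class standard deviations (default 1.5, a
  strongly but not perfectly separable signal at $n = 100$);
* *redundant* features: a relevant feature plus Gaussian noise
  (sd 0.5), detectably correlated copies that mRMR should postpone;
* *complementary* features: XOR pairs — two binary latents embedded in
  continuous noise whose parity tracks the class parity, individually
  uninformative, jointly predictive — the construction that separates
  JMI from MIM/mRMR;
* everything else: standard Gaussian noise. Planted roles are scattered
  over random column positions so index-based tie-breaking cannot
  accidentally favour them.

`standard_fixture()` pins the canonical dataset used across the tests:
$n=100$, $m=2000$, 20 relevant + 10 redundant + 4 complementary,
effect 1.5, seed 42. What passing tests on this generator do **not**
show: robustness to real microarray artifacts — probe effects, batch
effects, heavy-tailed marginals, class imbalance, dataset shift. The
generator is a controlled instrument for the bit-depth question, not a
microarray simulator.

## What the experiments show

On the standard fixture the depth grid reproduces the qualitative
pattern reported for real microarray panels: 4-bit rankings are near
chance (TPR $\approx 0$–0.1 against the baseline), 8 bits recovers most
of the ranking (TPR $\approx 0.8$–0.95), and 16/32 bits are essentially
indistinguishable from full precision (TPR $\ge 0.99$ here), with 4 bits
the worst depth at every method and every $k$. Classification through
the 3×5-fold harness with the reference 3-NN at $k=20$ is equal at 16
bits and at full precision on this fixture. The acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch at a
caller-supplied seed.

Problem sizes used throughout (chosen to make the full suite complete
comfortably on a single CPU): the $100\times2000$ fixture for grid and
CV experiments, $m=10$ datasets for brute-force oracle equivalence,
exhaustive lookup-table sweeps up to 12 total bits with strided sweeps
beyond.

## Limitations

* The fixed-point format models *values*; the final weighted MI sum is
  accumulated in double precision (accumulator precision is out of
  scope).
* When MI values across features sit closer together than the
  quantization interval, low-precision rankings devolve to index order;
  more bits are needed as $n$ and $m$ grow.
* Discretization is equal-width only (no MDL/entropy binning), matching
  the experimental protocol the package is built to study.
* SVM/boosting classifiers are supported only through the pluggable
  classifier contract; the in-repo reference classifier is 3-NN.
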