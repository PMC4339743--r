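---
title: "Ensemble regression for microbiome variable selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble regression for microbiome variable selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbensemble)
```

# The problem

Microbiome studies routinely regress a continuous outcome (for instance a
log colony-forming-unit count) on hundreds of taxon abundances measured in
a few dozen samples. In this $p \gg n$ regime a single penalized fit is
unstable: small perturbations of the data change which taxa are selected.
Ensemble approaches stabilize selection by averaging over many models —
either over perturbed datasets (subsamples, bootstrap resamples) or over
the model space itself (spike-and-slab posteriors explored by MCMC) — and
summarize each variable by an *inclusion probability*: the fraction of
ensemble members in which its coefficient is nonzero.

`mbensemble` implements eleven approaches behind one front-end,
`ensemble_fit()`, together with everything needed to evaluate them on
synthetic microbiome-like data: a count-table generator, design-matrix
construction, SNR-calibrated response simulation, gap-based variable
selection, ROC/AUC, F-score and rank-correlation metrics, and a
reproducible grid harness.

# From counts to a design matrix

Let $t_{ij}$ be the sequence count of taxon $j$ in sample $i$ after
removing all-zero rows and columns (`filter_zero()`). Smoothed relative
abundances use a pseudocount of 1,
$$\phi_{ij} = \frac{t_{ij} + 1}{\sum_{j=1}^{p}(t_{ij} + 1)},$$
so each row sums to exactly one and every entry is strictly positive. The
denominator sums the smoothed counts — the only reading under which
$\sum_j \phi_{ij} = 1$ holds, which is the property the compositional
argument relies on. The design matrix is
$x_{ij} = \log \phi_{ij}$ (natural log; the base only rescales
coefficients) with the *reference taxon* — the taxon with the largest
total count, ties broken toward the smaller column index — removed to
eliminate the sum-to-one redundancy. A no-log variant
(`build_design(log_transform = FALSE)`) is available.

# Simulated regression problems

Responses follow the linear model $y = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2 I)$. A scenario fixes:

* **sparsity** — the fraction of influential variables (grid
  $\{2\%, 3\%, 4\%\}$), mapped to a count by round-half-up; the drawn set
  is split into a positive and a negative half, with the extra variable on
  the positive half when the count is odd;
* **coefficient scheme** — $\beta = \pm 1$, or magnitudes drawn from
  $U(0.5, 1)$ with the sign of the half;
* **SNR** — $\mathrm{SNR} = \lVert X\beta \rVert_2 / (\sqrt{n}\,\sigma)$;
  the generator inverts this exactly,
  $\sigma = \lVert X\beta\rVert_2 / (\sqrt{n}\,\mathrm{SNR})$, so the
  nominal SNR is reproduced to machine precision (a property the test
  suite asserts at $10^{-12}$). The evaluation grid uses 0.25 (high
  noise), 4.60 (medium; the bacterial-data scale) and 16.00 (low noise).

Per-replicate seeds are derived from the scenario seed by a fixed affine
counter scheme, so any replicate is reproducible in isolation. Whether
the influential set is redrawn per replicate is configurable; the default
redraws it, which makes replicates exchangeable rather than conditioned
on one arbitrary truth.

# The modeling approaches

**ENC** is the baseline: elastic net
$$\hat\beta = \arg\min_\beta \; \mathrm{RSS} +
  \lambda\left(\alpha\lVert\beta\rVert_1 +
  \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right),$$
with $(\alpha, \lambda)$ chosen by leave-one-out cross-validation over
$\alpha \in \{0.1, \ldots, 1\}$ and a 100-point geometric $\lambda$ grid
from $\lambda_{\max}$ (the smallest penalty with an all-zero solution)
down to $\lambda_{\max} r$, $r = 10^{-3}$ for $n > p$ and $10^{-2}$
otherwise. The solver is cyclic coordinate descent with warm starts and
covariance updating; predictors are standardized internally and an
unpenalized intercept is always included. Every reported fit carries a
subgradient stationarity certificate (`$kkt`), checked at $10^{-6}$ in the
tests. Cross-validation ties prefer the larger penalty (the sparser
model), then the earlier $\alpha$.

The **frequentist ensembles** build $B = 100$ member datasets — subsamples
of size $\lfloor n/2 \rfloor$ (suffix `S`) or bootstrap resamples of size
$n$ (suffix `R`) — and fit the elastic net on each member over a shared
$\lambda$ grid computed once on the full data (sharing one grid is what
makes the per-$\lambda$ inclusion probabilities comparable across
members). With $S_\lambda(b)$ the support of member $b$ at penalty
$\lambda$:

* `LS`/`LR`: $P(j \in S(\lambda_{ENC})) = \frac1B \sum_b
  1_{j \in S_{\lambda_{ENC}}(b)}$ at the single cross-validated penalty;
* `SS`/`SR`: the average of $P(j \in S(\lambda_i))$ over the 100 grid
  points;
* `SSW`/`SRW`: the weighted average with the weight of $\lambda_i$
  proportional to the total number of selection events at $\lambda_i$
  (weights sum to one);
* `PS`/`PR`: stability selection with false-positive control. The grid is
  restricted to the largest region from the null-model end over which the
  average selected-set size $q$ keeps the per-family error bound
  $q^2 / ((2\pi_{thr} - 1) p) \le \mathrm{PFER}$; the stable set contains
  the variables whose inclusion probability reaches $\pi_{thr}$ anywhere
  in that region. Defaults $\pi_{thr} = 0.75$, $\mathrm{PFER} = 1$, both
  configurable — this is the standard formalization of "minimize the
  expected number of false positives".

The $\alpha$ used inside the ensembles is fixed at the full-data
cross-validated optimum (re-tuning per member is possible by passing
`alpha` explicitly per call); members whose subsampled response is
constant are redrawn with a seeded retry.

The **Bayesian ensembles** (`BMA`, `BMAC`) place a spike-and-slab prior on
the coefficients: independent Bernoulli spikes $\gamma_i \sim
\mathrm{Bern}(\pi_i)$ with $\pi_i = k/p$ ($k$ = expected model size), a
Zellner-type slab
$\beta_\gamma \mid \sigma^2 \sim N(0, \sigma^2 \Omega_\gamma^{-1})$ with
the smoothed information matrix
$$\Omega = \frac{g}{n}\left(w\, X^\top X + (1 - w)\,
  \mathrm{diag}(X^\top X)\right), \quad g = 1, \; w = 0.5,$$
which stays positive definite under exact collinearity, and
$1/\sigma^2 \sim \Gamma(\nu/2,\, ss/2)$ with $\nu = 0.01$ and
$ss = 0.5\,s_y^2$. The $\Gamma(\nu/2, ss/2)$ notation is read as
shape/rate; the moment pair sometimes quoted for this prior
(mean $\nu/ss$, variance $\nu/ss^2$) matches neither the shape/rate nor
the shape/scale convention, so the sampler follows the shape/rate reading
of the reference spike-and-slab software and we note the discrepancy here
rather than resolving it silently.

Conjugacy gives the marginal likelihood of any indicator $\gamma$ in
closed form (`log_marginal()`), which the Gibbs sampler
(`gibbs_sample()`) uses for systematic-scan single-site updates of
$\gamma$ with $\beta$ and $\sigma^2$ integrated out, followed by one exact
joint draw of $(\sigma^2, \beta_\gamma)$ per sweep. An intercept is
handled by centering $X$ and $y$ (a flat-prior intercept); `center =
FALSE` is available so enumeration oracles can work on raw data. Chains
default to 10,000 sweeps with 1,000 discarded, and inclusion
probabilities are the fraction of retained draws with a nonzero
coefficient. Chains start from the cross-validated elastic-net support
truncated to the $\lceil k \rceil$ largest coefficients — a deterministic
start that shortens burn-in and cannot change the stationary law.
`BMAC` chooses $k$ by five-fold cross-validation over
$\{1, 2, 4, 8, 16, 32\}$ (capped below $p$) using shortened fold chains
(2,000/200 by default) and the posterior-mean linear predictor, breaking
ties toward the smaller $k$.

The sampler caches the Cholesky factors of the active set and scores
add/remove proposals by $O(q^2)$ rank-one extensions and deletions,
refreshing the cache once per sweep; its correctness is pinned by two
oracles in the test suite — exact enumeration over all $2^8$ models on a
small problem (maximum absolute deviation below 0.02 at 50,000 retained
draws) and brute-force quadrature of the likelihood-times-prior integral
at $p \le 3$ (relative error below $10^{-4}$).

# Variable selection and evaluation

Approaches that emit inclusion probabilities are turned into selectors by
the largest-gap rule (`ld_select()`): sort the probabilities, take the
largest first-order lagged difference, select everything above it. Ties
take the earlier cut (the smaller set); an all-constant vector has no gap
and yields an empty selection with a warning.

ROC curves sweep 22 thresholds. A log-spaced ladder "between 0 and 1.01"
cannot contain 0, so the implemented sequence is $\{0\}$ together with 21
log-spaced values from $1.01 \times 10^{-3}$ to $1.01$ (configurable).
TPR and FPR use the true influential set as ground truth; the AUC is the
trapezoidal area over the achieved points augmented with the $(0,0)$ and
$(1,1)$ corners, since 22 thresholds need not span both extremes. The
F-score is the harmonic mean of precision and recall (0 when nothing true
is selected), and ranking quality is Spearman's correlation between
$|\beta|$ and the inclusion probabilities with average-rank ties —
the product-moment form on ranks is standard Spearman only under that
convention. Methods that only emit a selected set (ENC, PS, PR) are
scored by F-score and TP/FP alone; AUC and rank correlation are recorded
as missing for them.

# The synthetic count generator

No suitable public count table accompanies the motivating application
(the mouse 16S/ITS data are not deposited), so `generate_counts()`
emulates the *structural* properties a practitioner would recognize:
log-normal base abundances across taxa (the `dispersion` parameter is the
log-scale SD), one taxon boosted to `dominance` times the median taxon
(the future reference genus; the heavy tail of the remaining taxa is
winsorized just below it so the reference is unambiguous for every seed),
per-sample multiplicative noise, multinomial sampling at a depth drawn
log-normally around `depth_median`, and a final adjustment of zero cells
toward the target `zero_fraction` in either direction (with a target of
0, every cell ends at $\ge 1$). All-zero rows or columns are repaired by
one seeded count rather than resampling, keeping dimensions
deterministic.

Two presets mirror the dimensions of the motivating datasets:
`"bacterial-like"` ($30 \times 193$ taxa, median depth 3,500 — the design
matrix has $p = 192$) and `"fungal-like"` ($36 \times 48$, median depth
2,000, $p = 47$). Their zero fractions (0.65 and 0.50) and dominance
ratios are fixed realistic choices, since only dimensions and median
depths are documented for the real data; the generator's realism is
therefore structural, not distributional. Passing tests on these tables
shows the methods behave correctly on data with compositional structure,
heavy zero inflation and a dominant genus — it does not certify
performance on any particular real dataset, whose taxon correlation
structure the generator does not model.

# The evaluation harness

`run_grid()` crosses design $\times$ sparsity $\times$ coefficient scheme
$\times$ SNR $\times$ replicates $\times$ methods, computes a metrics
record per cell, and is deterministic from its config seed: every cell
derives its own seed, so results are independent of execution order and
of the worker count, and a checkpoint directory lets an interrupted grid
resume to an identical table. One elastic-net cross-validation is shared
by all methods on a given dataset. `aggregate_metrics()` reports boxplot
statistics (type-7 quartiles, $1.5 \cdot \mathrm{IQR}$ whiskers).
`method_similarity()` compares approaches by $S_{ij} = 1/(1 + D_{ij})$ on
the Euclidean distances between inclusion vectors, clustered with
centroid linkage.

For real compositional data, `dual_reference_fit()` runs the application
procedure: the two most abundant genera serve as alternate references,
the model is fit twice (each fit excluding one reference, optionally with
covariable blocks appended), and each variable's final probability
averages the fits in which it appears — each reference genus appears in
exactly one fit and keeps that fit's value. All columns (taxa,
covariables, treatment indicators) are penalized and standardized
identically; nothing in the procedure distinguishes block types, which is
the simplest defensible default and is flagged here because mixed scaling
conventions are a known judgment call.

# Numerical choices and problem sizes

* Coordinate descent converges on the maximum absolute coefficient change:
  $10^{-10}$ for single certified fits, $10^{-5}$ for path/CV work where
  only supports and prediction errors matter.
* The sampler guards $S = y^\top y - u^\top u \ge 0$ against roundoff and
  rejects proposals whose extended factorization is numerically singular.
* Reference-taxon and cross-validation ties are broken deterministically
  (smaller column index; larger penalty, then earlier $\alpha$; smaller
  $k$).
* The test suite and the acceptance script run scaled-down grids — 10–20
  replicates, 5,000-sweep chains with 1,000-sweep fold chains for the
  cross-validated expected model size — which we chose as the smallest
  sizes at which the qualitative method orderings are stable across
  seeds; the full-size defaults (130 replicates, 10,000 sweeps, 2,000
  fold sweeps) remain the package defaults.

# Known limitations

* The generator does not model taxon-taxon correlation, sequencing error
  or chimeras, and its parameters are not fitted to any real dataset.
* Only continuous responses are supported; generalized (logistic,
  multinomial, survival) variants are out of scope.
* `BMAC` uses the data twice (to tune $k$ and to fit); a hyperprior on
  $\pi$ would be the fully Bayesian alternative and is not implemented.
* The per-family error bound of `PS`/`PR` assumes the exchangeability
  conditions of stability selection; with strongly dependent predictors
  it is conservative rather than exact.
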