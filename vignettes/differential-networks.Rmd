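---
title: "Differential partial-correlation networks: models, tests and design choices"
author: "diffpcor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential partial-correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffpcor)
```

## The problem

Two physiological groups — in the motivating application, individuals with
normal versus impaired fasting glucose, profiled on a panel of M = 60
lipoprotein subclass concentrations — may differ very little in the *levels*
of individual measures while differing substantially in how the measures
*co-vary*. `diffpcor` quantifies association through partial correlations:
the correlation between two variables after conditioning on all remaining
ones, i.e. the scaled off-diagonal entries of the inverse covariance matrix.
Under a multivariate Gaussian model a zero partial correlation is exactly
conditional independence, so the nonzero pattern is a Gaussian graphical
model. The package builds one such association network per group, then a
*differential network* whose edges mark pairs where the partial correlation
changed significantly between the groups.

## Shrinkage estimation of partial correlations

With M variables and limited samples, the sample covariance is noisy or
singular and its inverse is useless. We therefore use the linear shrinkage
estimator

\[ U^{*} = \lambda T + (1 - \lambda)\, U, \]

on the correlation scale, where \(U\) is the sample correlation matrix and
the target \(T\) is the identity: unit diagonal, off-diagonal estimates
shrunk towards zero. Variances are not shrunk. The intensity \(\lambda\) is
the analytic optimum of Ledoit–Wolf type,

\[ \hat\lambda = \frac{\sum_{i \ne j} \widehat{\mathrm{Var}}(r_{ij})}
                      {\sum_{i \ne j} r_{ij}^2}, \]

clipped to \([0,1]\), with \(\widehat{\mathrm{Var}}(r_{ij})\) the unbiased
small-sample plug-in \(n/(n-1)^3 \sum_k (w_{kij} - \bar w_{ij})^2\) over the
per-sample products \(w_{kij}\) of values standardized with the
\((n-1)\)-denominator variance. Two conventions complete the definition:

* a zero denominator (all empirical correlations exactly zero) gives
  \(\lambda = 1\) — the data are indistinguishable from the target;
* \(n < 3\) gives \(\lambda = 1\) — the variance of a correlation cannot be
  estimated from fewer than three samples, so estimation degenerates
  gracefully to the target instead of failing. This keeps tiny strata
  usable, at the price of an empty network.

Partial correlations follow by inversion:
\(\mathrm{pcor}_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}\) with
\(\Omega = (U^{*})^{-1}\) (Cholesky-based; a singular input raises an error
advising \(\lambda > 0\)). At \(\lambda = 0\) this reproduces, to 1e-8, the
correlation of residuals from regressing each member of a pair on all other
variables — the property the test suite checks against an independent
regression oracle.

By default variables enter untransformed. Concentration data are often
log-normal; the pipeline exposes a `log_transform` flag rather than
defaulting to it, because partial correlation is already invariant to
per-variable linear rescaling and the reference analysis did not state a
transform.

## Edges of the individual networks

Each pair is tested against the null "the partial correlation is zero". We
use the analytic null density of partial correlations,

\[ p_0(r) \propto (1 - r^2)^{(\kappa - 3)/2}, \qquad r \in [-1, 1], \]

with \(\kappa\) the effective degree of freedom, so the two-sided p-value is
\(P(|R| \ge |r|) = 1 - I_{r^2}(\tfrac12, \tfrac{\kappa-1}{2})\) (a Beta tail).
With `kappa = "auto"` the degree of freedom is estimated from the observed
off-diagonal partial correlations themselves by maximum likelihood. A naive
fit over *all* pairs is badly biased whenever a non-negligible fraction of
pairs is truly associated: on the package's default simulated panel it
under-estimates \(\kappa\) by an order of magnitude and misses most true
edges. The estimator therefore restricts the likelihood to the null bulk: a
robust initial scale (the MAD of \(r\); null \(r\) is approximately
\(N(0, 1/\kappa)\) for large \(\kappa\)) defines a window of four null
standard deviations, and \(\kappa\) maximizes the correctly truncated
likelihood of the retained pairs. This keeps the estimate deterministic and
self-contained — no empirical-null mixture fitting — while being robust to
a sparse fraction of real signal. If the optimizer fails or runs to its
boundary, the fallback \(\kappa = \max(n - M - 1,\, 4)\) (the theoretical
degree of freedom of a full partial correlation) is used; the \(\kappa\)
actually applied is always reported. The approach presumes signal pairs are
a minority; on panels where most pairs are truly associated the fit is still
conservative, and passing a known \(\kappa\) explicitly is the better choice.

Edge inclusion is Bonferroni-conservative: a pair becomes an edge when its
p-value is at or below \(\alpha / K\), \(K = M(M-1)/2\) (inclusive, so ties
at the threshold are kept). Isolated variables stay in the node set, so an
individual network always has all M nodes.

## The differential network

For every pair we observe \(d = |r_A - r_B|\), the absolute difference of
the two group-wise shrinkage partial correlations. Its null distribution is
built by label permutation: all samples are pooled, group labels are
reassigned at random preserving the two group sizes, and both pseudo-groups
are refit *from scratch* — including re-estimation of \(\lambda\) — exactly
as the observed groups were. One shared pool of permutations serves all K
pairs (datasets are permuted, not pairs), so per-pair null samples are
dependent across pairs; the calibration tests therefore aggregate over
replicate datasets rather than over pairs of one dataset. The reference
protocol uses 100,000 permutations (the package default); tests and the
acceptance script use reduced depths stated below.

P-values use the add-one estimator
\(p = (1 + \#\{d^{*} \ge d\}) / (1 + B)\), which counts the observed
statistic as one realization of its own null and can never return zero. For
very small groups `permutation_null(method = "exhaustive")` enumerates all
\(\binom{n}{n_A}\) assignments instead of sampling; the suite uses this to
check the sampled null against exact enumeration.

Significance uses the *uncorrected* \(\alpha\) (default 0.05) on the
two-tailed permutation p-value: for a given sample size the power to detect
a change in a correlation is substantially lower than for a change in a
mean level, so a per-pair cut-off is retained deliberately. The expected
consequence — roughly \(\alpha K\) false differential edges under the
global null — is part of the design and is what the calibration tests
verify; a `bonferroni_differential` flag tightens the cut-off to
\(\alpha/K\) for users who prefer family-wise control.

Significant changes are classified relative to the first (reference) group:

* `sign_change` — opposite signs and both \(|r_A|, |r_B| \ge\)
  `min_magnitude` (default 0.05). The gate exists because a sign flip
  between two noise-level values is not a meaningful regulatory reversal;
  the reference analysis colors such edges without stating a rule, so the
  gate is an explicit, configurable interpretation.
* `increase` — \(|r_B| > |r_A|\); `decrease` — otherwise.

## Topology

Definitions follow the standard undirected conventions: degree \(k_i\);
degree distribution \(P(k)\) = nodes of degree \(k\) divided by the *total*
node count N (isolated nodes count in N but are not support points); Freeman
betweenness summing \(\sigma_{st}(v)/\sigma_{st}\) over unordered pairs
(unnormalized by default — a normalization flag exists and never changes the
ranking); local clustering \(c_i = K_i / \binom{k_i}{2}\) with \(c_i = 0\)
for \(k_i < 2\), averaged over all nodes for the network-level value.
Density is \(2E/(N(N-1))\) and average degree \(2E/N\) over all N nodes,
isolated included — a 60-node, 126-edge network thus has average degree 4.20
and density 0.071 at three decimals. The degree-distribution slope is a
least-squares fit of \(P(k)\) against \(k\); the default log–log scale reads
the distribution as a power law \(P(k) \sim k^{\gamma}\). Because published
slope values depend on unstated fitting choices (scale, binning, zero
handling), the slope is always reported together with its scale label and
is not treated as a reproducible target. Graph algorithms are delegated to
igraph; the k<2 clustering convention and the distribution/slope definitions
are applied on top.

## The simulator

`simulation_spec()` describes two Gaussian graphical models sharing a
block-diagonal partial-correlation backbone — blocks emulate panels of
closely related measures such as lipoprotein subclasses, which correlate
strongly within a size class — plus chain links between consecutive blocks
(the lipoprotein cascade runs across the size range). The groups are
identical except for a chosen set of differential pairs whose group-B
partial correlation is overridden. Defaults mirror the motivating study's
conditions: M = 60 variables in 14 blocks (four of 5, ten of 4), group
sizes 4406 and 531, within-block partial correlation 0.2 (the largest round
value for which 5-member equicorrelated blocks remain positive definite
without repair), cross-block links at 0.2, and three planted differential
pairs covering the three change categories.

Construction: the unit-diagonal partial-correlation pattern maps to a
precision matrix with \(\Omega_{ij} = -\mathrm{pcor}_{ij}\); if that matrix
is not positive definite, the smallest \(\delta \in \{0, 0.05, 0.1, \dots\}\)
with \(\min \mathrm{eig}(\Omega + \delta I) \ge 10^{-6}\) is added and the
matrix re-standardized to unit diagonal (an error is raised past
\(\delta = 2\)). Inflation attenuates the requested values, so the
*realized* partial correlations are recomputed from the final matrix and
stored — every recovery statement in the tests is made against realized,
not requested, values. Sampling draws the two groups from the zero-mean
Gaussians with covariance \(\Omega^{-1}\), deterministically given the seed.

What the simulator does *not* emulate: non-Gaussian marginals, detection
limits, measurement noise structure, or the strong mean differences real
cohorts can show. Passing tests therefore demonstrate correctness of the
estimators and calibration of the tests under the Gaussian graphical model,
not robustness to real-data pathologies.

## Numerical and reproducibility choices

* \(\lambda\) is clipped to \([0,1]\); \(\lambda = 1\) on a zero
  denominator or \(n < 3\).
* Matrix inversion is Cholesky-based; symmetry of inputs is required to
  1e-8 and of outputs enforced to below 1e-10.
* p-value comparisons with thresholds are inclusive (\(\le\)); ties in
  p-values need no breaking (all tied significant pairs are kept).
* Permutations and simulation draws use R's Mersenne-Twister generator
  under an explicit, recorded seed; the caller's RNG state is restored
  afterwards. Identical configurations produce byte-identical outputs, and
  every pipeline output file name carries a hash of the configuration.
* The input file's column order is the canonical variable ordering
  everywhere (pair indexing, matrices, edge tables). Rows with missing
  values are dropped and counted (complete-case analysis, matching
  cohort-style exclusion of incomplete profiles).

## Problem sizes used by the checks

The test suite and acceptance script scale the Monte-Carlo work to desk
size: null calibration uses M = 10 with 200 samples per group, 500
permutations and 200 replicate datasets (acceptance tests; the script uses
100 replicates at 300 permutations); sign-flip recovery plants
\(+0.4 \to -0.4\) on a 6-variable panel with 1000 samples per group, 2000
permutations and 50 replicates (script: 20 replicates at 1000); family-wise
error uses M = 20, n = 500 and 100 identity-model replicates; the full-panel
demonstration runs the default 60-variable spec with 1000 permutations.
These sizes are the package's validation choices; the method itself defaults
to the 100,000-permutation protocol.

## Known limitations

* The \(\kappa\) null fit presumes mostly-null pairs; dense-signal panels
  push it conservative (fewer edges than truth), never anti-conservative in
  our checks, but an externally supplied \(\kappa\) is preferable there.
* The uncorrected differential cut-off trades family-wise error for power
  by design; differential edge lists on large panels contain an expected
  \(\alpha K\) false pairs and should be read as a screening output.
* Between-group differences in marginal variances do not affect partial
  correlations (scale-invariance), but strong mean shifts combined with
  label permutation can inflate pooled correlations; the test is exchangeable
  under the full joint null, which is the hypothesis actually tested.
* The sign-change gate `min_magnitude` is an interpretation layer on top of
  the significance test, not part of it; setting it to zero restores a pure
  sign rule.
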