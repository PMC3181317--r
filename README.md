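# diffpcor

Differential partial-correlation networks for two-group molecular profiling
data.

## What problem this solves

Two physiological groups measured on the same panel of variables — the
motivating case is lipoprotein subclass concentrations in individuals with
normal versus impaired fasting glucose (prediabetes) — can look almost
identical variable-by-variable while differing markedly in how the
variables co-vary. `diffpcor` targets exactly that: it quantifies
association by **partial correlations** (association between two variables
conditioning on all others, the scaled off-diagonal of the inverse
covariance), builds a per-group association network, and then tests every
pair for a **change** in partial correlation between the groups. It is
aimed at metabolomics / systems-biology analysts comparing association
structure across conditions, but applies to any samples × variables table
with a two-level group label.

## The method

Per group, the correlation matrix is estimated by linear shrinkage with the
Ledoit–Wolf analytic intensity and an identity target,

U\* = λT + (1 − λ)U,  λ̂ = Σ<sub>i≠j</sub> Var̂(r<sub>ij</sub>) / Σ<sub>i≠j</sub> r<sub>ij</sub>²  (clipped to [0, 1]),

and partial correlations follow from the inverse,
pcor<sub>ij</sub> = −Ω<sub>ij</sub>/√(Ω<sub>ii</sub>Ω<sub>jj</sub>),
Ω = (U\*)⁻¹. Each pair is tested against zero under the analytic null
density p₀(r) ∝ (1 − r²)^((κ−3)/2), with κ fitted by maximum likelihood on
the null bulk of the observed partial correlations; edges pass a Bonferroni
threshold α/K, K = M(M−1)/2.

The **differential network** tests, per pair, d = |r<sub>A</sub> −
r<sub>B</sub>| against a permutation null: group labels are repeatedly
reassigned (group sizes preserved), both pseudo-groups are refit from
scratch (λ re-estimated each time), and p = (1 + #{d\* ≥ d})/(1 + B).
Significant pairs (uncorrected α by default — power for correlation changes
is low, and this choice is deliberate) are classified relative to the first
group as `increase`, `decrease`, or `sign_change`. Networks are
characterized by degree, degree distribution P(k) and its fitted slope,
Freeman betweenness, and clustering coefficients (c = 0 for degree < 2).

A block-structured Gaussian graphical model simulator (blocks emulating
lipoprotein subclasses, with planted differential edges) makes the entire
pipeline testable without access to cohort data.

## Worked example

Simulate a 20-variable panel (four correlated blocks plus singletons) where
one cross-block partial correlation flips sign (+0.2 → −0.2) between the
groups, then run the pipeline:

```r
library(diffpcor)

spec <- simulation_spec(
  block_sizes = c(3, 3, 3, 3, rep(1, 8)),
  within_block_pcor = 0.25,
  cross_block_edges  = data.frame(i = 1, j = 4, pcor = 0.2),
  differential_edges = data.frame(i = 1, j = 4, pcor_B = -0.2,
                                  category = "sign_change"),
  n_A = 800, n_B = 600, seed = 42)
ds <- sample_dataset(spec)

fit <- fit_group(ds, "A")
net <- build_network(edge_pvalues(fit),
                     bonferroni_threshold(0.05, 190))
global_summary(net)
dn <- build_differential_network(ds, n_perm = 5000, seed = 7)
dn
```

which prints:

```
Shrinkage partial-correlation fit (group 'A')
  variables: 20  samples: 800
  shrinkage intensity lambda: 0.1469
  |pcor| range: 0.000273 - 0.274
Global network properties
  Connected nodes            12
  Isolated nodes             8
  Total number of edges      13
  Network density            0.068
  Average degree             1.3
  Slope of degree distr.     -3.969 (log-log)
  Clustering coefficient     0.533
  Top hubs: B01.1 (k=3), B02.1 (k=3), B01.2 (k=2)
Differential network: A vs B
  pairs tested: 190  permutations: 5000  cut-off p <= 0.05
  differential edges: 9
    increase: 3, decrease: 4, sign_change: 2
  differentially connected variables: 13  unconnected: 7
```

Reading the output: group A's individual network recovers the 13 planted
associations (12 within-block pairs plus the cross-block link) at the
α/K = 2.6e-4 threshold, with the 8 background variables isolated. In the
differential analysis the planted pair B01.1–B02.1 is the strongest hit
(d = 0.342, p = 2.0e-4, the smallest attainable at B = 5000) and is
classified `sign_change`; the remaining significant pairs are the expected
scatter at the uncorrected 0.05 cut-off. `differential_edges(dn)` returns
the significant pairs as a data frame; `write_network()` exports GraphML or
TSV edge tables.

A command-line wrapper with `screen` / `network` / `diffnet` / `topology` /
`simulate` subcommands is installed at `inst/cli/diffpcor-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(find.package("diffpcor"))')/cli/diffpcor-cli.R" \
  diffnet --input data.tsv --group-column group --n-perm 100000 --seed 1 \
  --output-dir results/
```

Every run writes a YAML log (parameters, per-group λ, κ, seed, counts) and
stamps output files with a configuration hash.

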