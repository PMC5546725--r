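---
title: "Co-expression module inference across expression compendia: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression module inference across expression compendia: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clicr)
```

# The problem

Given a query gene set (a pathway, a protein complex, a hit list) and a large
compendium of expression datasets, which subsets of the query are genuinely
co-expressed, in which datasets, and which other genes in the transcriptome
share that co-expression? Averaging correlations over one dataset — or over
all datasets — fails in two characteristic ways: a pathway is usually active
(and hence co-regulated) in only a minority of conditions, so its signal is
diluted by the datasets where it is silent; and some genes correlate with
nearly everything, so they top any naive correlation ranking regardless of the
query. `clicr` addresses both with a Bayesian partition model over *Fisher
z-transformed correlations* with per-dataset selection indicators, and an
expansion score that tests candidates against their own *gene-specific*
correlation background instead of zero.

# Preprocessing and background estimation

Each dataset is a genes-by-samples matrix of non-negative values. The pipeline
(`build_compendium()`) applies, per dataset:

1. log-scale detection: a maximum below 30 indicates log2 units, and values
   are exponentiated (`rescale_if_log()`);
2. removal of datasets with fewer than 6 samples (correlations too noisy) or
   a maximum below 1000 (truncated or mis-scaled uploads);
3. column-mean normalization: every sample column is scaled to the grand mean
   of the original column means. The target value is a design choice — any
   common constant equalizes the columns; using the grand mean preserves the
   total signal;
4. the pairwise Pearson correlations of all gene rows are mapped through
   z = atanh(r). Genes with zero variance are excluded (their correlations
   are undefined). Correlations of exactly ±1 are clamped to |r| ≤ 1 − 1e-6
   so downstream likelihoods stay finite;
5. the *dataset background* (θ~d,0~, σ²~d,0~) is the mean and population
   variance of all N(N−1)/2 pairwise z values, and the *gene-specific
   background* (θ~d,0,i~, σ²~d,0,i~) the mean and population variance of
   gene i's N−1 z values. Population (not n−1) divisors follow the estimator
   definitions; at these sample sizes the difference is negligible.

**Quality control.** A well-normalized dataset has a unimodal, near-normal z
background; batch structure or bad normalization produces multimodal ones. We
compare a Gaussian-kernel density fit of the z values (Silverman bandwidth,
1024-point grid spanning θ~d,0~ ± 6σ~d,0~, trapezoid integration) with the
normal fit N(θ~d,0~, σ²~d,0~) by the L1 (total-variation) distance
δ = ∫|p − q| and drop datasets with δ > 0.1 or σ²~d,0~ > 1. For very large
compendia the moments are exact streaming sums; only the kernel fit may use a
seeded subsample of at most 10⁶ pairs.

# The partition model

For a query of n genes over D retained datasets, let Z~d~ be the n×n matrix
of query z-correlations in dataset d. Memberships I assign each gene to one
of K module labels or to a null group (label 0). A binary indicator S~d,k~
says whether dataset d "supports" CEM k. Within a supported CEM, pairwise z
values are modelled as N(θ~d,k~, σ²~d,k~); all other pairs (between CEMs,
involving null genes, or within unsupported CEMs) follow the dataset
background N(θ~d,0~, σ²~d,0~), which is treated as known from preprocessing.

Conjugate priors: θ~d,k~ ~ N(μ~θ~, σ²~d,k~/κ~θ~) and σ²~d,k~ ~
Inv-Gamma(α~σ~, β~σ~); S~d,k~ ~ Bernoulli(π~S~); and P(I) ∝ exp(−v~K~·K),
penalizing the number of modules.

Defaults (all dimensionless, on the z scale where relevant):

| parameter | default | meaning |
|---|---|---|
| μ~θ~ | 1.5 | prior within-CEM z mean; tanh(1.5) ≈ 0.9 Pearson |
| κ~θ~ | 100 | prior precision scale for θ~d,k~ |
| α~σ~, β~σ~ | 1000, 1000 | pins σ²~d,k~ near 1, the natural scale of variance-stabilized z |
| π~S~ | 0.1 | prior dataset-selection probability |
| v~K~ | n/D | module-count penalty |
| K̄ | 5 | number of fixed-K chains (labels per chain) |
| M | 1000 | Gibbs sweeps per chain |

Two conventions are deliberately resolved here because the model statement
leaves them open. First, the Gibbs conditional for a gene's label includes
the null label 0 among the sampled categories; otherwise no gene could ever
enter the documented null group. Second, the K in P(I) ∝ exp(−v~K~K) is
counted as the number of labels currently occupied by at least two genes —
a "module" needs a pair — which makes the prior comparable across chains run
with different numbers of available labels.

## Collapsed sampling

θ, σ² and S are integrated out analytically. The θ/σ² integral is the
standard Normal–Inverse-Gamma marginal of the within-CEM z values, computed
entirely in log space (`log_nig_marginal()`); the S sum turns each
(dataset, CEM) factor into
log[π~S~·e^m1^ + (1−π~S~)·e^m0^], with m1 the NIG marginal and m0 the
background likelihood of the same pairs. The collapsed likelihood is the
background likelihood of *all* pairs plus these per-CEM corrections
(`log_collapsed_lik()`), so a gene update touches only the factors of the
CEM it leaves and joins. The sweep loop is implemented in C++ with
incremental sufficient statistics (pair count, Σz, Σz² per dataset and CEM);
the running log posterior is refreshed from the cached factors once per sweep
to stop floating-point drift, and the tests verify the incremental value
against a full R-side recomputation.

One chain is run for each K in 1..K̄, initialized with all genes null, for M
sweeps; every state visited after every single-gene update is a MAP
candidate. Ties across chains keep the smaller K. After selection, CEM
labels are renumbered in decreasing size order and singleton labels are
demoted to the null group. All randomness flows through R's generator (the
C++ code draws via `unif_rand`), with chain K seeded at `seed + K`, so fits
are exactly reproducible.

The suite checks the sampler against an exactly enumerated posterior on a
6-gene, 3-dataset, K = 2 problem (3⁶ = 729 states): visit frequencies over
50 000 post-burn-in sweeps must match within total-variation distance 0.05.
The fixture's signal is deliberately *moderate* (a 3-gene module at z ≈ 0.9
in one dataset): the posterior is label-symmetric, and with a near-degenerate
signal a finite chain would sit in one of the two symmetric modes and the
test would measure mixing rather than correctness.

## Point estimates, weights, strength

Conditional on the MAP partition, θ̂~d,k~ and σ̂²~d,k~ are the sample mean
and population variance of the within-CEM z values per dataset, with σ̂²
floored at 1e-6 (a CEM with a single pair in a dataset has zero empirical
variance, and the expansion densities must stay finite). The dataset weight
p̂~d,k~ = π~S~e^m1^ / (π~S~e^m1^ + (1−π~S~)e^m0^) is the posterior
probability that dataset d supports CEM k; a CEM with no pair in a dataset
has m1 = m0 = 0 and weight exactly π~S~. The CEM strength
φ~k~ = (1/D)·Σ~d~ p̂~d,k~(m1~d,k~ − m0~d,k~) is a weighted average log Bayes
factor; φ > 0.1 is read as "co-expressed" and φ > 1 as "strongly
co-expressed".

Note that p̂~d,k~ is *not* expected to hover near π~S~ on ordinary
non-supportive datasets. When the within-CEM pairs sit exactly on a clean
dataset's background, m1 − m0 is strongly negative (the prior pins the
foreground variance near 1 while the background is far tighter), so p̂ → 0.
The prior value π~S~ is recovered only when a CEM contributes no pairs.

# Expansion

For each CEM k and candidate gene i outside the query,
LLR~k,i,d~ = Σ~j∈k~ [log N(z~d,j,i~ | θ̂~d,k~, σ̂²~d,k~) −
log N(z~d,j,i~ | θ~d,0,i~, σ²~d,0,i~)], and the integrated score is
Σ~d~ p̂~d,k~·LLR~k,i,d~ — the posterior mean of S~d,k~ replaces the binary
indicator. Candidates above 0 form CEM+; above 10 they are flagged
significant. Ties are broken lexicographically by gene identifier, and every
score reports how many datasets contributed (a gene absent from a dataset
contributes nothing there). nLLR divides the integrated LLR by CEM size so
that assignments of an uncharacterized gene can be compared across CEMs of
different sizes (`assign_uncharacterized()`).

The gene-specific H0 is the package's defence against "hub" genes that
correlate with much of the transcriptome: their z values to a CEM are
unremarkable *relative to their own background*, so their LLR stays low even
when their raw correlation to the CEM is high. The `background = "dataset"`
ablation of `predict()` replaces every gene's H0 with the dataset background
and is used by the tests to verify the direction of this correction.

Two subtleties are worth recording. First, the foreground density is peaked
(σ̂² is typically ~1/(m−3) ≈ 0.02 at 50 samples), so the best possible
candidate is one whose z profile *matches θ̂~d,k~* — an exact copy of a
member, whose z to its original clamps at atanh(1 − 1e-6) ≈ 7.25, is heavily
penalized by that same density. "More correlated" is not "better" under this
likelihood, and the tests assert top ranks for module-strength candidates
rather than for literal copies. Second, after column-mean normalization the
*average* correlation of any gene with the whole transcriptome is close to
zero by construction (the normalization removes, to first order, any factor
loaded uniformly by all genes), so a hub's gene-specific background is
elevated mostly in its variance and in its correlation with a large block of
genes, not as a large mean shift; the correction works through those terms.

# The synthetic compendium generator

`simulate_compendium()` emulates the structure the model assumes, with truth
labels for testing: many independent datasets; per-dataset latent factors
combined with fixed gene loadings plus independent noise (unit total
variance, so correlations are loading products); planted modules sharing a
module factor only in their supportive datasets; expansion-pool genes
carrying the same signal (optionally at their own strength via
`pool_pearson`, which provides graded "near-miss" candidates); and an
expression map 1000 + 250·x floored at 1, so datasets are linear-scale,
positive, and exercise rather than bypass the magnitude filters.

Three structural choices deserve explanation:

* **A dataset-wide factor** (squared loading `background_correlation` = 0.1)
  mimics the raw-data dataset effect. Column-mean normalization removes it
  almost exactly — which is the realistic behaviour: background z values end
  up centred near 0 with variance ≈ 1/(m−3).
* **A block factor** carried by 30% of background genes (squared loading
  0.25), weakly by module/pool genes (0.2) and strongly by hub genes (0.81).
  Because only part of the transcriptome loads it, normalization does not
  remove it; it gives the compendium a realistic correlated substructure and
  gives hub genes their genome-wide correlation. A factor loaded by *all*
  genes cannot produce a hub that survives normalization (see above), which
  is why hubs are planted on the block factor.
* **Bimodal datasets** (two sample blocks with gene-specific opposite mean
  shifts) produce the multimodal z background that the TV-distance QC is
  designed to remove, and are used to test it.

The default configuration is the study condition used throughout the
end-to-end tests and the reproduction script: 40 datasets × 50 samples, 500 background genes, an 8-gene
and a 6-gene module at within-module Pearson 0.81, each supported by 10
disjoint datasets, 10 expansion-pool genes per module, one hub, and a query
that adds 4 noise genes. The benchmark configuration for the
leave-one-out comparison gives the second module a weaker context (0.65):
with two equally strong modules a single merged CEM still selects both
supportive dataset groups and the no-partition ablation loses nothing at
rank 50, so heterogeneous context strength — the situation the partition
step exists for, and the reason strength-stratified recall curves are
informative — is the appropriate benchmark design.

What the generator does *not* emulate: probe-level noise, saturation,
heavy-tailed expression, missing genes per platform, or duplicated datasets.
Passing tests demonstrate correctness of the inference machinery under the
model's own assumptions at desk scale, not performance on real compendia of
thousands of GEO datasets.

# Numerical choices and degenerate inputs

* correlations clamped to |r| ≤ 1 − 1e-6 before atanh;
* all marginals computed in log space via `lgamma`; the two-branch selection
  factor via log-sum-exp;
* σ̂²~d,k~ floored at 1e-6; gene-specific background variances floored at
  1e-12 in the expansion densities;
* sweep order is fixed ascending gene index; label draws use a single
  cumulative-probability inversion of R's uniform stream;
* no burn-in for MAP search (every visited state competes); the
  posterior-frequency diagnostics discard the first 10% of sweeps;
* MAP ties prefer smaller K, then the earlier chain;
* queries must contain at least 2 genes measured in the compendium; a
  single-gene query is an error by design (co-expression needs a pair);
* LOOCV seeds each held-out run at `seed + index`, and a run whose reduced
  query yields no CEM records rank ∞.

# Problem sizes

The test suite and the acceptance script run entirely on generated data: the
sampler-exactness check enumerates 729 states and draws 55 000 sweeps; the
recovery study fits 20 independently generated 40-dataset compendia; the
benchmark runs full leave-one-out (18 fits) plus ablation and baseline. These
sizes keep a full run in a few minutes on one CPU while leaving each check
statistically meaningful.

# Known limitations

* The MAP search over fixed-K chains has no split–merge or tempering moves;
  at query sizes ≤ ~250 genes the per-gene conditional scan mixes well, but
  very large queries would need the larger-K̄ scheme exposed in
  `clic_control()`.
* With v~K~ = n/D the module-count penalty is mild: on a pure-noise query
  the MAP occasionally (order 1-in-10 compendia at the default study scale)
  promotes one lucky gene pair (a ~4–5σ sampling fluke in one dataset) into
  a weak 2-gene CEM with φ barely above 0.1. The CEM strength, not the mere
  existence of a CEM, is the intended guard against over-reading such
  output.
* Dataset weights are posterior selection probabilities under a sharply
  specified foreground prior; they saturate quickly (0 or 1) and should not
  be read as graded effect sizes.
* The diagonal-covariance treatment of the pairwise z values (pairs sharing
  a gene are treated as independent) is a modelling approximation inherited
  from the model family; it is not corrected here.
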