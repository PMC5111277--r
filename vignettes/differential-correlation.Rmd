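---
title: "Differential correlation analysis: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential correlation analysis: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgcor)
```

## The model

`dgcor` tests, for each gene pair, whether the correlation of the two
genes' expression differs between two conditions. The per-condition sample
correlation $r$ (Pearson or Spearman, on pairwise-complete observations)
is variance-stabilized with the Fisher transform $z = \mathrm{atanh}(r)$.
Under approximate bivariate normality the transformed coefficient is
close to normal with variance $1/(n-3)$ (Pearson) or $1.06/(n-3)$
(Spearman), where $n$ is the number of complete observations behind that
particular pair in that condition — so missing data and unequal group
sizes propagate into per-pair variances rather than being ignored. The
test statistic is

$$ dz = \frac{z_2 - z_1}{\sqrt{s^2_{z_1} + s^2_{z_2}}}, $$

referred to the standard normal, two-sided. The denominator is the
variance sum of two independent estimates — the standard two-sample
construction. Positive $dz$ means a gain of correlation in the
second-listed condition of `compare`; swapping the conditions negates
every $dz$ and leaves p-values unchanged. The same convention carries
through the aggregate statistics, so a gene-level median $dz > 0$ is a
tendency towards gain of correlation in the second condition.

Independently of the $dz$ test, each condition's correlation is
classified as significantly positive, significantly negative, or neither
(two-sided p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df,
threshold $\alpha$), and the pair is labeled with the Cartesian product of
the two states — nine classes such as `+/0` or `-/+`. A pair can be `+/0`
without being significantly differential; the class describes states, the
$dz$ test describes change. Per-condition p-values are deliberately not
multiplicity-adjusted: they define descriptive states, not discoveries.

### Sign restriction

When only one correlation direction is biologically meaningful — positive
correlations with a transcriptional activator, say — `sign_type =
"positive"` clamps negative coefficients to zero *before* the transform
(mirrored for `"negative"`). The class label always uses the unclamped
coefficients: the restriction changes what counts as evidence of change,
not the description of each condition.

## Multiple testing by permutation

All-pairs analysis of $G$ genes performs $\binom{G}{2}$ tests. Rather than
relying on the parametric p-values being exactly calibrated (they inherit
the bivariate-normality assumption behind the variance formulas), the
default adjustment shuffles the sample labels across the two compared
conditions, reruns the entire pipeline per shuffle, and pools every
permuted $|dz|$ across pairs and permutations into one reference null.
Each observed pair is ranked in that pool with an add-one pseudocount:

$$ p_i = \frac{1 + \#\{v \in \text{pool}: v \ge |dz_i|\}}{1 + |\text{pool}|}. $$

Because the pool is shared, even 10 permutations (the default) of a
10,000-pair analysis give a null of 100,000 values; the add-one form makes
the resolution floor of the scheme explicit. The proportion of true nulls
$\pi_0$ is estimated by the spline method: raw estimates
$\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ over the grid
$\lambda = 0.05, 0.10, \ldots, 0.95$, a cubic smoothing spline with 3
effective degrees of freedom, evaluated at the largest $\lambda$ and
clamped to $(0, 1]$. The grid and spline df are not prescribed anywhere
authoritative; they are package defaults, exposed as arguments, and the
fallback ($\pi_0 = 1$, i.e. plain BH behaviour) triggers with a warning
when fewer p-values than grid points are available. q-values are the
$\pi_0$-scaled step-up minimum $q_i = \pi_0 \min_{p_j \ge p_i} m p_j /
\text{rank}_j$.

The aggregate tests (`median_dz_test()`) are *non-pooled*: one statistic
per gene, each compared only against its own permutation replicates, so
the permutation count sets a hard floor of $1/n_{perm}$ on attainable
p-values. The default is 1,000 permutations (printing a p of 0 as
"< 1/n"); single-gene-set analyses with few statistics warrant 10,000.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `method` | pearson | correlation estimator; spearman inflates $s^2_z$ by 1.06 |
| `alpha` | 0.05 | per-condition significance for class labels |
| `sign_type` | all | clamp correlations before the $dz$ transform |
| `adjust`, `n_perm` | perm, 10 | pooled permutation q-values |
| `sig_threshold` | 0.05 | reporting threshold on q (class shown vs `NonSig`) |
| `central_pct`, `dispersion_pct` | 0 / 0.25 typical | expression-filter quantiles |
| `n_perm` (aggregate) | 1000 | non-pooled permutation count |
| `min_size`, `max_size` | 50, 600 | gene-set size window in enrichment comparison |

Gene filtering removes genes below the chosen quantile of a central
tendency (median or mean) and/or of a dispersion measure (dispersion
index = variance/mean, or sd) — low-information genes whose correlations
are mostly noise. Quantiles interpolate linearly between order statistics
and ties at the cutoff survive; since re-computing percentile cutoffs on a
filtered matrix would remove a further slice, the realized absolute
cutoffs are attached to the result and can be passed back to make the
filter idempotent. Union ("and/or") semantics are the default, with an
`intersection` option.

## Numerical choices and degenerate inputs

- $|r| \ge 1 - 10^{-12}$ is clipped to that bound before `atanh` (with a
  warning), so duplicated genes yield finite statistics.
- Any pair with fewer than 4 complete observations in either condition,
  or zero variance in either gene, is undefined: it propagates as `NA`,
  is excluded from the permutation pool and from $\pi_0$ estimation, and
  classifies as `"NA"`.
- Each compared condition must contain at least 4 samples (the $n-3$
  variance denominator); violations are hard errors.
- Ties in the sorted output (equal $|dz|$) break lexicographically by
  gene ids, so results are bit-reproducible.
- Spearman uses average ranks for ties and no continuity correction.
- In the enrichment comparison, any zero contingency cell triggers the
  Haldane–Anscombe +0.5 correction on all four cells; the two signatures'
  log odds ratios are compared with $z = (OR_1 - OR_2)/\sqrt{SE_1^2 +
  SE_2^2}$, the variance sum for independent estimates. BH adjustment is
  applied within each set category (e.g. BP/CC/MF) separately. The
  default universe is every gene surviving the expression filter — the
  conservative choice when annotation coverage is unknown — and is an
  explicit argument.

## The simulation benchmarks

### Pair level

`build_pair_spec()` emulates a bulk RNA expression experiment in which
most pairs are uncorrelated and a known minority changes: 600 genes in
three groups — 300 "activated" (high mean, high dispersion), 100
"housekeeping" (high mean, halved dispersion), 200 "silent" (low mean) —
with per-gene means drawn from a negative binomial with dispersion 0.5
(floored at 1) and per-gene variance $\mu + d\mu^2$. Group location
parameters are not prescribed by any external source; the defaults
($\mu = 100$ expressed, $\mu = 5$ silent) produce the intended bimodality
of expression means, and "one-fold lower dispersion" for housekeeping
genes is realized as $d$ halved (0.25 vs 0.5). For each of the 8 planted
classes (`+/0`, `0/+`, `-/0`, `0/-`, `+/-`, `-/+`, `+/+`, `-/-`), 19
consecutive super-diagonal positions among the activated genes receive
correlation ±0.5 per condition; placing signal only on the
super-/sub-diagonal keeps the matrix near positive definite with mixed
signs. `+/+` and `-/-` plant identical correlations in both conditions,
so of 152 designated pairs 114 are truly differential — 38 strong
($|\Delta\rho| = 1$) and 76 medium ($|\Delta\rho| = 0.5$). Samples are
multivariate normal per condition (`MASS::mvrnorm`).

Ranking all 179,700 pairs by $|dz|$ against this truth yields AUC
$\approx 0.73$ at 10 samples per condition and $> 0.99$ at 100 (test
suite: 5 replicate seeds at n = 10 vs 100; acceptance script: 3
replicates), with power monotone in sample size on matched seeds. These
problem sizes (600 genes, up to 100 samples, 3–5 replicates) keep the
whole validation suite within a few minutes while leaving the AUC
estimates stable to well under the margins asserted.

### Module level

`build_module_spec()` plants two disjoint 30-gene modules; a fraction
$\kappa$ (the network connectivity, 0.5–1) of each module's
super-diagonal positions carries correlation 0.9 in condition A and none
in condition B. Positive definiteness is enforced by an eigenvalue floor
at 0.4 of the largest eigenvalue, which deliberately attenuates the
realized correlations (to roughly 0.25–0.3); the planted 0.9 compensates,
and condition B remains exactly uncorrelated. The repair runs on the
*correlation* matrix, which is then renormalized and scaled by the gene
variances: applied to the covariance directly, the relative floor would
be set by the single most variable gene and would erase the planted
structure entirely. Module *detection* is out of scope — the package
scores any detector's output via `module_recovery_metrics()` (best
sensitivity over detected modules under a size cap, best Jaccard over
all; an empty detection is scored as the all-gene pseudo-module, fixing
the floor Jaccard 30/600 = 0.05).

### What the simulations do not emulate

Multivariate normal draws with planted product-moment correlations are a
clean test of the statistic, not of real data: there are no counts, no
library-size or batch effects, no missing values, no heavy tails, and the
planted structure is sparse and block-free outside the designated
positions. Passing benchmarks therefore demonstrates correctness and
ranking power under the stated model, not robustness to the full
messiness of RNA-seq; normalization and covariate correction are assumed
to happen upstream.

## Design decisions worth knowing

- **dz denominator and sign.** The variance-sum denominator
  $\sqrt{s^2_{z_1} + s^2_{z_2}}$ is the standard construction for a
  difference of independent estimates (a difference form degenerates for
  equal sample sizes), and the package verifies it reproduces published
  worked-example z-scores to within rounding. $dz$ is second-condition
  minus first throughout, including the aggregate medians.
- **Classification uses unclamped coefficients** under sign restriction
  (see above).
- **Pooled vs non-pooled nulls.** Pair-level FDR shares one pooled null
  (few permutations suffice, memory is the constraint at genome scale);
  aggregate gene-level tests use per-statistic nulls (permutation count
  bounds the attainable p-value).
- **`bh_adjust()` wraps `stats::p.adjust`**; the q-value/π₀ machinery is
  implemented in-package and validated against null and alternative
  simulations in the test suite.

## Limitations

- Two conditions only; no trend tests across three or more groups.
- The variance formulas assume approximate bivariate normality; heavy
  deviations are exactly what the permutation mode is for, so prefer
  `adjust = "perm"` for calibrated error rates.
- Empirical p-values are granular at $1/(|\text{pool}|+1)$; with few
  pairs (heavy filtering, `split_gene`) increase `n_perm` accordingly.
- Correlation is undirected and pairwise: a significant pair says
  nothing about causality or about conditioning on other genes.
- Local false discovery rates are not implemented; the option name is
  reserved in the configuration schema.
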