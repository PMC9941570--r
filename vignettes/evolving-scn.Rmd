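---
title: "Methods: evolving structural covariance networks from sparse longitudinal volumes"
author: "dynscn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolving structural covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A structural covariance network (SCN) is a weighted graph whose nodes are
parcellated brain regions (ROIs) and whose edges are across-subject
correlations of regional volumes at a given age.  In accelerated
longitudinal pediatric cohorts the data are sparse and irregular: most
children are seen once, at ages scattered over a decade, so an SCN "at
age t" cannot be computed by pooling an age bin without discarding the
actual ages.  `dynscn` estimates the full age-indexed correlation matrix
$R(t)$ — and from it thresholded networks and their summaries — at any
age in the observed range, and tests whether child-level covariates (sex
by maternal education, or a continuous cognitive score) shape the
*evolution* of the network summaries.

## The estimator

Write a visit as a pair $(T_i, Y_i)$ of age and an $m$-vector of ROI
volumes.  The pipeline is:

1. **Mean growth curves.** Each ROI's conditional mean volume
   $\mu_j(t) = E(Y_j \mid T = t)$ is estimated by a local-linear kernel
   smoother (same kernel family as the regression step below).  The
   smoother reproduces linear functions exactly, so growth trends do not
   leak into the covariance estimates at first order.
2. **Raw covariances.** Each visit contributes the rank-one matrix
   $\hat C_i = (Y_i - \hat\mu(T_i))(Y_i - \hat\mu(T_i))'$, an unbiased
   (up to mean-estimation error) but extremely noisy reading of the
   conditional covariance at age $T_i$.
3. **Local Fréchet regression.** The conditional Fréchet mean of the
   $\hat C_i$ under the Frobenius metric, localized at age $t$ with
   local-linear weights
   $s_i(t,h) = \hat\sigma_0^{-2} K_h(T_i - t)\,[\hat b_2 - \hat b_1 (T_i - t)]$,
   has a closed form over the positive-semidefinite (PSD) cone: the
   weighted average $\sum_i s_i \hat C_i / \sum_i s_i$ followed by
   projection onto the cone (eigenvalues clipped at zero).  The
   projection matters because local-linear weights are negative near the
   design boundary, so the raw average can have (slightly) negative
   eigenvalues.  With two covariates (age and a cognitive score) the
   weights take the bivariate local-linear form with a product kernel and
   per-dimension bandwidths.
4. **Standardization and thresholding.**
   $\hat R(t) = D^{-1/2} \hat\Sigma(t) D^{-1/2}$ with
   $D = \mathrm{diag}(\hat\Sigma(t))$; then value-retaining thresholding
   at $\theta$: entries $\ge \theta$ keep their correlation value, all
   others (including every negative correlation, since $\theta > 0$)
   become zero, and the diagonal is zero.  Networks are never binarized.
5. **Summaries.** Weighted modularity
   $Q = s^{-1}\sum_{ij}(a_{ij} - d_i d_j / s)\,\delta_{m_i m_j}$ over a
   detected partition, and global efficiency
   $E = m^{-1}\sum_i \frac{\sum_{j\neq i} l_{ij}^{-1}}{m-1}$ with
   weighted shortest-path lengths; both averaged over the threshold grid.
6. **Inference.** For evaluation ages $t_1 < \dots < t_N$ the integrated
   measure $I(t_j) = \sum_{l \ge j} \bar M(t_l)(t_l - t_{l-1})$ (with
   $t_0 = 0$) summarizes the trajectory from $t_j$ onward; the test
   statistic at $t_j$ is the variance of $I_k(t_j)$ across the $K$
   groups (divisor $K-1$), and its null distribution is obtained by
   permuting labels (or the score column) and re-running the estimation.
   The one-sided p-value is the proportion of permutations whose
   statistic is $\ge$ the observed one (ties count).

### Working assumptions

Visits are treated as independent pairs, also when one child contributes
several.  This matches the estimator's formulation for sparse designs
and keeps permutation of visit labels exchangeable under the null; the
`unit = "child"` option permutes whole children instead, as a robustness
check when within-child dependence is a concern.  The mean curves are
fit once on the pooled sample (they do not depend on group labels);
`mean_per_group = TRUE` refits per group.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| kernel | gaussian | — | unbounded support keeps local designs nonsingular in sparse age regions; epanechnikov selectable |
| age bandwidth | $1.06\,\mathrm{sd}(T)\,n^{-1/5}$ | years | normal-reference rule; reproducible without tuning |
| score bandwidth | $1.06\,\mathrm{sd}(Z)\,n^{-1/5}$ | score units | same rule, per dimension of the product kernel |
| mean-smoother bandwidth | same rule; optional LOO CV | years | CV uses the linear-smoother shortcut (no refit loop) |
| thresholds | 0.60–0.90 by 0.05 | correlation | lower bound enforces sparsity, upper avoids fragmentation |
| evaluation ages | 1–9 | years | one year inside the observed range, limiting boundary effects |
| length rule | `"weight"` | — | path length is the sum of correlation weights along the path, the literal reading of the definition above; the common `"inverse"` convention (stronger edge = shorter) is selectable and recorded in outputs |
| Q | 5000 (full), a few hundred for exploration | permutations | p-value resolution 1/Q |
| p-value | $\#\{T^{(q)} \ge T\}/Q$ | — | plain proportion; `add_one` switches to $(\#+1)/(Q+1)$ |

For grouped analyses the bandwidth combines the *pooled* age spread with
the group's own sample size, $h_k = 1.06\,\mathrm{sd}(T)\,n_k^{-1/5}$.
Group sizes are preserved by the permutation scheme, so bandwidths are
identical across permutations and the statistic compares like with like.

## Community detection

Modularity needs a partition.  Networks with at most 8 nodes are solved
*exactly* by enumerating all set partitions (Bell(8) = 4140, evaluated
via cached same-module pair lists), which makes the reported modularity
deterministic and free of heuristic error.  Larger networks use a seeded
multilevel (Louvain-style) local-moving + aggregation heuristic with 5
restarts, keeping the best modularity; the seed is derived
deterministically from the analysis seed and the cell coordinates, so
results are reproducible and invariant to evaluation order.  The test
suite cross-checks both paths against an independent exhaustive oracle
and against igraph.

## Numerical choices and degenerate inputs

* PSD projection clips eigenvalues at exactly 0 (no jitter).  If
  clipping leaves a zero variance on the diagonal, the correlation step
  refuses with an error naming the ROI — the symptom of oversmoothing or
  a constant ROI, not something to silently patch.
* The local-design floor for $\hat\sigma_0^2$ (and the bivariate Schur
  complement) is $10^{-12}$; below it the weights error and advise a
  larger bandwidth.  Inside the permutation engine such cells mark the
  whole permutation as failed; failed permutations are discarded and
  counted, never silently dropped.
* Correlations within $10^{-8}$ of $\pm 1$ are clipped to the bound; the
  diagonal is set to exactly 1.
* An edgeless network (all correlations below $\theta$) has $Q = 0$ and
  $E = 0$ by definition, with a warning in interactive use; the
  threshold bounds were chosen to make this rare.
* Threshold averaging sums the grid values sequentially (not via
  `mean()`), so the R route and the compiled permutation engine agree
  bitwise; the observed run of a permutation test is byte-identical to
  computing the measure curves directly.

## The synthetic cohort generator

`synthetic_config()` + `generate_cohort()` emulate an accelerated
longitudinal community cohort: 554 children by default, visit counts
drawn from an empirical 1–8 visit distribution (most children once),
ages uniform on 0.17–10 years, sex ratio 309/554 male, 62% of mothers
with a bachelor's degree (ordinal education levels 6–7 vs 1–5), and an
ELC-like cognitive score distributed Normal(100, 15²).  Volumes follow
saturating-exponential growth curves, $v_j(t) = a_j(1 - 0.7 e^{-0.7t})$
(about 80% of the adult level by age 2, about 30% at birth), with a 12%
coefficient of variation and a two-block correlation structure
("non-cortical" block = first 30% of ROIs) whose within-block
correlation rises with age, is higher under high maternal education
(+0.10), and falls with the score (−0.10 per SD) — the directions the
grouped-modularity and score-efficiency analyses are designed to
detect.  An optional divergence term lets one group's coordination
accelerate after a given age (used for power experiments), and an
optional child-level log-normal volume factor introduces within-child
dependence to probe the i.i.d.-visits assumption.  Positive definiteness
of the implied correlation is verified on a dense age grid at
construction, with the failing age named.

What the generator does **not** emulate: scanner and segmentation error,
site effects, realistic ROI-specific covariance geometry (two
exchangeable blocks instead of 91 anatomically distinct regions),
non-uniform age sampling (enrollment waves), or attrition.  Passing
tests therefore demonstrate that the estimator and tests recover *known*
covariate-dependent correlation dynamics under realistic design
sparsity — not that any particular real cohort satisfies the model.

## What the tests compute

The suite validates each stage against independent oracles: the weight
formulas against direct transcriptions, the closed-form Fréchet estimate
against a projected-gradient minimizer of the weighted Frobenius
objective, modularity/efficiency against exhaustive-partition and
Floyd–Warshall oracles and igraph, and the full pipeline against
committed golden outputs (bitwise, fixed seed).  Statistical behaviour
is checked on generated cohorts: correlation recovery error decreases
from 300 to 3000 visits (20 replicates, ages 2/5/8, m = 10); the group
permutation test's type-I error at the 0.05 level sits inside the exact
binomial 95% band over 200 replicate null cohorts (m = 6, 400 visits,
Q = 200); power against a post-age-5 divergence in one group exceeds the
null rate; and on a 91-ROI cohort with score-decreasing coordination the
global-efficiency curves at scores 80/100/120 are strictly ordered at
ages 7–9.  Problem sizes (m = 6–10 for replicated experiments, m = 91
for the single full-scale run, Q = 200 instead of 5000) are chosen so
the whole suite runs in minutes on one core while keeping every
statistical conclusion at its stated confidence; `scripts/acceptance.R`
recomputes the same quantities from scratch.

## Known limitations

* The Frobenius metric can produce rank-deficient estimates after
  clipping; near the age boundary with small effective sample size,
  thresholded measures acquire an upward noise bias (variance of
  $\hat R$ pushes entries over $\theta$).  Evaluation at ages 1–9 within
  a 0.17–10 design mitigates this; estimates at the extreme ages of the
  design should not be over-interpreted.
* Repeated visits of a child violate independence; the visit-permutation
  null is then only approximately exchangeable.  The child-level
  permutation unit is provided, but the default follows the method's
  stated procedure.
* The multilevel heuristic does not guarantee maximum modularity for
  m > 8; reported modularity is the best found over seeded restarts.
* p-values are not adjusted across evaluation ages: each age's test
  already concerns the whole trajectory from that age onward, and the
  per-age statistics are strongly dependent by construction.

## A worked sketch

```{r example}
library(dynscn)

cfg <- synthetic_config(n_children = 554, m_rois = 20, seed = 1)
cohort <- generate_cohort(cfg)

fit <- frechet_scn(cohort, group = "sex_mated")
summary(fit)
R5 <- predict(fit, ages = 5, groups = "F_high")      # correlation at age 5
A5 <- threshold_network(R5, 0.8)                      # SCN at theta = 0.8
plot(fit, measure = "modularity", ages = 1:9)

pt <- permutation_test_groups(cohort, measure = "modularity",
                              ages = 1:9, Q = 500, seed = 1)
print(pt)

fe <- frechet_scn(cohort, elc = "elc")
eff <- scn_measure_curves(fe, "global_efficiency", ages = 1:9,
                          scores = c(80, 100, 120))
```
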