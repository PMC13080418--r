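---
title: "Comparing inventories as measures of a general factor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing inventories as measures of a general factor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`geninfo` answers a practical psychometric question: when a clinic
administers several ordinal symptom inventories to the same patients,
which inventory measures the *shared general factor* — interpretable as
general internalizing pathology in a psychotherapy population — most
efficiently, in total and per item? This vignette documents the model,
the estimation choices, what the synthetic registry emulates, and the
known limitations.

## The measurement model

Each ordinal item $j$ with $K_j$ categories is assumed to discretize a
latent standard-normal response
$y_j^\* = \lambda_j^\top \theta + \varepsilon_j$, where $\theta$ holds one
general factor and $k-1$ specific (content) factors with correlation
matrix $\Phi$, $\varepsilon_j \sim N(0, \psi_j)$ with
$\psi_j = 1 - \lambda_j^\top \Phi \lambda_j$, and the observed category is
the number of thresholds $\tau_{jc}$ below $y_j^\*$. This is the
multidimensional normal-ogive graded response model, and it is exactly the
model implied by a factor analysis of the polychoric correlation matrix —
which is why all information statistics here are computed on the ogive
metric, where the chain from polychorics to item response curves is
internally consistent.

### Stage 1–2: dimensionality

The polychoric matrix is estimated two-step (thresholds from the marginal
cumulative proportions; each pairwise correlation by Brent maximization of
the bivariate-normal rectangle likelihood on pairwise-complete rows,
tolerance $10^{-8}$, $|\rho| \le 0.999$). The bivariate normal CDF uses
Sheppard's arcsine-integral form under a fixed 48-node Gauss–Legendre
rule, accurate to about $10^{-13}$ across the admissible range, including
$|\rho| = 0.999$. Items whose top category has fewer than `min_count = 3`
observations are merged downward first — the rule a data manager would
apply to a rarely endorsed "most or all of the time" response on an
aggression item.

The share of variance–covariance carried by the first principal component
gauges how dominant a general factor would be. The number of factors is
chosen by Horn's parallel analysis against nulls built by independently
permuting each item's column, which preserves the ordinal marginals
exactly; the criterion compares each leading observed eigenvalue to the
null mean (default) or 95th percentile, stopping at the first failure,
with `n_random = 100` permutations. Both stages run on pretreatment
scores and on post-minus-pre change scores; change scores take up to
$2K-1$ levels and are treated as numeric, so their correlation matrix and
parallel-analysis nulls are Pearson-based. The mean-criterion and
permutation-null defaults are conventions — the retention literature
offers several variants, and both criteria are exposed.

### Stage 3: bifactor EFA

Factors are extracted by minimum residual (least-squares on the
off-diagonals; uniquenesses optimized by L-BFGS-B, communalities clipped
at 0.995 with a Heywood flag) and rotated by **bi-geomin**: the geomin
complexity $\sum_i \big(\prod_{j \ge 2} (\lambda_{ij}^2 +
\epsilon)\big)^{1/(k-1)}$ is applied to columns $2..k$ while column 1 —
the general factor — is unpenalized. Rotation uses the standard oblique
gradient-projection algorithm with 30 random starts (plus the identity)
under a fixed seed; oblique rotation is the default, $\epsilon = 0.01$.
The general column is then aligned: the column with the most loadings at
or above 0.20 in magnitude moves to position 1 and is sign-flipped
positive. The 0.20 cut-off for "loads on the general factor" is a
reporting convention, not an estimate.

Two cautions from this implementation's own testing are worth recording.
First, the geomin criterion with small $\epsilon$ can genuinely prefer a
degenerate solution when specific blocks are perfectly homogeneous (equal
loadings); heterogeneous loadings — the realistic case — break the tie.
Second, gradient projection on this criterion converges slowly near the
optimum; the iteration cap is 5000 with tolerance $10^{-6}$ on the
projected-gradient norm.

A stability screen mirrors the handling of items with extreme, unstable
estimates: items at the Heywood clip or with rotated loadings beyond 1.5
in magnitude are listed and the model refit without them.

### Stage 4: marginalization

A specific factor contaminates any naive use of the conditional item
parameters: an anxiety item's discrimination reflects both general and
anxiety-specific variance. With the nuisance factors conditionally normal
given the general factor $t$ (mean $\Phi_{21} t$, covariance
$\Phi_{22} - \Phi_{21}\Phi_{12}$), integrating the conditional ogive over
them is available in closed form:

$$P(X \ge c \mid t) = \Phi\!\left(\frac{\alpha t - \tau_c}{\sigma}\right),
\qquad \alpha = \lambda_g + \lambda_s^\top \Phi_{21}, \qquad
\sigma^2 = \psi + \lambda_s^\top(\Phi_{22} - \Phi_{21}\Phi_{12})\lambda_s,$$

so the marginal model is a unidimensional graded response model with
$a^\* = \alpha/\sigma$ and $b^\*_c = \tau_c/\alpha$. The projection is
exact on the ogive metric — the tests verify it against independent
Gauss–Hermite integration to $10^{-14}$ — and approximate on the logistic
metric, which is why the logistic conversion (scaling constant
$D = 1.702$) is reporting-only. Marginal discrimination never exceeds the
conditional one when specific loadings are orthogonal, often shrinking it
substantially; skipping this step would systematically overstate every
contaminated item's information about the general factor.

### Stage 5: Fisher information

Point item information is
$I_j(\theta) = \sum_c (\partial \pi_{jc}/\partial\theta)^2 / \pi_{jc}$;
test information sums over an inventory's items; total information is the
area under the curve, by 101-node Gauss–Legendre quadrature over
$[-6, 6]$. The integration range is a choice: $\pm 6$ covers the
clinically discussed $[-2, 2]$ midrange with wide margin, and totals for
well-located items change by under 0.5% when widening to $\pm 8$ (a
tested invariant); both bounds and node count are arguments. Averaged
total information divides by inventory length; StdEM is
$1/\sqrt{I(\theta)}$; curves are reported on a 201-point grid over
$[-4, 4]$, the inner ~95% of a standard-normal trait. In the far tails
category probabilities are computed from survival functions to avoid
cancellation, with a $10^{-300}$ floor as the final guard.

### Bootstrap

Confidence intervals are nonparametric percentile intervals over person
resamples (default $B = 1000$), re-running the whole chain per resample
with the factor count fixed at the point estimate's $k$ — re-running
retention per resample would conflate model-selection and sampling
variability. Rotational indeterminacy is handled by matching each
resample's columns to the point estimate's general loadings by maximal
absolute Tucker congruence with sign correction; without this, percentile
intervals on information statistics would be meaningless. Resample fits
use 5 random rotation starts by default (the point estimate keeps 30) — a
robustness/cost trade-off, configurable. A statistic is flagged as skewed
when its point estimate leaves the central third of its interval, the
usual symptom of bifactor instability.

## The synthetic registry

Real psychotherapy-registry data are legally non-distributable, so the
package generates a registry-like cohort from a known model and treats
the model as ground truth. The frozen generating model
(`registry_true_model()`, drawn once from fixed ranges under an internal
build seed) encodes the study conditions:

* 51 unique items — CORE-OM 34 (0–4; 10 flagged as the embedded CORE-10),
  PHQ-9 9 (0–3), OASIS 5 (0–4), AUDIT-C 3 (0–4);
* one general factor with loadings in $[0.4, 0.85]$ on loading items, and
  **zero** general loading on the three AUDIT-C items and the two
  CORE-OM aggression items, so the general factor is internalizing
  rather than a p-style factor;
* eight content-specific factors (anxiety — loaded strongly by OASIS —
  alcohol, risk, mood, somatic, functioning, social, wellbeing), factors
  mutually uncorrelated;
* thresholds emulating a distressed pretreatment population, with risk
  and alcohol items rarely endorsed and a deliberately sparse top
  category on CORE-OM 22 to exercise the truncation rule;
* $n_{\text{pre}} = 5223$ by default with completion rate 0.593 at
  posttreatment, where the general factor shifts down by 0.8 SD (a
  typical pre/post psychotherapy effect size) and latent scores carry a
  0.5 autocorrelation so change scores retain a factor structure;
  item-level missingness is completely at random, default 0, because
  missing posttreatment data in such registries arise mainly from
  treatments still running, not from symptom levels.

One generator design choice deserves emphasis. Specific-factor loadings
alternate in sign within content blocks (bipolar specifics, as when a
block mixes straight- and reverse-worded items). With uniformly positive
specific loadings, the general column of the loading matrix is almost a
linear combination of the specific columns, the implied correlation
matrix has only $k-1$ eigenvalues above any permutation-null baseline,
and parallel analysis *cannot* recover the generating factor count — the
well-known under-extraction on bifactor data. The bipolar design was
fixed from population-level eigenvalues of candidate models (no data
involved) and makes all nine structural eigenvalues cleanly detectable at
registry scale.

What passing the recovery tests shows — and what it does not. At
$n = 5000$ the pipeline recovers general loadings with RMSE under 0.05,
flags exactly the designed zero-general items as non-loading, and
reproduces per-inventory total information within 10% of the true values
obtained by marginalizing the generating parameters directly. That
validates the machinery under a correctly specified model with MCAR
missingness and no response styles, local dependence, or informative
dropout; it does not certify behaviour on real data, where none of those
idealizations hold exactly.

## Numerical choices and degenerate inputs

* Polychoric pairs with a degenerate table return a bounded, flagged
  estimate; a non-positive-semidefinite pairwise matrix is repaired by
  clipping eigenvalues at $10^{-6}$ and rescaling to unit diagonal
  (`smoothed = TRUE`).
* Items collapsing to a single category (possible in bootstrap
  resamples) are carried with zero correlations and logged rather than
  aborting the resample.
* A zero marginal slope with non-trivial thresholds yields $a^\* = 0$
  with undefined locations and a flag; a negative marginal slope is
  reverse-coded so $a^\* \ge 0$, recorded in `reversed`.
* Ties in the general-column alignment break by the larger sum of
  squared loadings, with a warning.

## Problem sizes used in the shipped checks

The test suite and the acceptance script validate at the scales the
methods are meant for while staying desk-runnable: full recovery at
$n = 5000$ with all 51 items (parallel analysis with 100 polychoric
permutation nulls is the dominant cost), a shared medium cohort at
$n = 1500$ for structural checks, consistency oracles at $n = 20{,}000$
for single pairs, and a reduced bootstrap ($n = 500$, 20 items,
$B = 100$). The acceptance script's sensitivity re-run keeps the main
run's factor count, as a re-fit at known $k$, and therefore skips the
retention stage.

## Limitations

* Exploratory bi-geomin with a small $\epsilon$ has known local-minimum
  and degeneracy risks; 30 seeded starts mitigate but cannot guarantee a
  global optimum.
* The marginalization is exact only under the normal-ogive/conditionally
  normal model; with a logistic link it would be approximate.
* Percentile bootstrap intervals inherit bifactor instability; the
  skewness flag marks, but does not repair, such cases.
* No measurement-invariance testing across waves is included; the
  change-score stages address only the dimensionality question.
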