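# geninfo

Compare ordinal self-report symptom inventories as measures of a single
**general latent factor**, using marginal item response theory.

Routine outcome monitoring in psychological therapies increasingly relies
on a broadband "general internalizing pathology" construct rather than
disorder-specific scores. When several inventories (here: the 34-item
CORE-OM with its embedded 10-item CORE-10, the PHQ-9, the OASIS and the
AUDIT-C) are administered to the same patients, a natural question is which
of them measures the shared general factor most efficiently — overall and
per item. `geninfo` implements the full *isolate-and-analyse* workflow for
that question:

1. **Polychoric correlation** of the pooled ordinal items
   (pairwise-complete, two-step maximum likelihood, sparse top categories
   merged when fewer than 3 responses are observed).
2. **Dimensionality**: share of variance–covariance explained by the first
   principal component, and Horn's parallel analysis against
   column-permutation nulls — on pretreatment scores and on
   post-minus-pre change scores.
3. **Exploratory bifactor analysis**: minimum-residual extraction followed
   by **bi-geomin** rotation (geomin complexity on the specific columns,
   the general column unpenalized; gradient projection with random
   starts), general-factor alignment and a stability screen for items with
   extreme estimates.
4. **Marginalization**: each item's multidimensional normal-ogive graded
   response model is projected onto the general factor alone. With the
   nuisance factors conditionally normal given the general factor *t*, the
   marginal is again a normal ogive,
   P(X ≥ c | t) = Φ((αt − τ_c)/σ) with α = λ_g + λ_sᵀΦ₂₁ and
   σ² = ψ + λ_sᵀ(Φ₂₂ − Φ₂₁Φ₁₂)λ_s, giving marginal discrimination
   a\* = α/σ and boundary locations b\*_c = τ_c/α. The projection is exact
   on the ogive metric.
5. **Fisher information**: point item/test information
   I(θ) = Σ_c (∂π_c/∂θ)²/π_c, total information as the area under the
   information curve, length-averaged totals (total / number of items),
   standard error of measurement 1/√I(θ), and nonparametric bootstrap
   percentile confidence intervals with congruence-based factor alignment
   across resamples.

Because real psychotherapy-registry data cannot be redistributed, the
package ships a **synthetic registry generator** (`default_registry_spec()`,
`sample_responses()`) that emulates the study conditions — 51 unique items
across the four inventories, ~5000 pretreatment respondents with ~59%
posttreatment completion, one dominant general factor plus eight content
factors, alcohol and aggression items with zero general loading — and
exposes the true parameters so every stage can be validated against known
ground truth.

## Worked example

```r
library(geninfo)

spec <- default_registry_spec()          # 51 items + frozen true model
coh  <- sample_responses(spec$model, spec$items, n_pre = 2000, seed = 5)

fit <- fit_bifactor(coh$pre, k = 9, items = spec$items, seed = 1)
general_factor_covariance_share(fit)
#> [1] 58.54891

mg   <- marginalize(fa_to_mgrm(fit, fit$polychoric))
prof <- information_profile(mg, spec$items)
comparison_table(prof)
#> # A tibble: 5 × 7
#>    rank inventory n_items     total averaged comparison diff_averaged
#>   <int> <chr>       <int>     <dbl>    <dbl> <chr>              <dbl>
#> 1     1 CORE_OM        34 146.      4.28     <NA>              NA
#> 2     2 CORE_10        10  40.7     4.07     1. vs. 2.          0.210
#> 3     3 PHQ9            9  30.4     3.38     2. vs. 3.          0.692
#> 4     4 OASIS           5  15.3     3.06     3. vs. 4.          0.320
#> 5     5 AUDIT_C         3   0.00184 0.000614 4. vs. 5.          3.06
```

Reading the table: `total` is the area under each inventory's test
information curve for the general factor over θ ∈ [−6, 6]; `averaged`
divides by inventory length, so rank 1 is the most informative measure *per
item*; `diff_averaged` is the drop between adjacent ranks. The AUDIT-C row
is essentially zero because its items do not load the general factor — its
apparent information would be an artefact of the alcohol-specific factor,
which the marginalization removes. Against ground truth
(`true_marginal_information(spec$model, "CORE_OM")` = 147.7 here), the
estimates above are within ~2.5% at n = 2000.

The one-call pipeline, with parallel analysis choosing the factor count and
a posttreatment wave enabling the change-score stage:

```r
run <- run_pipeline(coh$pre, spec$items, post = coh$post,
                    n_factors = "auto", seed = 1, out_dir = "results/run1")
bs  <- bootstrap_pipeline(coh$pre, spec$items, k = run$k, B = 1000, seed = 1)
sens <- core10_sensitivity(coh$pre, spec$items, k = run$k, run_parallel = FALSE)
```

`tidy()`, `glance()` and `autoplot()` methods cover the fitted objects
(scree and parallel-analysis plots, loading heatmaps, information and
StdEM curves).

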