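# basinrates

Why do some regions accumulate rapidly speciating species? In continental
faunas — freshwater fishes along the Andes–Amazon gradient are the
textbook case — assemblages at high elevation are dominated by young
lineages that both speciate and evolve their morphology (especially body
size) unusually fast. `basinrates` implements the complete analysis chain
for quantifying this pattern at the level of drainage-basin assemblages,
together with a fully seeded synthetic data generator with known causal
structure, so that every stage can be validated against closed forms and
brute-force oracles.

The package is aimed at macroevolution / macroecology researchers who
want a tested, scriptable version of this analysis surface:

* **Tip speciation rates.** The equal-splits statistic
  $\mathrm{ES}_i = \sum_j l_j 2^{-(j-1)}$ (pendant edge first, halving
  rootward) and its inverse, the DR statistic; a node-density estimator
  (splits on the root-to-tip path over tip depth) for cross-method
  concordance. Polytomies count as $k-1$ simultaneous splits.
* **Trait evolution.** log10 body-size transform; per-tip Brownian
  rate proxies (squared standardized terminal contrasts); univariate
  Brownian imputation of missing trait values (GLS root state,
  conditional-normal means, reported conditional SDs); the Fritz–Purvis
  $D$ statistic for phylogenetic clustering of missingness.
* **Assemblages.** Basin summaries (mean/median/min/max, optional
  inverse range-size weights), richness and species density
  $SD = SR/A^z$, Shannon soil diversity, richness filters and
  taxon/basin exclusions with provenance logs.
* **Inference.** z-score standardization (sample SD; log10 area),
  iterative VIF screening (threshold 5), standardized OLS with t-based
  95% CIs, lmg hierarchical partitioning of $R^2$ (weighted subset
  enumeration, brute-force-verified), commonality analysis over the four
  predictor groups (morphological evolution, diversity-dependence,
  climate, habitat), Moran's $I$ on residuals (knn weights, permutation
  p), and coordinate correlations.
* **Synthetic data.** Birth–death trees with Poisson rate-shift regimes
  (recent-burst dynamics), regime-linked Brownian body-size evolution,
  elevation-structured landscapes, and clade-cohesive occupancy, all
  deterministic under a seed, with truth tables for recovery tests.

## Worked example

```r
library(basinrates)

cfg  <- sim_config(seed = 1)           # the default study conditions
data <- simulate_dataset(cfg)          # tree + traits + landscape + truth
rep  <- analyze_dataset(data, analysis_options(), seed = 1)

length(data$tree$tip.label)            # extant species in the clade
#> [1] 686
nrow(rep$basin_summary)                # basins surviving the filter
#> [1] 120
round(rep$ols$r_squared, 3)            # variance explained
#> [1] 0.916
round(sort(rep$lmg$pct_of_r2, decreasing = TRUE), 1)[1:4]
#>  rate_body_size       elevation              sr stream_gradient
#>            41.4            33.9            14.6             5.0
round(unlist(rep$moran[c("i", "expectation", "p_value")]), 4)
#>           i expectation     p_value
#>      0.2574     -0.0084      0.0010
```

Read: the body-size evolution-rate summary of each basin carries the
largest share of the explained variance in basin mean DR (41.4% of
$R^2$), with elevation the strongest abiotic predictor (33.9%). On
these synthetic data that ordering reflects the generative model:
elevation drives the speciation regimes and (through the
$\sigma^2 \propto \lambda$ link) body-size evolution, and burst clades
anchor at high elevation. Moran's $I$ flags positive residual spatial
autocorrelation — a real feature of the data, since burst clades occupy
contiguous basins — which is exactly what the diagnostic is for. The
winner ordering varies across seeds (burst-anchor placement is random);
`scripts/acceptance.R` reports how often each element of the structure
is recovered over 50 seeded replicates.

The numbered scripts under `analysis/` run the same chain as a
step-by-step narrative (simulate, tip rates, traits/imputation,
assemble + fit, sensitivity scenarios) and write their tables under
`results/`.

## Package layout

```
R/                  implementation (tree I/O, simulator, tip rates,
                    traits, assemblage, inference, spatial, pipeline)
analysis/           numbered narrative drivers over the package API
scripts/acceptance.R   headline-quantity recomputation
tests/testthat/     unit, property and acceptance suites with
                    independent oracles
vignettes/          the methods vignette (model, assumptions, design)
```
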