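# greengov

Quantitative tooling for urban green-space governance research: how much
green space do cities have, what does it do to residents' health, how
strong and coherent are the policies behind it, and how fairly is access
to it shared?

The package is aimed at spatial epidemiologists and urban-policy analysts
working with city-by-year panels, reflectance rasters and coded legal
texts. Because the multi-city studies in this literature rarely deposit
their data, `greengov` pairs every estimator with a synthetic-data
generator that plants known effect sizes, so the whole pipeline is
testable end to end by parameter recovery.

## What it computes

* **Green-space extraction** — NDVI `(NIR − Red)/(NIR + Red)` from paired
  reflectance grids (ESRI ASCII format), coverage, mean NDVI, 4-connected
  patch areas and the fragmentation index `1 − Σaₖ²/A²`.
* **Spatial autocorrelation** — Moran's I
  `I = n/S₀ · Σᵢⱼ wᵢⱼ zᵢ zⱼ / Σᵢ zᵢ²` with two-sided permutation
  inference over knn / inverse-distance / contiguity weights.
* **Panel models** —
  fixed-effects (within) estimation of `Y_it = αᵢ + β₁G_it + β₂X_it + ε_it`
  with cluster-robust errors and VIF screening;
  Hansen-style single-threshold regression
  `Y_it = αᵢ + b₁G_it + b₂ max(G_it − γ, 0) + …` with SSR grid search,
  residual-bootstrap existence test and LR confidence set — the slope
  ratio `(b₁+b₂)/b₁` is the "acceleration factor" past the threshold;
  exact linear-programming quantile regression (vertex solutions of the
  check-loss LP) for quantile-varying health effects.
* **Spatial Durbin model** — `y = ρWy + Xβ + WXθ + ε` by concentrated
  maximum likelihood, with the LeSage–Pace average-effects decomposition
  `S_k(W) = (I − ρW)⁻¹(Iβ_k + Wθ_k)` into direct, indirect (spillover)
  and total effects, `direct + indirect = total` by construction.
* **Policy scoring** — PSI `Σ(score × weight)` over clause mandatoriness /
  penalty severity / public participation (weights 0.40/0.30/0.30, raw 1–5
  and ×20 scaled), and the keyword co-occurrence network PCI
  `100(0.6·density + 0.4·clustering)`.
* **Accessibility equity** — exact Euclidean distance-to-green on
  population grids, population-weighted Lorenz curve and Gini coefficient,
  and between-group distance ratios / coverage gaps.
* **Synthetic data** — generators for panels, rasters, policy corpora,
  equity grids and spatial-lag fields, each returning a `truth` record of
  every planted parameter.

See `vignettes/greengov-methods.Rmd` for the models, conventions and
design decisions in detail.

## Worked example

Generate a synthetic 30-city × 14-year panel with the default planted
values (coverage threshold 0.38, slope acceleration 3.3×, 9.7%
above-threshold mental-health improvement), then recover them:

```r
library(greengov)

bundle <- gen_panel(panel_gen_config(seed = 42))
bundle
#> Synthetic panel bundle: 30 cities x 14 years (seed 42)
#>   planted: threshold 0.38, slope ratio 3.30, MH improvement 9.7%

controls <- c("pop_density_growth", "env_fiscal_share", "realestate_inv", "pm25")
fit_threshold(bundle$panel, "chronic_rate", "coverage", controls,
              n_boot = 199, seed = 1)
#> Single-threshold panel fit
#>   threshold gamma = 0.3822  (95% LR set [0.3585, 0.4105])
#>   slope below = -1.0529, above = -3.2120 (ratio 3.05)
#>   bootstrap p (no-threshold null) = 0.0050
```

The estimated kink sits at 38.2% coverage; past it the disease-decline
slope steepens about 3-fold, and the bootstrap rejects the no-threshold
null. A single panel is noisy — medians over 200 replicate panels (what
`scripts/acceptance.R` computes) land on the planted 38 / 3.3 / 9.7.

Spatial spillovers on a simulated spatial-lag field:

```r
field <- gen_sdm_field(n = 400, rho = 0.49, seed = 7)
fit_sdm(field$y, field$X, field$weights, n_draws = 500, seed = 1)
#> Spatial Durbin model: n = 400, rho = 0.5148, sigma2 = 1.034
#>   loglik = -587.77, AIC = 1189.55
#> Effects decomposition:
#>   regressor  direct indirect   total se_direct se_indirect se_total
#> 1        x1 -0.6350  -0.9200 -1.5550   0.05961      0.2315   0.2642
#> 2        x2  0.2418   0.4206  0.6624   0.06451      0.2557   0.2972
```

The spatial lag (planted 0.49) is recovered at 0.51, and each row's
direct and indirect effects sum exactly to its total.

Policy strength and coherence of a generated "strong" corpus:

```r
docs <- gen_policy_corpus("strong", seed = 1)
score_psi(docs)
#> Policy Strength Index
#> mandatoriness       penalty participation
#>         4.667         4.417         4.417
#>   PSI raw = 4.517 (1-5 scale), scaled = 90.3 (0-100)
build_cooccurrence(docs, lexicon = readLines(system.file(
  "extdata", "policy_lexicon.txt", package = "greengov")))
#> Keyword co-occurrence network: 12 terms, density 0.864, clustering 0.867
#>   top degree term: ecological restoration; PCI = 86.5
```

Accessibility equity on a gridded city with people clustered away from
the green edge:

```r
g <- gen_equity_grid(40, 40, "clustered", "edge", seed = 1)
gini_lorenz(accessibility(g), g$population)
#> Accessibility equity: Gini = 0.3013, mean distance = 3887.0 m
group_gaps(g, "far", "near")
#> $group_ratio    [1] 2.213757
#> $coverage_gap_pct   [1] -23.26454
```

The "far" group travels 2.2× farther to green space on average and has 23
percentage points less green coverage — the planted inequity.

`run_pipeline(list(seed = 42))` chains all stages (simulate → raster →
spatial → panel → SDM → policy → equity) from one config and returns a
consolidated report.

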