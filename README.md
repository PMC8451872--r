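# deercomp

Inference tools for interspecific competition between sympatric deer —
roe deer (*Capreolus capreolus*, a concentrate selector) and fallow deer
(*Dama dama*, an intermediate feeder and frequent superior competitor) —
from annual pellet-group count surveys on a habitat-stratified plot grid,
plus a daily weather record. The package is aimed at wildlife ecologists
running (or re-analysing) multi-year sign-survey studies who need the full
chain from raw plot counts to selected models, reproducibly and with every
stage testable against simulated ground truth.

## What it computes

**Densities.** The fecal accumulation rate method: plots are cleared, then
re-counted after ~35–40 days, and density follows from

```
D = count / (plot_area_km2 × interval_days × defecation_rate)
```

averaged over plots (optionally area-weighted within habitat strata), with
a seeded percentile bootstrap (B = 1000) for SEs, 95% CIs, and
inverse-CI-width precision weights. Default defecation rates: 20 (roe) and
25 (fallow) pellet groups/day.

**Spatial overlap.** Per habitat × year, the Pianka niche-overlap index

```
P = Σ O_iF·O_iR / sqrt(Σ O_iF² · Σ O_iR²)
```

on the species' per-plot use proportions, and the shared-space proportion
n_FR / n_R (fraction of roe-used plots also used by fallow deer).

**Models.** A from-first-principles fitting engine restricted to the four
family–link pairs the analyses need: weighted Gaussian (identity),
binomial (logit), negative binomial NB2 (log) and Beta (logit), the middle
two also with crossed random intercepts via the Laplace approximation
(penalised Newton over the random effects + curvature correction;
deterministic starts, bit-reproducible fits; agrees with lme4/glmmTMB to
~3 decimals on shared data). Model selection fits every
marginality-respecting subset of a global model plus the null, ranks by
AICc, applies the nesting rule (retain only models within ΔAICc ≤ 2 of the
best *and* strictly better than every simpler nested candidate), and
reports standardized Akaike weights, after a Pearson collinearity screen
(|r| ≥ 0.5 blocks the run unless overridden).

**Three pipelines.** `run_density_analysis()` (roe density in year t vs
fallow density in years t and t−1, roe in t−1, growing-season rainfall in
t−1; weighted Gaussian), `run_occupancy_analysis()` (roe presence and
abundance at plots vs habitat × local fallow abundance with plot and year
random intercepts, plus per-habitat arid/non-arid models), and
`run_overlap_analysis()` (Beta models of both overlap indices vs habitat,
rainfall, and pellet sums). `run_pipeline()` orchestrates everything from
a single config and writes a markdown + JSON report.

**Synthetic data.** `simulate_dataset()` generates the whole study design
— 258 five-metre plots over six habitats, 11 annual surveys, negative
binomial counts with plot/year random effects, a lagged competitor effect
on roe density and plot-level suppression of roe by fallow — with known
truth, so every estimator above is validated by parameter recovery. See
`vignettes/deercomp-methods.Rmd` for the models, defaults and their
rationale.

## Worked example

Simulate the default 11-year study (with the second year unsurveyed, as a
gap-handling exercise), estimate densities, and run the density model
selection:

```r
library(deercomp)

cfg <- run_config(
  simulation = list(truth = simulation_truth(), years = 11L),
  bootstrap_reps = 1000L, missing_years = 2008L,
  collinearity_override = TRUE, seed = 3L)
res <- run_density_analysis(cfg)

head(res$density_table[res$density_table$species == "roe",
                       c("year", "density", "se", "ci_low", "ci_high")], 4)
#>  year  density        se   ci_low  ci_high
#>  2007 4.177394 0.7122406 2.792234 5.646683
#>  2009 2.936934 0.5798628 1.872396 4.181034
#>  2010 4.147347 0.6181849 2.948619 5.460350
#>  2011 6.731497 1.1315261 4.621229 9.073586

res$selection
#> AICc model selection (16 candidates, 2 retained)
#>                  model k  loglik   aicc delta_aicc retained weight
#>             fallow_tm1 3 -13.367 38.734      0.000     TRUE 0.6629
#>                 (null) 2 -16.843 40.086      1.352     TRUE 0.3371
#>               fallow_t 3 -15.855 43.711      4.977    FALSE     NA
#>               rain_tm1 3 -16.201 44.402      5.667    FALSE     NA
#>  ...

res$best_fit
#> gaussian(identity) fit: roe_t ~ fallow_tm1
#>   n = 8, logLik = -13.367, k = 3, AICc = 38.734
#>   (Intercept)                    12.494  (6.963; 18.024) *
#>   fallow_tm1                     -0.290  (-0.537; -0.044) *
```

Reading the output: each simulated year's roe density (ind/km²) comes with
its bootstrap CI (2008 is absent — the configured gap year); the AICc
window plus nesting rule retain the lagged-competition model (Akaike
weight 0.66) alongside the null; and its fitted slope −0.290 (95% CI
excluding 0, starred) recovers the generating truth b = −0.326 — the
decline in roe density per additional fallow deer/km² present the year
before. At this design size (8 usable years) such a detection is the
favourable outcome, not the guaranteed one: across replicates the lagged
term tops the ranking in under half of runs, a power fact the methods
vignette quantifies. A single Pianka call, `pianka_index(c(1, 3),
c(2, 2))`, returns `0.8944272`.

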