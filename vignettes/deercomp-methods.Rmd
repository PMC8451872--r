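---
title: "Models and methods behind deercomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deercomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deercomp)
```

# The scientific problem

deercomp studies interspecific competition between two sympatric deer: roe
deer (*Capreolus capreolus*), a concentrate selector dependent on nutritious
forage, and fallow deer (*Dama dama*), an ecologically flexible intermediate
feeder that is frequently the superior competitor. Field signal comes from
annual pellet-group count surveys on a fixed grid of circular plots
stratified over habitat classes, plus a daily weather record. Three linked
analyses are supported:

1. **Study-area density trends** — does roe density track fallow density in
   the previous year (delayed competition), its own past density
   (density dependence), or growing-season rainfall (resource pulse)?
2. **Plot-scale occupancy** — is roe presence/abundance at a plot suppressed
   by local fallow abundance, and does the suppression differ by habitat or
   by arid versus non-arid growing seasons?
3. **Spatial overlap** — do the species share space more when growing-season
   rainfall is low (resource scarcity forcing niche overlap)?

# Density estimation: the fecal accumulation rate method

Each year plots are cleared of pellet groups and re-visited after roughly
35–40 days. For a plot with count $c$, area $A$ (km²), interval $d$ (days)
and a species defecation rate $r$ (pellet groups/day), the plot-level
density is

$$\hat D = \frac{c}{A \, d \, r},$$

and the study-area estimate is the mean over plots (or an
area-fraction-weighted mean of habitat means when stratified). Defaults use
the field-standard rates of 20 (roe) and 25 (fallow) pellet groups per day.
Each plot uses its own interval, since clearing rounds take several days and
intervals genuinely vary between plots.

Uncertainty comes from a percentile bootstrap over plots (within habitat
when stratified), $B = 1000$ resamples under a recorded seed. A bootstrap
was chosen because plot counts are heavily zero-inflated and overdispersed,
so no parametric interval is trustworthy; the percentile interval needs no
distributional assumption. Annual precision weights are the inverse of the
95% interval width (inverse bootstrap variance is available as an option —
the two orderings agree, but width is the more conservative and the more
literal reading of "precision of the annual estimate"). Weights are
rescaled to mean 1 before model fitting so the weighted Gaussian likelihood
— and therefore AICc — stays on a scale comparable across candidate models.

A caveat worth stating: under multiplicative lognormal random effects the
plain mean of per-plot densities estimates $D \cdot E[e^{u}] > D$, so with
plot/year heterogeneity switched on the estimator tracks *relative* rather
than absolute density. That is exactly the use the density model makes of
it, and the simulator applies the same plot and year effects to both
species, so lagged-slope recovery is unaffected. The calibration tests
(unbiasedness within 3%, bootstrap coverage 90–98%) are run with the random
effects off, where absolute recovery is the right target.

# Spatial overlap indices

For each habitat × year, with $O_{iF}$ and $O_{iR}$ the proportions of the
fallow and roe totals found in plot $i$:

$$P = \frac{\sum_i O_{iF} O_{iR}}
           {\sqrt{\sum_i O_{iF}^2 \; \sum_i O_{iR}^2}},$$

the Pianka (1973) symmetric niche-overlap index, bounded in $[0, 1]$ by
Cauchy–Schwarz. The square root in the denominator is part of the standard
formulation and is what makes the bound hold. The second index,
$n_{FR}/n_R$, is the fraction of roe-used plots also used by fallow deer; it
depends only on presence patterns. When a species is entirely absent from a
habitat-year the indices are undefined and recorded as missing — coding
them 0 would conflate "no overlap" with "species absent" — and such records
are excluded from the overlap models. Proportions are computed within the
habitat-year's own plots, and pinewood is excluded throughout because roe
deer never occur there.

# Weather covariates and aridity

The growing season is March 1 – July 31 (153 days; February never enters
the window, so leap years change nothing). Rainfall is summed and
temperature averaged over that window; gaps up to 5 consecutive days are
tolerated (rain treated as 0 with a warning, temperature linearly
interpolated), larger gaps are an error. Years are classed arid/non-arid by
a De Martonne-type index $R \cdot (12/5) / (T + 10)$ split at the
within-dataset median, ties going to non-arid. The exact drought index
behind the original two-level classification is not fixed by the design;
any monotone rainfall-dominated index produces the same ordering of years,
which is all a two-level factor uses, so the method is pluggable (fixed
threshold and rainfall-only median variants are provided). Temperature is
carried in the index but never enters the regressions, where it would be
collinear with rainfall.

# The model-fitting engine

All models are fitted from first principles, restricted to the four
family–link pairs the analyses need: gaussian–identity (weighted),
binomial–logit, negative binomial–log, Beta–logit.

* **Weighted Gaussian**: closed-form via QR on the square-root-weighted
  design; t-based intervals with $n-p$ degrees of freedom; the reported
  log-likelihood is the weighted Gaussian likelihood at the ML variance.
* **GLMs**: Fisher-scoring IRLS with step halving (the log-likelihood never
  decreases across accepted iterations), dispersion ($\theta$ for NB2,
  $\phi$ for Beta) profiled by univariate likelihood maximisation,
  alternating to joint convergence (relative log-likelihood change
  $< 10^{-10}$, at most 200 alternations). The negative binomial uses the
  quadratic (NB2) parameterisation, variance $\mu + \mu^2/\theta$. Beta
  responses exactly at 0 or 1 (the shared-space proportion is 1 by
  construction in fully co-used habitat-years) are shrunk by
  $(y(n-1) + 0.5)/n$; interior values are untouched, and the shrink is
  optional.
* **GLMMs**: random intercepts only, one or more crossed grouping factors.
  The marginal likelihood uses the Laplace approximation: the joint
  log-density is maximised over the stacked random effects $u$ by a
  penalised Newton iteration on the sparse indicator design
  ($H = Z'WZ + D^{-1}$, dense Cholesky at the modest dimensions involved),
  and the curvature correction $-\tfrac12 \log|H|$ is applied. Estimation
  is two-staged for speed and reproducibility: variance and dispersion
  parameters are first optimised with the fixed effects profiled at the
  joint mode, then all parameters are refined jointly (BFGS with a short
  Nelder–Mead guard) on the full Laplace objective. Starts are
  deterministic — the fixed-effect GLM and variances of 0.1 — so fits are
  bit-reproducible. A variance collapsing below $10^{-6}$ is a boundary
  fit: recorded as 0 and removed from the parameter count. Wald covariance
  comes from the numerical Hessian of the Laplace objective (falling back
  to the conditional information at the mode if that Hessian is not
  usable). On shared datasets the fits agree with lme4 and glmmTMB to
  about three decimals in coefficients and log-likelihood, which the test
  suite checks as an independent cross-validation of the implementation.

Confidence intervals are Wald on the link scale (t for gaussian, normal
otherwise), with a per-coefficient flag for excluding zero. AICc is
$-2\ell + 2k + 2k(k+1)/(n-k-1)$ with $n$ the number of observations for
every family — the common multimodel-inference convention; a grouped
"effective n" for mixed models would change the correction but not the
ranking at these sample sizes — and $k$ counting fixed coefficients,
estimated random-effect variances, and the dispersion where present.

# Model selection

Every admissible subset of the global model's fixed terms is fitted —
marginality respected (an interaction only ever appears with both main
effects), the null model always included, random structure held constant.
Retention uses the AICc window *and* the nesting rule: a model is retained
only if its AICc is within 2 units of the minimum and strictly lower than
that of every strictly simpler candidate nested within it, judged against
all candidates (the stricter reading; comparing only within the Δ ≤ 2 set
is available as an option). "Within 2 units" is read as ΔAICc relative to
the best model, the only scale on which the rule is meaningful. Ties
between nested pairs go to the simpler model. Standardized Akaike weights
are computed within the retained subset. Non-converged candidates are
dropped with a warning rather than failing the run. Before fitting, rows
with missing values in any global-model column are dropped once so all
candidates share one response vector, and covariates are screened by
pairwise Pearson correlation: $|r| \ge 0.5$ blocks the pipeline unless
explicitly overridden (indicators of the same factor are skipped;
zero-variance columns are reported as degenerate, not correlated).

# The synthetic-data generator

The generator exists so every stage can be verified by parameter recovery;
its defaults are the study conditions the package validates against.

* **Landscape**: 258 circular plots of 5 m radius allocated to six habitat
  classes (ecotone 15%, oakwood 23%, scrubland 19%, garigue 16%, open —
  set-aside grassland and crops pooled — 17%, pinewood 10%) proportionally
  to area by largest remainder. The three-way split of the 58% of
  sclerophyllic scrubwood among oakwood/scrubland/garigue is the package's
  own choice; only the total is pinned by the study-area description.
  Habitat preference weights (ecotone and oakwood rich for roe, garigue
  poor, open areas heavily used by fallow, pinewood roe-free) encode a
  qualitative ranking only and are normalised so the area-weighted mean
  weight is 1, keeping study-area density interpretable.
* **Annual dynamics**: fallow density follows a deterministic trajectory —
  a plateau around 20 ind/km², a ~33% decline mid-series, then stable,
  with ±1.7 year-to-year wiggle superimposed (see the plot-count bullet
  for why the wiggle is structural, not decoration). Roe density in year
  $t$ is $a + b\,F_{t-1}$ plus $N(0, \sigma_p)$ truncated at zero,
  defaults $a = 10.341$, $b = -0.326$, $\sigma_p = 1$; these equilibria
  keep roe density well inside the positive range so truncation is rare.
* **Plot counts**: expected count = density × habitat weight × plot area ×
  interval × defecation rate × $e^{u_{plot} + u_{year}}$, the roe
  expectation further multiplied by the avoidance factor
  $e^{s(h) \cdot F_{plot}} / E[e^{s(h) F}]$, where $F_{plot}$ is the
  realised fallow count (local suppression, default $s = -0.35$
  everywhere) and the denominator — the negative-binomial probability
  generating function at $e^s$ — normalises the factor to mean 1.
  Normalisation matters: suppression models roe deer *redistributing*
  activity away from fallow-used plots, not defecating less overall, so
  total roe deposition must stay equal to density × area × interval ×
  rate. Without it, study-area roe deposition would depend on fallow
  density twice — once through the annual equation, once through the
  aggregated plot suppression — and the annual slope $b$ would not be the
  recoverable truth of its own generator. The plot-level log-linear slope
  $s$ is unaffected by the normalisation. Counts are negative-binomial
  with shape 1.5 — the same family fitted downstream, a deliberate
  self-consistency. Plot effects persist across years (log-scale SD 0.68)
  and year effects are shared across plots (SD 0.055); both defaults are
  the square roots of the variance components the package's own abundance
  model structure estimates on field-scale data, giving the crossed
  random-intercept structure the occupancy models assume.
  The fallow trajectory carries deterministic year-to-year wiggle large
  enough that consecutive densities correlate below 0.5, the ceiling the
  predictor collinearity screen enforces; a perfectly smooth
  plateau–decline trajectory would make the lagged and same-year
  densities near-duplicates and model selection could not attribute the
  effect to the correct lag. Pellet decay is not simulated: the clearing
  design makes decay within the interval a second-order effect, folded
  into an optional retention multiplier of 1. Plot coordinates are not
  simulated — plots are exchangeable within habitat, because nothing
  downstream uses spatial position beyond habitat class.
* **Weather**: annual growing-season totals drawn from
  $N(250, 80^2)$ mm truncated at zero and spread over wet days, scaled so
  the seasonal total matches the draw exactly; temperature is a seasonal
  sinusoid around 15.6 °C. The growing-season mean/SD are free
  configuration chosen to span arid and wet Mediterranean years.
* **Overlap records**: the habitat-year Pianka index cannot be given an
  exact logit-linear rainfall slope through plot-level counts — the index
  is a nonlinear functional of two count vectors — so recovery of the
  overlap regression is validated on records drawn directly from the
  generative Beta model, $\mathrm{logit}(\mu) = -0.814 - 0.002 \cdot
  \mathrm{rain}$, precision 30, with per-habitat logits for the shared
  proportion. The survey-derived overlap table remains the default
  analysis path; the generative table is the recovery harness.

What passing recovery tests do *not* show about real data: the generator
has no spatial autocorrelation beyond habitat, no observer error in pellet
identification, no decay-rate variation between habitats, and exact
knowledge of defecation rates. Conclusions about absolute density in the
field inherit those caveats; relative trends are robust to most of them.

# Pipeline conventions

* Reference levels: habitat → ecotone; aridity → arid.
* The density model's annual table loses the first year to the lag, and any
  unsurveyed year removes both lagged pairs straddling the gap (with an
  11-year series and one missing year this leaves 8 usable rows).
* Occupancy models use only plot-years where at least one species was
  detected, the filter applied before the per-habitat split; pinewood is
  dropped. Habitats with fewer than 10 usable plot-years are skipped with a
  warning.
* Best Gaussian models get a Shapiro–Wilk residual normality check.
* Every run is a pure function of (config, seed): bootstrap seeds are
  derived sub-seeds, optimiser starts deterministic, reports byte-stable.

# Power of the density pipeline at the study's design size

A fact worth understanding before reading the replicate tests: with 8
usable annual rows, selecting the lagged-competition model over the null
requires its AICc to beat the null's, and the small-sample correction makes
that a demanding bar — the penalty difference between $k = 3$ and $k = 2$
at $n = 8$ is 5.6 likelihood units, i.e. a t-statistic above roughly 2.46.
The generator's slope truth ($b = -0.326$) is itself an estimate-scale
value; passing it through a fresh survey-measurement layer attenuates the
measured slope to about $-0.27$ (errors-in-variables from the ~9% relative
error of the annual fallow estimates), and the replicate t distribution
centres near 2.4. The consequence, which the acceptance test documents
rather than hides: the lagged term's *sign* is recovered essentially
always (99/100 replicates), the null model wins when the effect is absent
(90/100), but the lagged term tops the AICc ranking in only ~40% of
replicates. Detection of a competition effect of this magnitude at an
8-year design is, in other words, a near coin toss, and a single
favourable realisation clears the bar comfortably — a caution against
over-reading one-off model-selection outcomes at small $n$ that the
simulator makes quantitative.

# Problem sizes used in validation

The packaged tests validate the chain at these scales, chosen to exercise
every code path at full fidelity while keeping the suite quick to run:
density calibration on 200 surveys of the full 258-plot design (bootstrap
coverage on 500); GLMM recovery on 100 replicates of 60 groups × 25
observations; density-pipeline power on 100 replicates of the 11-year
design with one gap year (bootstrap 200 within replicates); overlap
recovery on 200 replicates of 55 habitat-year records; occupancy structure
on a 72-plot, 6-year design. The full 258-plot occupancy models fit in
minutes rather than seconds and produce the same structure.

# Known limitations

* Random slopes, autocorrelated errors, zero-inflated families and
  detection-corrected occupancy are out of scope; "occupancy" here means
  presence/abundance of sign at plots.
* Wald intervals, not profile likelihood; for variance parameters near
  boundaries Wald coverage is approximate.
* AICc model comparison assumes identical response vectors, hence the
  global complete-case rule.
* The Beta overlap models are fitted without random terms by default (a
  year or habitat intercept can be added through the engine, but the
  habitat-year records provide little replication to estimate it).
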