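---
title: "Partitioning spatiotemporal variation in size-dependent fish growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning spatiotemporal variation in size-dependent fish growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavegrowth)
```

## The problem

Growth rate is a key life-history trait, and in fishes it is usually
size-dependent: a 70 mm charr and a 120 mm charr in the same pool do not grow
at the same rate. When many small, effectively isolated populations are
monitored by capture--mark--recapture (CMR) over many years, one can ask how
much of the variation in growth is spatial (among sites, averaged over
years), temporal (among years, averaged over sites), and spatiotemporal (the
site-by-year residual) — and how much of each share acts on all sizes equally
(size-independent, the *intercept* of the growth function) versus
differentially by size (size-dependent, the *slope*), and how much tracks an
environmental covariate such as water temperature.

Two features of real CMR data make this hard. First, most fish are not
caught at most occasions, so individual growth trajectories are riddled with
gaps; dropping incomplete trajectories discards most of the data and biases
the rest. Second, environmental covariates themselves have missing records.
`cavegrowth` addresses both with a Bayesian state-space model in which
unobserved fish sizes *and* missing covariate cells are latent quantities
sampled jointly with the parameters (data augmentation), so all downstream
summaries integrate over their uncertainty.

## The model

**Sampling frame.** Sites ("caves", indexed $j$) are visited each June and
August ("capture occasions", indexed $t$); the June$\to$August interval is
*summer* ($\approx$ 2 months, 67 days between the nominal mid-dates 16 June
and 22 August) and August$\to$June is *winter* ($\approx$ 10 months, 298 or
299 days). Seasons are indexed $h$.

**Temperature process and observation.** Seasonal mean water temperature in
cave $j$, year $t$ is
$$T_{hjt} = a_h + a_{hj} + a_{ht} + \varepsilon_{hT},$$
with season-specific cave and year varying intercepts and a cave-by-year
residual, each with its own variance ($V_{aj}, V_{at}, V_{\varepsilon T}$).
Observed cells carry a fixed, essentially-zero observation variance
($10^{-4}$ °C²) so that observed and missing cells can be treated uniformly
in the augmentation; missing cells are sampled from their full conditional
each iteration.

**Growth process.** Latent fork length propagates as
$$z_{ij,t+1} = z_{ijt} + g(z_{ijt})\, D_{iht},$$
where $D_{iht}$ is the number of days between the fish's captures (actual
capture dates when both are recorded, nominal mid-dates otherwise) and the
growth function is linear in centred size:
$$g(z) = \alpha_{jt} + b_{jt}\,(z - \bar z) + e,$$
$$\alpha_{jt} = \alpha_h + \alpha_{hj} + \alpha_{ht} + \alpha_{hjt}
  + \alpha_{hT}(T_{hjt} - \bar T), \qquad
  b_{jt} = b_h + b_{hj} + b_{ht} + b_{hjt} + b_{hT}(T_{hjt} - \bar T).$$
Intercept--slope pairs at each level (cave, year, cave-by-year; all
season-specific) are bivariate normal with an estimated 2×2 covariance.
Sizes at first capture are $N(\mu_0, \sigma_0^2)$; measured lengths are the
latent size plus $N(0, \eta^2)$ noise, with $\eta^2$ estimated *separately*
from field repeat measures and passed to the fit as a known constant.
Centring constants $\bar z$ and $\bar T$ are grand means of the observed
values, stored in the panel so fits are reproducible.

**Internal units.** Growth is handled in mm per month, where one "month" is
the season's nominal day span divided by its month count (33.5 d in summer,
29.8 d in winter); an interval of $D$ days contributes $D/\text{month-days}$
months. Seasonal totals are then exactly the monthly rate × 2 (summer) or
× 10 (winter), which is how `monthly_to_seasonal()` converts. Where a
per-season scale is wanted (variance tables are often printed that way),
`repeatability(..., scale = "season")` multiplies variances by the squared
month count.

## Estimation

No general MCMC engine is assumed: every full conditional of this model is
Gaussian, inverse-gamma or inverse-Wishart, so `fit_growth()` implements a
pure Gibbs sampler.

* **Latent sizes** are updated in a red--black sweep over occasion parity
  (cells of equal parity are conditionally independent given the rest), which
  vectorises over fish.
* **Priors** are minimally informative: $N(0, 100^2)$ on fixed effects,
  half-$t(3)$ priors on standard deviations (scale 5 for intercept-level and
  temperature SDs, 0.5 for slope-level, 10 for the residual growth SD, 50
  for $\sigma_0$), and a Huang--Wand prior on each 2×2 intercept--slope
  covariance (half-$t(2)$ marginal SDs, near-uniform correlation). All are
  configurable via `priors_config()`.
* **Recentring moves.** The fixed intercept trades off against the mean of
  each random-effect level (a posterior ridge that stalls plain Gibbs
  samplers). After each sweep the sampler draws the translation between the
  fixed effect and each level's deviations from its full conditional — the
  likelihood is invariant along this direction, so the move is exact and
  leaves the posterior unchanged while restoring good mixing.
* **Defaults** are 4 chains × 2,500 iterations (500 warmup); convergence is
  judged by the split-chain statistic (threshold 1.05) and effective sample
  sizes, exposed via `diagnostics()`. Desk-scale tests use 2 shorter chains
  — the reduced effort is a test-budget choice, stated where used.
* Fish captured only once are retained: they inform $\mu_0$, $\sigma_0^2$
  and the measurement model, but contribute no growth intervals. Latent
  support ends at the last capture — there is no survival model, so death
  and permanent emigration are indistinguishable from non-capture, and
  extrapolating past the last capture would require assumptions the model
  does not make.

### Derived quantities

All derived quantities are computed **per posterior draw**, then summarised;
a ratio of posterior means is not the posterior mean of the ratio, and the
test-suite checks the order of operations on deliberately skewed draws.

* Temperature-associated variance by the rule $V(a + bx) = b^2V(x)$:
  e.g. the temporal share is $V_{at}\,\alpha_{hT}^2$. Spatial uses the
  among-cave temperature variance, spatiotemporal the residual cave-by-year
  temperature variance.
* Slope variances are converted to growth-variance units by multiplying by
  $\sigma^2_{fl}$, the variance of fork lengths after a period of that
  season's growth, estimated by `fork_length_variance()` as the total
  variance of an intercept model with cave and year grouping factors (an
  assumption: the upstream description of this side-model's grouping is not
  public; the plain variance is available as a cross-check via
  `method = "simple"`).
* Repeatability proportions: $V_j = V_{\alpha j} + V_{\alpha(b_j)} + V_{j,T}$
  (and likewise for $t$, $jt$), $V_g = V_j + V_t + V_{jt}$, and each of the
  nine components divided by $V_g$, which sum to exactly 1 per draw. The
  residual $V_e$ is *excluded* from the denominator, following the
  definition of $V_g$ as the spatiotemporal variance; because the source
  material also prints a total alongside $V_e$ that could be read either
  way, the report additionally prints a clearly labelled share including the
  residual rather than asserting one reading.
* `asymptotic_size()` annualises the growth function (2 summer + 10 winter
  months) per draw and solves $g(z^*) = 0$, i.e. $z^* = \bar z - \alpha/b$;
  draws with $b \ge 0$ are flagged undefined, not dropped.

### Validation

`plan_removals()` / `run_ppc()` implement the holdout scheme: each round
removes one observation from each of 10 (configurable) distinct fish,
refits the full joint model, and predicts the held-out measurements
(latent size + measurement noise); at the defaults of 10 fish × 99 rounds
this yields 990 predictions, scored by 95%-interval coverage, Pearson
correlation, and mean absolute residual. Eligibility requires ≥ 3 captures
with at least one interior capture, so every holdout leaves a two-point
trajectory and stays inside the latent support (the original scheme's
eligibility rule is unstated; this is the weakest rule that keeps every
holdout predictable). Each round refits the full joint model with an
independent MCMC run; rounds are independent by construction.

## The synthetic world

`simulate_scenario()` generates data with exactly the structure the model
assumes, plus a truth manifest for recovery tests. The `"paper-like"` preset
is a stated world, fixed once:

* 20 caves, 15 occasions (August year 1 through August year 8), a 320-cell
  temperature grid with 22% of cells missing at random.
* Temperature means 6.33/4.32 °C (summer/winter) and variance components
  (0.22, 0.15, 0.35) / (0.21, 0.03, 1.03) for cave/year/residual.
* Growth fixed effects 3.4 / 0.82 mm month⁻¹, slopes −0.05 / −0.02 month⁻¹,
  temperature effects 0.40 / −9.85×10⁻⁴ mm month⁻¹ °C⁻¹. Random-effect and
  residual variances are taken from the fitted decomposition of the
  motivating system *read on the per-season scale* and converted to the
  internal monthly scale (/4 summer, /100 winter). The season-scale reading
  is forced by internal consistency: winter components exceed summer ones
  while winter growth is the less variable per month, and a per-month
  reading would imply ±40 mm winter swings against a mean winter total of
  8 mm.
* Measurement error η² = 0.6 mm²; duplicate measurements for 76 fish at the
  last June occasion.
* Quantities the motivating study does not state were chosen once as
  calibration of the stated world and not revisited: capture probability
  0.5 per occasion, per-occasion residence ("survival") 0.8, 90 initial +
  10 recruited fish per cave per occasion, and initial sizes
  $N(75, 15^2)$ at recruitment. With these, the preset reproduces the
  stated panel scale (≈ 9,200–9,600 observations of ≈ 3,700–3,800 fish,
  grand mean fork length 90–95 mm across seeds). Fish below the 45 mm
  tagging threshold are not emitted, mirroring the field protocol.
* Intercept–slope correlations default to 0 (the source states multivariate
  normality with estimated covariance but no values); the generator accepts
  nonzero correlations.
* A propagated size that would fall ≤ 0 has its residual resampled rather
  than truncated, keeping the process linear-Gaussian; the event count is
  logged in the truth manifest and is zero at preset parameters.

What the generator does **not** emulate: the two-visits-per-occasion
sub-structure, tag loss, size-dependent capture probability, and any real
ecological nonlinearity (resource pulses, density dependence). A green
recovery test therefore establishes that the estimator recovers the model's
own parameters from data of realistic size and missingness — not that the
model is true of any real system.

## Numerical choices and degenerate inputs

* With η² = 0, observed latent sizes are pinned to their measurements
  (the sampler special-cases η² < 10⁻¹²).
* Variance components can be fixed to exactly 0 (`fixed=` argument),
  dropping that deviation; designs with < 2 caves or < 2 years are rejected
  unless the corresponding components are fixed.
* A season-year with no data draws its effects from the prior; a
  temperature season with no observed cells is an error.
* Draws with $V_g = 0$ leave the repeatability ratios undefined; they are
  excluded from summaries with a reported count.
* Temperature-model designs with a single cave or year run but flag the
  variance components as unidentifiable.

## Known limitations

* The sampler is single-threaded R; a paper-scale panel (≈ 9,000
  observations) fits in minutes-to-tens-of-minutes at full effort, which is
  acceptable for an analysis package but slower than a compiled sampler.
* η² is fixed at its point estimate in the growth fit (the measurement
  module reports an interval; propagating it is a one-line override via
  `fixed = list()` variants but is not the default, matching the two-stage
  design).
* Temperature effects on growth mix more slowly than other parameters
  (they are partially confounded with year effects); the default chain
  length handles this, but very short desk runs may flag them.
* Ablation `no_season` collapses the seasonal structure but keeps
  half-year temporal groups; a coarser annual grouping would be a different
  model, not provided.
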