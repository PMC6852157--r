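---
title: "Methods: functional responses, allometry and encounter-rate simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional responses, allometry and encounter-rate simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bencounter)
```

# The model

## Functional responses under depletion

The per-capita feeding rate of a consumer at resource density $N$ is
modelled by the generalised functional response

$$f(N) = \frac{b\,N^{q+1}}{1 + b\,h\,N^{q+1}},$$

with capture (search) coefficient $b$, handling time $h$, and shape
exponent $q \ge 0$ interpolating between the hyperbolic type II ($q=0$)
and sigmoidal type III ($q=1$) forms; $q = h = 0$ gives the linear
type I response. With $h > 0$ intake saturates at $1/h$.

Feeding trials rarely replace consumed resources, so the constant-density
assumption behind $f(N)$ is violated within a trial. The package therefore
fits the depletion-corrected (random-predator) expectation: the expected
number eaten $N_e$ from an initial stock $N_0$ over duration $T$ solves
the implicit equation

$$N_e = N_0\left(1 - e^{\,c\,(h N_e - T)}\right), \qquad c = b\,N_0^{\,q}.$$

**Exponent convention.** Printed forms of this equation sometimes carry
$N_0^{\,q+1}$ in the exponent, but that form does not reduce to the
classic random-predator equation at $q = 0$, and is dimensionally
inconsistent with a per-capita attack coefficient $b N^q$. The package
defaults to $c = b N_0^{\,q}$ and exposes the alternative as
`convention = "q_plus_1"` in `rogers_eaten()` so both readings can be
compared.

**Solver.** For $h > 0$ the unique root in $[0, N_0]$ has the closed form
$N_e = N_0 - W\!\big(c h N_0\, e^{-c (T - h N_0)}\big)/(c h)$ with $W$ the
principal Lambert-W branch. The package ships its own vectorised
`lambert_w0()`: Halley iteration on $w e^w = x$ for $x < 3$ and Newton
iteration on the overflow-safe logarithmic form $w + \log w = \log x$
otherwise, so arguments up to the double-precision limit are handled
without evaluating $e^w$. Wherever the W argument would overflow `exp()`,
`rogers_eaten()` falls back on a bracketed `uniroot()` on $[0, N_0]$; the
two paths agree to better than $10^{-8}$ relative error over a wide
parameter grid (see the test suite), and a damped fixed-point iteration
serves as a third, independent oracle in tests.

## Likelihood, fitting and model selection

Counts eaten are modelled as
$\text{eaten} \sim \text{Binomial}(N_0,\, N_e/N_0)$ — the standard choice
for depletion designs, with probabilities clipped to
$[10^{-9}, 1-10^{-9}]$. Four variants are fitted by maximum likelihood
(`fr_fit()`): type I ($h=q=0$), type II ($q=0$), type III ($q=1$) and the
general model ($q \ge 0$ free). Optimisation works on $\log b$ and
$\log h$ (scale invariance; the $h \to 0$ boundary is pushed to $-\infty$
rather than a hard wall) with $q$ box-constrained at 0; a 5 × 5 grid in
$(b, h)$ (× 3 values of $q$ for the general model) is scored and local
optimisation (L-BFGS-B; Brent for the one-parameter type I) is run from
the five best grid points. Non-convergence is flagged, never silently
returned, and a trial set in which nothing was eaten returns a flagged
null fit with $b = 0$. Uncertainty is summarised by Wald intervals on the
optimised scale from the observed information; these stand in for profile
intervals throughout (including the generator round-trip tests) because
they are orders of magnitude cheaper and adequate at the simulated signal
strengths.

Model selection uses the small-sample Akaike criterion
$\mathrm{AICc} = -2\ell + 2k + 2k(k{+}1)/(n{-}k{-}1)$. The lowest-AICc
variant wins outright unless competitors sit within ΔAICc < 2, in which
case the proportional-consumption diagnostic arbitrates
(`proportional_trend()`): a locally weighted (loess, span 0.75, degree 1)
regression of eaten/$N_0$ on $\log_{10} N_0$ is classified as flat
(type I), decreasing (type II) or rise-then-fall (type III), with "flat"
meaning a smoothed change below 5% of the mean proportion per decade of
density. The general model is treated as II-like when its fitted
$q < 0.5$ and III-like otherwise; remaining ties go to the model with
fewest parameters. The span and flatness tolerance are defaults exposed
as arguments; they are conventional smoothing choices, not fitted
quantities.

## Derived rates

Because $b$'s units depend on $q$, capture rates are compared across fits
at the half-saturation density $N_{1/2} = (bh)^{-1/(q+1)}$, where intake
is half its maximum. The default reading is the effective attack
coefficient $b N_{1/2}^{\,q}$ (which is $b$ when $q=0$); the local slope
of the response curve there, $b(q{+}1)N_{1/2}^{\,q}/4$, is available as
`method = "derivative"` since the phrase "slope at half saturation" admits
both readings. Maximum feeding rate is $1/h$. Both are converted to
biomass units (g m$^{2\,\text{or}\,3}$ d$^{-1}$ and g d$^{-1}$) by
multiplying by resource wet mass and rescaling the trial time unit to
days. Shape exponents, whose distribution mixes point masses at 0 and 1
with positive reals, are compared between strategies by non-parametric
bootstrap of group means (`bootstrap_mean_q()`, 2000 resamples).

## Meta-analysis

Per-pair capture and maximum feeding rates (log$_e$, then z-scored across
the table) are modelled by linear mixed models with a random intercept per
taxonomic group. The fixed-effect candidates are the hierarchical set
built from log consumer mass, log resource mass and log temperature, their
two-way interactions (only alongside both parents), and encounter strategy
as a non-interacting categorical term — exactly 36 structures including
the null. Structures are ranked by AICc under maximum likelihood (REML
log-likelihoods are not comparable across fixed structures); the selected
structure is refitted by REML for reported coefficients. Temperature
enters as $\log(^\circ\mathrm{C})$ — deliberately not an Arrhenius
$1/kT$ correction — so records at or below 0 °C are rejected with a clear
message. Prediction bands come from a case-resampling bootstrap stratified
by strategy (preserving group sizes), refitting and predicting at
population level (random effects zeroed) over a log-mass grid at each
strategy's median covariates; bands are percentile intervals, clamped to
contain the full-data point prediction.

## The encounter-rate simulator

One consumer occupies a square toroidal arena. Active consumers move at
the allometric speed $V = 2.67\,l^{1.05}$ m s$^{-1}$ (body length $l$ in
m, from wet mass via $l = (m/\rho)^{1/3}$ cm with tissue density
$\rho = 1$ g cm$^{-3}$), carrying a discoid in-plane encounter region of
radius $r = r_0 m^{0.36}$ ($r_0 = 0.01$ m g$^{-0.36}$, a declared
calibration constant). Filter feeders are stationary with a hemispheric
region anchored to the seabed; alternatively their region radius can be
sized from a clearance rate $Q$ by flux balance, $r = \sqrt{2Q/(\pi U)}$,
the radius whose flow-facing half-disc intercepts volume flux $Q$ at
current speed $U$ (a documented reconstruction of the clearance-based
region). Movement is a random walk: persistent heading plus Gaussian
turning noise (default SD 30° per step) in 2D, isotropic redraw in 3D.
Planktonic resources are additionally advected along +x by a per-step,
per-resource draw from Normal(0.1, 0.01) m s$^{-1}$ (the "±" of the
calibrated current read as an SD); they reflect at the seabed and the slab
top.

Numerical choices:

* **Time step.** $dt = \min(r / (5 v_{\max}), 1)$ s, so no agent can cross
  the region between detections (no continuous-time detection is
  attempted).
* **Detection and relocation.** An encounter is region entry after
  movement; encountered resources are immediately relocated uniformly at
  random *outside* the region, so resource count and density are exactly
  conserved (the encounter-limited regime; consumption is not modelled
  inside the simulator). Relocation can re-seed the consumer's future
  path, a small (<5%) upward bias relative to ballistic kinetic theory.
* **Flow-through boundary.** With pure advection on a torus the
  cross-stream coordinates of resources never mix: the subset of resources
  aligned with the hemisphere would be exhausted after one wrap and the
  rate would collapse — an artefact, not physics. Advected resources
  therefore re-enter at the upstream edge with a freshly drawn uniform
  cross-section, as a laminar current carrying new water, keeping the
  cross-stream distribution stationary. Walk-only agents use the plain
  torus.
* **Arena size.** Side $8r$, slab height $10r$. When the density law
  implies fewer than 20 or more than 3000 resources in that volume, the
  simulation runs at a clamped count and rates are rescaled linearly —
  valid because encounter rates are linear in density in this regime
  (verified by a dedicated test).
* **Validation regime.** The kinetic oracles $2rVn$, $2r\langle
  V_{rel}\rangle n$ and $nU\pi r^2/2$ assume ballistic motion on the scale
  of $r$. Validation runs therefore use weak turning (5° per step); with
  the production default of 30° per step a persistent-turning walker
  re-covers its own track and realises ~15–20% less than the ballistic
  rate, which is a property of diffusive search, not a solver error.

Per-strategy resource fields come from `default_strategy_scalings()`:
power laws for unitary resource mass and density versus consumer mass.
These are calibration inputs, not fitted values — chosen once so that
filter feeders face very small (~10$^{-8}$ g) planktonic resources at
10$^6$–10$^9$ m$^{-3}$ volumetric densities while active strategies face
10$^{-2}$–10$^0$ g benthic resources at 10$^0$–10$^2$ m$^{-2}$, spanning
resource masses from 10$^{-11}$ to 10$^1$ g across consumer masses from
10$^{-6}$ to 10$^2$ g, with static resources denser and larger than
mobile ones. They can be replaced by laws fitted to data with
`fit_strategy_scalings()`, which regresses per-mass-bin *minimum*
densities (scarce-resource, encounter-limited logic; a lower-decile
alternative is a flag).

## The synthetic-data generator

`generate_meta_dataset()` emulates the structure of a benthic
feeding-trial compilation: consumer masses log-uniform over eight orders
of magnitude (10$^{-6}$–10$^2$ g), a strategy mix dominated by
active-static, active-mobile and filter feeding (38/33/21% plus small
sit-and-wait, deposit and grazer fractions), true $(b, h)$ drawn around
mass power laws with log-normal scatter, and shape exponents from a
mixture of point masses at 0 (55%) and 1 (25%) with uniform positive
values (20%) — mirroring the atypical fitted-$q$ distribution that
motivates the bootstrap comparison. Trials use doubling density series
(5 levels from 2 by default) because geometric designs are the
functional-response convention; replicate counts per level are a free
parameter (12 by default) since source studies rarely report them.
Trial noise is binomial around the deterministic depletion expectation —
deliberately the same likelihood the estimator fits, so generator and
estimator are self-consistent; an event-level (Gillespie-style) depletion
mode exists for robustness checks. Every pair draws its RNG substream
from the master seed (`substream_seed()`), so single pairs regenerate
identically without re-running the whole dataset.

What the generator does *not* emulate: digitisation error from published
figures, non-binomial overdispersion, arena-wall effects, temperature
dependence of the true parameters, and correlation between $b$ and $h$
beyond their shared mass scaling. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation machinery
under the stated noise model, not robustness to every pathology of real
compilations.

## Problem sizes used in tests

The test suite runs the recovery and validation studies at deliberately
modest sizes chosen to keep Monte-Carlo error well inside the asserted
tolerances: 50 seeds for type II parameter recovery (6 density levels ×
25 replicates), 24 selection simulations for the II-vs-III consistency
check, 1000 replicates × 100–120 steps for the kinetic validations, and
25 replicates per mass for the strategy-ordering sweep. The pipeline
smoke test uses 20 pairs and 100 ABM replicates.

## Known limitations

* Wald (not profile or bootstrap) intervals for functional-response
  parameters; they degrade near the $h \to 0$ boundary.
* The simulator models encounters only: no capture success, handling
  interruption, satiation, predator interference, or turbulent/boundary-
  layer hydrodynamics.
* Sit-and-wait, deposit and grazer strategies are generated and carried
  through tables but excluded from mixed-model fitting and from the
  simulator's strategy set, matching their data-poor status.
* `log(temperature in °C)` is not a physically principled temperature
  scale; it is retained deliberately for comparability, with the
  covariate structure exposed so an Arrhenius variant can be added by the
  user at the meta-table stage.
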