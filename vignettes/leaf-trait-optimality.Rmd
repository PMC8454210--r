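---
title: "Optimality models for leaf traits along elevation gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimality models for leaf traits along elevation gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafoptim)
library(dplyr)
```

## The problem

Four leaf traits summarise much of the photosynthetic strategy of a plant
community: the ratio of leaf-internal to ambient CO~2~ partial pressure
($\chi$), the maximum carboxylation capacity standardised to 25&nbsp;°C
($V_\mathrm{cmax25}$), leaf mass per area ($M_a$) and leaf nitrogen per
area ($N_\mathrm{area}$). Along a mountain transect all four change
systematically, but elevation bundles several distinct causes: air
pressure falls, temperature falls, vapour pressure deficit and radiation
change, the growing season shortens, and moisture often peaks at
mid-elevations. Eco-evolutionary optimality theory provides trait
predictions that need no site-level calibration, which makes it possible
to *attribute* observed trait differences to individual environmental
drivers instead of to "elevation" as a whole. `leafoptim` implements that
workflow: bioclimate derivation, the four trait models, coefficient
re-calibration, driver attribution, uncertainty propagation, evaluation
against observed trait tables, and a synthetic transect generator so the
entire pipeline is testable without any external data.

## The models

### $\chi$: the least-cost hypothesis

Leaves are assumed to minimise the combined unit costs of maintaining
transpiration and carboxylation capacity. The optimum is

$$\chi = \frac{\Gamma^*}{c_a} +
  \left(1 - \frac{\Gamma^*}{c_a}\right)\frac{\xi}{\xi + \sqrt{D}},
  \qquad
  \xi = \sqrt{\frac{\beta\,(K + \Gamma^*)}{1.6\,\eta}},$$

where $\Gamma^*$ is the photorespiratory compensation point (Pa), $K$ the
effective Michaelis–Menten coefficient of Rubisco (Pa), $\eta$ the
viscosity of water relative to 25&nbsp;°C, $D$ the vapour pressure deficit
and $\beta = 146$ the cost ratio. $\chi$ is bounded by $\Gamma^*/c_a$
from below and 1 from above and decreases with $D$. Note the units: $\xi$
has units of $\sqrt{\mathrm{Pa}}$, so $D$ enters in Pa. The user-facing
`d0` argument is in kPa, following the bioclimate table convention, and
is converted internally — a frequent source of silent errors in
re-implementations, which is why the conversion lives in exactly one
place.

Both $\Gamma^*$ and the O~2~ partial pressure in
$K = K_c(1 + P_O/K_o)$ scale linearly with air pressure, which is how
elevation acts on $\chi$ and $V_\mathrm{cmax25}$ independently of
climate. $K_c$, $K_o$ and $\Gamma^*$ follow Arrhenius scaling from their
25&nbsp;°C references (39.97&nbsp;Pa, 27.48&nbsp;kPa, 4.332&nbsp;Pa, with
activation energies 79,430, 36,380 and 37,830&nbsp;J&nbsp;mol^−1^). The
viscosity ratio uses the Vogel empirical equation
$\eta(T) = 2.414\times10^{-5}\,10^{247.8/(T_K - 140)}$&nbsp;Pa&nbsp;s;
its coefficients are exposed in `leaf_constants()` like every other
constant.

### $V_\mathrm{cmax25}$: the coordination hypothesis

Rubisco-limited and light-limited photosynthesis rates are assumed equal
under average daytime conditions, giving

$$V_\mathrm{cmax} = \varphi_0 R_0\,
  \frac{c_i + K}{c_i + 2\Gamma^*}
  \sqrt{1 - \left(\frac{c}{m}\right)^{2/3}},
  \qquad m = \frac{c_i - \Gamma^*}{c_i + 2\Gamma^*},$$

with $\varphi_0 = 0.085$&nbsp;µmol&nbsp;C&nbsp;µmol^−1^&nbsp;photon,
$c = 0.41$ and $c_i = \chi c_a$. Standardisation to 25&nbsp;°C divides by
the peaked Arrhenius factor $f_v(T)$ with $H_a = 71{,}513$,
$H_d = 200{,}000$&nbsp;J&nbsp;mol^−1^ and an entropy term that acclimates
linearly to growth temperature,
$\Delta S = 668.39 - 1.07\,T_g$&nbsp;(J&nbsp;mol^−1^&nbsp;K^−1^, $T_g$ in
°C). The mixed convention — Celsius inside the $\Delta S$ relation,
Kelvin inside the exponentials — is deliberate and documented here
because the two readings give different curves; the adopted one anchors
$f_v(25) = 1$ exactly, which the test suite asserts to $10^{-12}$.

### $M_a$: leaf economics for deciduous species

Combining the optimal trade-off between $M_a$ and leaf longevity, the
proportionality of potential leaf lifespan to
$M_a/V_\mathrm{cmax25}$ ($u \approx 8889$, $k = 30$&nbsp;g&nbsp;biomass
mol^−1^&nbsp;C), and the coordination model yields a closed-form
theoretical $M_a$, implemented as `lma_theoretical()`. Its composite
temperature dependence — through $\chi$, $\Gamma^*$, $K$ and $f_v$ —
amounts to a decline in $\ln M_a$ of about 3% per degree at standard
conditions; the package recomputes this number by numerical
differentiation rather than hard-coding it (see
`scripts/acceptance.R`). The construction-cost constant CC cancels from
the calibrated model; `lma_theoretical()` takes it as an explicit
argument (default 1.5&nbsp;gC&nbsp;gC^−1^) and is used for elasticity
work only, never for site prediction.

Site prediction uses the linearised, calibrated deciduous model

$$\ln M_a = 1.22\,\ln R_\mathrm{LAI} + 0.78\,\ln f - 0.06\,T_g
  - 0.60\,\ln \alpha_p + 1.70,$$

where $R_\mathrm{LAI}$ is the canopy-averaged daily photon dose, $f$ the
growing-season fraction of the year (standing in for the leaf longevity
of deciduous species) and $\alpha_p$ the AET/PET moisture index. The
model is intentionally restricted to deciduous species: without leaf
longevity information an evergreen $M_a$ is not identified.

### $N_\mathrm{area}$

Two formulations are provided. The two-step model sums structural
nitrogen ($10^{-2.67} M_a^{0.99}$) and metabolic nitrogen
($\mathrm{alloc} \times 0.003135\,V_\mathrm{cmax25}$, with the
allocation multiplier either the original 9.5 or a locally refitted
value, 7.2 by default). The direct model,
$N_\mathrm{area} = 0.02\,M_a + 0.003\,V_\mathrm{cmax25}$, skips the
intermediate allometries; it applies to non-nitrogen-fixing plants, with
an optional additive offset for fixers estimated by
`fit_narea_coefficients(include_n_fixer = TRUE)`. Under the algebraic
identification (structural term linearised, alloc ×&nbsp;0.003135 =
0.003) the two coincide exactly, which the tests verify on a grid.

## Temperature bases and other tunable choices

Traits acclimate on different timescales. By default $\chi$ and
$V_\mathrm{cmax25}$ are driven by mean July daytime temperature
($T_{dJ}$, the month trait data are typically collected, computed from
the diurnal cycle geometry by `daytime_temperature()`) while $M_a$ is
driven by the growing-season mean $T_g$ — deciduous leaves are built
once per season and integrate the whole of it. Every user-facing
function accepts a `temperature_basis` argument to swap these.

Whether a published "growing-season mean temperature" is a daytime mean
or an all-hours mean is often ambiguous. `growing_season_stats()`
computes the all-hours daily mean over days above the 0&nbsp;°C baseline
(both the baseline and the input series are under the user's control),
and `daytime_temperature()` provides the daytime construction, so either
reading can be assembled explicitly.

The canopy averaging behind $R_\mathrm{LAI}$ is not standardised in the
literature that reports it. `canopy_light()` converts the mean
growing-season PAR flux to a daily dose over a 12-hour daylight window
and applies the Beer–Lambert canopy mean
$(1 - e^{-kL})/(kL)$ with extinction coefficient $k = 0.5$; both the
window and $k$ are configurable constants. This is a documented stand-in
for an unspecified weighting, and it has the right limits (no canopy
→ no attenuation; attenuation strictly decreasing in LAI; light never
created).

Air pressure uses the standard isothermal-lapse barometric formula
(101.325&nbsp;kPa, 0.0065&nbsp;K&nbsp;m^−1^, 288.15&nbsp;K), ambient CO~2~
is a fixed 400&nbsp;ppm mole fraction times local pressure, and the
atmospheric δ^13^C needed by the isotope inversion defaults to
−8&nbsp;‰. All of these are `leaf_constants()` entries and can be
overridden per call or via the YAML configuration consumed by
`run_pipeline()`.

## Attribution of trait differences to drivers

`decompose_contributions()` implements the three-step one-at-a-time
decomposition: build an average-site baseline (driver means; the
pressure-derived quantities are *recomputed* from the mean elevation,
not averaged — the barometric profile is convex, so the two differ);
move one driver at a time from baseline to the site's value and
re-predict; report the difference as that driver's contribution. The
"pressure/elevation" driver moves `patm` and everything derived from it
(ambient CO~2~, $\Gamma^*$, $K$, $P_O$) while climate stays at baseline —
i.e. ambient CO~2~ is recomputed when elevation is perturbed, because
partial pressure is a pressure-times-mole-fraction quantity. For
$V_\mathrm{cmax25}$, the $\chi$ input itself is one of the drivers,
set to the site's own predicted $\chi$ while the other inputs stay at
baseline.

Because $\ln M_a$ is additive in its transformed drivers, its ln-space
contributions sum to the total site-minus-baseline difference exactly
(asserted to $10^{-10}$). $\chi$ and $V_\mathrm{cmax25}$ are not
additive; the residual interaction is computed and reported in its own
column rather than silently folded into a driver, so stacked bar charts
built from the table (see `autoplot()`) are honest about what
one-at-a-time decomposition can and cannot apportion.

## Uncertainty propagation

`propagate_uncertainty()` applies the first-order formula
$u^2(y) = \sum_i (\partial m/\partial n_i)^2 u^2(n_i)$ with central
finite differences (relative step $10^{-4}$, configurable), assuming
independent parameters; `mc_propagate()` is the Monte-Carlo oracle used
to verify it. For the linear $N_\mathrm{area}$ model the two agree
exactly; for the mildly nonlinear $\chi$ and $V_\mathrm{cmax25}$ models
they agree to within a few percent at the default uncertainty
magnitudes; for a strongly curved toy ($y = x^2$ at a stationary point)
they diverge by construction, and the test suite pins that divergence
down as documentation.

The default parameter uncertainties in `default_uncertainties()`
($u(\beta) = 30$, $u(c) = 0.04$, regression-coefficient scale
uncertainties for the $M_a$ and $N_\mathrm{area}$ models) are plausible
exploration values chosen once, not a reproduction of any particular
published budget. For a faithful budget they should be replaced by the
standard errors reported by the calibration fits on the data at hand
(`tidy(fit)$std.error`).

## The synthetic transect

`transect_scenario()` fixes the study conditions the package is tested
under: 18 sites from 1143 to 4361&nbsp;m on a single latitude
(29.6°&nbsp;N), temperature declining at 5.5&nbsp;K&nbsp;km^−1^ from a
22&nbsp;°C July daytime mean at the lowest site, a hump-shaped moisture
index peaking mid-transect (the lowest and uppermost sites drier), VPD
derived from saturation vapour pressure and a humidity profile that
tracks the hump, growing-season fraction falling from 0.75 to 0.35,
radiation rising and LAI falling with elevation, 15 species per site
(80% deciduous, 10% nitrogen fixers with a +0.3&nbsp;g&nbsp;m^−2^
$N_\mathrm{area}$ offset), and lognormal species noise with ln-scale sd
0.2 on $M_a$ and $V_\mathrm{cmax25}$, 0.1 on $N_\mathrm{area}$ and
additive sd 0.04 on $\chi$. Leaf δ^13^C is back-computed from each
species' $\chi$ by inverting the discrimination model, so the isotope
path is exercised end to end. Everything is deterministic given the
scenario seed.

What the generator does *not* emulate: spatial east–west moisture
structure, within-canopy light gradients, trait–trait error correlation
(available as independent noise only), measurement error distinct from
species-level variation, and any deviation of the trait-generating
process from the models themselves. That last point matters for
interpreting tests: synthetic evaluation scores are near-perfect by
construction and validate the *plumbing*, not the models' adequacy on
real vegetation.

One structural property of real transects is reproduced deliberately:
the drivers covary strongly with elevation. A consequence — visible if
you calibrate on the transect itself — is that the $M_a$ regression is
ill-conditioned on transect data alone; coefficient recovery experiments
therefore use independently sampled designs, and that distinction is
kept explicit in the tests.

```{r example}
scenario <- transect_scenario(seed = 1)
sites <- generate_sites(scenario)
predictions <- predict_traits(sites)
predictions

traits <- generate_traits(sites, scenario)
observed <- site_mean_traits(traits)
joined <- dplyr::left_join(observed, predictions, by = "site_id",
                           suffix = c("_obs", "_pred"))
agreement_stats(joined, chi_obs, chi_pred)
```

## Numerical choices and degenerate inputs

* Central finite differences everywhere a derivative is needed
  (sensitivities, elasticity checks), with steps scaled to the argument
  magnitude.
* `chi_optimal()` refuses $D_0 \le 0$ and sites where
  $c_a \le \Gamma^*$; `vcmax_coordination()` names the failing
  inequality when $m \le c$ (too little CO~2~ or too dim a light
  environment for the square-root term to exist).
* Isotope-derived $\chi$ outside $(0, 1.2)$ is flagged, never clipped or
  dropped, so filtering is an explicit, visible pipeline step.
* `daytime_temperature()` signals polar day/night
  ($|\tan\varphi\tan\delta| \ge 1$) as an explicit out-of-domain error.
* Calibration drops incomplete records listwise with a logged count and
  refuses rank-deficient designs naming the offending column.
* All fits are plain least squares via `lm()`; results are invariant to
  row permutation (asserted).

## Problem sizes

The test suite and the reproduction script are sized for a laptop: the
transect has 18 sites and 270 species records; the coefficient-recovery
experiment uses 200 replicates of $n = 600$; Monte-Carlo verification
uses 10,000 draws per trait model; the isotope round-trip checks 1,000
random admissible values. These sizes were chosen so each property is
measured well inside its tolerance, and they are stated here so that
anyone scaling the experiments up knows the baseline.

## Known limitations

* The deciduous $M_a$ model is not applicable to evergreen species and
  the package does not attempt it.
* No $J_\mathrm{max}$ prediction; the coordination model's square-root
  term assumes electron-transport capacity is not limiting at the scale
  the model is applied.
* Parameter covariances are ignored in propagation (the first-order
  formula as used assumes independence).
* Input-climate uncertainty (as opposed to parameter uncertainty) is out
  of scope.
* The moisture effect on $M_a$ is empirical, not derived from optimality
  theory; where moisture limitation is severe the model inherits that
  gap.
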