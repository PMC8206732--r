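---
title: "Methods: simulating climate-change risk for winter wheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating climate-change risk for winter wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatclim)
```

## What the package computes

`wheatclim` estimates how a changing climate alters both the *mean* and the
*risk profile* of winter wheat yields. The pipeline has four stages:

1. a **stochastic daily weather generator**, parameterized by monthly site
   statistics and perturbed by scenario change factors;
2. a **daily-timestep wheat simulator** (thermal-time phenology,
   radiation-use-efficiency biomass accumulation with CO2 fertilization, a
   layered soil-water bucket with a moisture choking function, and grain-set
   damage from drought or heat around flowering);
3. **stress indices** computed from four paired runs per season;
4. **ensemble risk summaries**: percentiles, recurrence intervals,
   coefficient of variation, and boxplot statistics across a spread of
   GCM-like scenarios.

The stress decomposition rests on four yields simulated on *identical*
weather:

* $Y_p$ — potential yield: flowering-tolerant cultivar, water limitation off;
* $Y_w$ — water-limited yield of the same tolerant cultivar;
* $Y_{wd}$ — water-limited yield of a cultivar drought-sensitive around
  flowering only;
* $Y_{wh}$ — water-limited yield of a cultivar heat-sensitive around
  flowering only;

from which the indices are the proportional losses

$$\mathrm{WSI} = 1 - Y_w/Y_p, \qquad
  \mathrm{DSI} = 1 - Y_{wd}/Y_w, \qquad
  \mathrm{HSI} = 1 - Y_{wh}/Y_w .$$

WSI is a *source-capacity* stress (season-long water limitation restricting
assimilation); DSI and HSI are *sink-capacity* stresses (grain-number
reduction in a window around anthesis). The 95th percentile of an index over
many simulated years, e.g. $\mathrm{WSI}_{95}$, is the loss level exceeded
with 5% probability — once in 20 years on average, since a loss at
percentile $q$ recurs every $1/(1-q)$ years.

## The weather generator

Each harvest year is generated independently as a season-spanning series
(1 October through 31 August, non-leap 365-day calendar) with one child RNG
seed derived per year from the master seed, so ensembles are reproducible
and cells can be computed in any order.

* **Precipitation occurrence** is a monthly first-order two-state Markov
  chain with transition probabilities $p_{w|d}$ and $p_{w|w}$; its
  stationary wet-day frequency is $p_{w|d}/(1 + p_{w|d} - p_{w|w})$, which
  the tests verify empirically.
* **Wet-day amounts** are gamma-distributed with month-specific means and a
  shape parameter shared across months (default 0.75, a typical value for
  daily rainfall skewness in maritime climates).
* **Temperature** is a smooth seasonal cycle plus an AR(1) residual
  (stationary sd 2.5 degC, lag-1 autocorrelation 0.65 by default). The
  cycle interpolates mid-month knots linearly; knots are adjusted by a fixed
  12x12 linear solve so that calendar-month averages of the daily cycle
  reproduce the configured monthly means exactly. Daily tmax/tmin are the
  mean plus/minus half the monthly diurnal range, with a tmax depression
  (default 1.5 degC) on wet days.
* **Radiation** is a clearness index times extraterrestrial radiation from
  standard solar geometry at the site latitude, reduced (default factor
  0.55) on wet days.

Cross-correlation is limited to the two wet-day effects; there is no full
cross-covariance matrix. This reproduces the features the crop model is
sensitive to — wet/dry spell structure, rain-temperature-radiation
coupling in sign, seasonal cycles — but not observed spell-length
distributions or extreme-value behaviour of any real station. Passing tests
therefore demonstrate internal consistency of the analysis under plausible
GB-like conditions, not validation against observed weather.

### Climate scenarios and the GCM-like ensemble

A scenario holds a CO2 concentration plus twelve monthly change factors:
additive temperature deltas, multiplicative precipitation and radiation
factors — the standard change-factor practice for perturbing a weather
generator. The baseline scenario is 363.8 ppm with zero deltas and unit
factors; the two 2050 pathways use 487 ppm (RCP 4.5) and 541 ppm (RCP 8.5).

`make_gcm_ensemble()` emulates the inter-model spread of a multi-model
ensemble: each member draws one winter and one summer anomaly per variable
from normal distributions and interpolates them through the year with a
cosine weight (January = winter, July = summer). Defaults (chosen once, as
study conditions, from typical mid-century anomalies over Great Britain):

| parameter | RCP 4.5 | RCP 8.5 |
|---|---|---|
| winter warming mean (sd), degC | 1.4 (0.45) | 1.8 (0.55) |
| summer warming mean (sd), degC | 1.9 (0.55) | 2.5 (0.65) |
| winter precipitation factor mean (sd) | 1.05 (0.06) | 1.07 (0.07) |
| summer precipitation factor mean (sd) | 0.90 (0.08) | 0.85 (0.10) |

## The crop simulator

The simulator is a deliberately compact process model in the Sirius
tradition, not a reimplementation of any calibrated model. One season runs
from sowing (20 October by default) to maturity at a daily step.

**Phenology.** Thermal time is $\max(0, (T_{min}+T_{max})/2 - T_{base})$.
Emergence occurs 150 degC d after sowing. Development then accumulates
thermal time modulated by a photoperiod factor
$f_p = 1 - s_p (D_{sat} - D)/D_{sat}$ (clamped to [0,1]) with daylength $D$
from the sunrise equation. Vernalization accumulates vernal-days with a
triangular effectiveness over 0-12 degC (peak at 6 degC), saturating at 40;
the final leaf number interpolates from 14 (unvernalized) to 8 (fully
vernalized). Anthesis occurs when development reaches
$\mathrm{phyllochron} \times (\mathrm{FLN} + 2.5)$ (phyllochron 100 degC d),
maturity a further 650 degC d later.

**Canopy and biomass.** LAI tracks leaf stage (0.75 per leaf, capped at
6.5) until anthesis and senesces during grain fill, at a rate multiplied by
$(2 - f_w)$ under water stress. Daily biomass is
$\mathrm{RUE} \times f_{CO_2} \times 0.5\,R_s \times (1 - e^{-k\,\mathrm{LAI}})
\times f_T \times f_w$ with RUE 2.2 g MJ$^{-1}$ PAR, $k = 0.45$, PAR taken
as half of global radiation, and a temperature factor $f_T$ ramping 0 to 1
over 0-8 degC and declining above 25 degC. CO2 fertilization is linear:
$f_{CO_2} = 1 + 0.30\,(C - 364)/364$, i.e. +30% RUE at doubling.

**Water.** The soil is a stack of 5-cm layers sharing the available water
capacity equally (default 177 mm over 30 layers, full at sowing). Roots
deepen at 1 mm per degC d. Potential evapotranspiration uses an
equilibrium-evaporation (Priestley-Taylor-type) formula
($\alpha = 1.26$, $R_n = 0.6 R_s$), split into soil evaporation and
transpiration by canopy cover $1 - e^{-k\,\mathrm{LAI}}$. The *moisture
choking function* $f_w = \min(1, \mathrm{FTSW}/0.5)$ of the root-zone
fraction of transpirable soil water multiplies assimilation, soil
evaporation, transpiration and the senescence acceleration. Withdrawals are
taken proportionally to layer content and capped by availability; the
balance closes exactly each day (rain = storage change + evaporation +
transpiration + drainage), which the tests assert to $10^{-9}$ mm.

**Grain yield.** At anthesis, ear mass is 25% of biomass; potential grain
number is 100 grains per g ear mass, multiplied by the grain-set factor. A
drought-sensitive cultivar loses grain set linearly in the mean of
$(1 - f_w)$ over $\pm 5$ days around anthesis (slope 1.0); a heat-sensitive
cultivar loses $0.05$ per degC d of $T_{max}$ above 27 degC in the window;
both floored at 0.2; a tolerant cultivar keeps exactly 1. Grain mass is
post-anthesis assimilation plus remobilizable stem reserves (40% of
anthesis biomass), capped by grain number times the 45 mg potential grain
weight. Yields are dry matter, 1 t/ha = 100 g/m^2.

### Design choices worth flagging

* **Photoperiod sensitivity (default 0.6, saturation 16 h).** With weak
  photoperiod control, development accrues mostly from mild winter
  temperatures, so uniform warming advances anthesis by over a month and
  the shortened season erases the CO2 fertilization gain — the opposite of
  the qualitative balance this analysis is built to study. A sensitivity of
  0.6 concentrates development in spring, keeps baseline anthesis in
  mid-May and preserves the expected net effect (higher 2050 yields with a
  moderate phenology advance). Even so, the simulated advance (~3 weeks for
  ~+2 degC) overstates what calibrated wheat models produce (~8-12 days);
  phenology *shifts* here are qualitative.
* **Free parameters.** Parameters not pinned by the model description
  (LAI per leaf, temperature-factor ramp, reserve fraction) were set once so
  that baseline water-limited yields at the demo sites fall in the 8-12 t/ha
  range typical for GB winter wheat, and not revisited.
* **Potential run.** The potential ($Y_p$) run forces $f_w = 1$ but still
  tracks the water balance; its diagnostics are not used.
* **Failed seasons** (anthesis or maturity not reached within the weather
  record) are returned flagged, excluded from summaries with a warning
  count, never silently dropped.
* **Quantile convention.** All percentiles — index percentiles, boxplot
  statistics, the exceedance check — use linear interpolation of order
  statistics at position $1 + q(n-1)$. Boxplot whiskers are the 10th/90th
  percentiles with outliers outside them, not 1.5 IQR.
* **Tie-breaks and degeneracy.** Indices clamp tiny negative values from
  floating error to zero but raise an error if the yield ordering
  $Y_w \le Y_p$, $Y_{wd} \le Y_w$, $Y_{wh} \le Y_w$ is genuinely violated;
  index computation refuses zero $Y_p$ or $Y_w$.

## Demo study conditions and problem sizes

The built-in demo sites span the national water-deficit contrast: a warm,
dry "southeast" site (~600 mm/yr) and a cool, wet "northwest" site
(~1300 mm/yr), both on the default 177 mm AWC profile, sown 20 October.
They are invented but seasonally realistic; nothing is fitted to station
records.

The test suite runs desk-scale versions of the full design: 2000-year
exceedance calibration at the dry site (the empirical
$\Pr(\mathrm{WSI} > \mathrm{WSI}_{95})$ lands at 5%), stress-ordering
checks over 1000 randomized seasons, water-balance closure over 100 random
seasons, and a 2-site x 4-scenario x 30-year demo ensemble for
determinism and direction-of-effect checks (2050-like scenarios raise mean
yield and advance anthesis; the dry site carries the larger
$\mathrm{WSI}_{95}$). These sizes were chosen so the whole suite runs in a
few minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

```{r demo, eval = FALSE}
mf <- demo_fixture(seed = 1)      # 2 sites, baseline + 3 GCM-like members, 30 yr
ens <- run_ensemble(mf)
glance(ens)
autoplot(ens, "mean_yield")
plot_loss_curves(ens)
```

## Known limitations

* No nitrogen (or other nutrient) dynamics, no waterlogging, no pests or
  diseases: yields are water/heat/CO2-limited only.
* The generator's semi-empirical realism stops at monthly statistics and
  first-order persistence; heatwave clustering and multi-week droughts are
  underdispersed relative to real weather, so absolute index magnitudes
  (e.g. the size of $\mathrm{HSI}_{95}$ under strong warming) are
  indicative only.
* The grain-set dose-response slopes and the choking-function shape are
  plausible stand-ins; results that depend on their exact values are
  qualitative.
* Scenario members perturb means only; changes in variability (e.g. more
  variable summer rainfall) are not represented.
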