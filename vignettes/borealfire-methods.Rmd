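---
title: "Process-based fire weather, burned area, and fire carbon in borealfire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-based fire weather, burned area, and fire carbon in borealfire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(borealfire)
```

# The model

`borealfire` simulates daily wildfire occurrence, spread, burned area, and
fire carbon emissions on a regular grid.  It is a process-based scheme:
fire happens where there is fuel to burn, an ignition source, and dry
enough fine fuels, and the area it burns follows from weather-driven
spread rates and a population-dependent chance of being put out.

## Fire weather

Fuel dryness is tracked with the Canadian Forest Fire Weather Index (FWI)
system, driven by daily maximum temperature, relative humidity, wind
speed, and 24-h rainfall.  Three prognostic moisture codes are stepped
every day:

* **FFMC** — fine surface litter; a kinetic drying/wetting model with a
  one-day lag.  Higher FFMC means drier fuel (standard convention).
* **DMC** and **DC** — the loosely compacted duff and the deep compact
  organic layer.  The model exposes only FFMC, ISI, and BUI to the fire
  scheme, but DMC and DC are carried as internal state because BUI is
  defined from them; this is mathematically unavoidable.

Two derived indices feed the fire module: **ISI** (FFMC plus wind: a
spread-rate proxy) and **BUI** (DMC plus DC: fuel available for
consumption).  The equations are the published standard chain; we use the
self-consistent fine-fuel moisture conversion constant 147.27723 of the
updated standard code release, which makes the moisture/code conversion
an exact inverse pair (with the older rounded constant, FFMC drifts by a
few hundredths per day under constant weather and has no fixed point,
which the test suite would catch).  Startup values are the conventional
FFMC 85, DMC 6, DC 15, configurable via `fwi_initial()`; no
overwintering adjustment of DC is applied.  A single Canadian day-length
factor table is used for all latitudes.

Note one deliberate convention choice: the moisture probability below
*increases* with FFMC, consistent with the standard FWI semantics in
which high FFMC means dry, ignitable litter.

## Fire occurrence

The daily probability of fire for a representative area
(`a_rep` = 800 km²) is a product of three conditional probabilities,

$$P_f = P_b \, P_i \, P_m,$$

* $P_b$: linear ramp in aboveground biomass between 0.2 and
  1.0 kg C m⁻² (no fuel, no fire; saturates in closed forest).
* $P_m$: logistic in FFMC, $P_m = \mathrm{logit}^{-1}(-25.2 + 0.34\,\mathrm{FFMC})$.
* $P_i$: ignition.  The natural part ramps linearly in annualized
  cloud-to-ground lightning between 0.25 and 10 strikes km⁻² yr⁻¹.  The
  anthropogenic part is $\min(1, (p_d/300)^{0.43})$ in population density
  $p_d$ and saturates at 300 persons km⁻².  The two combine as
  complementary probabilities, $P_i = P_{nat} + (1-P_{nat})P_{hum}$,
  the precursor module's semantics; both the ramp shape and the exponent
  are configurable because only the thresholds are firmly pinned down.

Lightning thresholds are quoted as annual rates; daily strike densities
are annualized before comparison (×365 inside the simulator, matching
its no-leap calendar; `annualize_strikes()` defaults to 365.25).

## Spread and burned area

The downwind spread rate $v_d$ is PFT-class specific (Eq. forms for
needleleaf trees, broadleaf trees, and grasses), each the product of the
class maximum $v_{d,max}$ with an ISI scalar and (for trees) a BUI
scalar.  Both scalars are normalized so they approach 1 as the index
grows without bound: the printed coefficients 0.7568 and 0.8482 are the
scalar values at the reference BUIs 64 and 32, where the exponential
term is exactly 1.  Grass spread depends on ISI alone plus the green
fraction `r_green`; fully cured grass approaches $1.3\,v_{d,max}$.
Default maxima are 2.3 / 3.8 / 0.92 / 4.97 km h⁻¹ for needleleaf
evergreen, continental needleleaf, broadleaf, and grass PFTs.

Fires grow as ellipses: length $(v_d + v_u)\,\Delta t$ with
$\Delta t = 24$ h, breadth length/LB with
$LB(w) = 1 + 10(1 - e^{-0.06 w})$ (circular in calm air, saturating at
11).  The upwind rate defaults to $v_u = 0.2\,v_d$.  Both the LB form
and the upwind fraction are inherited from the precursor default fire
module and are isolated behind configuration, since only their
qualitative behavior is pinned by the source material.

The same-day extinction probability is
$q = 0.5 + 0.5\,(1 - e^{-\pi (p_d/p_{d,max})^{v}})$ with
$v = \ln(-\ln(1-e^{-\pi})/\pi) / \ln(p_{d,min}/p_{d,max})$ and defaults
$p_{d,min} = 0.001$, $p_{d,max} = 0.1$ persons km⁻², giving
$q(p_{d,min}) = 0.5216 \approx 0.5$ and $q(p_{d,max}) = 0.9784 \approx 1$.
With exponentially distributed fire duration the expected area per fire
is $a_r = a_1 (1-q)(2-q)/q^2$, and per-PFT burned area scales with cell
area and cover relative to the representative area:
$A_b = P_f\,a_r\,(A_g f_\alpha)/a_{rep}$.  We additionally cap $A_b$ at
the PFT extent $A_g f_\alpha$ — a safeguard for extreme parameter
corners that the source equations leave open.

## Carbon

Each burned fraction combusts pool carbon with per-PFT, per-pool
emission fractions (leaf, stem, root, litter, **and soil** — the soil
fraction is a bulk profile-average combustibility) and kills live
biomass into litter with mortality fractions; emitted carbon converts to
CO₂ by 44/12.  Only CO₂ is accounted.  The shipped
`inst/extdata/combustion.yaml` values are **synthetic placeholders**:
the calibrated tables live in supplementary material we do not
reproduce.  They preserve the qualitative ordering litter > leaf > soil
> stem ≈ root and respect emission + mortality ≤ 1 per live pool, and
every value can be overridden.  Carbon is conserved per event to
1e-12 relative, enforced by tests.

# The synthetic forcing generator

`scenario_config()` + `generate_forcing()` define the study conditions:
a 20 × 20 grid of 576 km² cells (comparable to a 0.22° grid) run for 50
years by default.  Each variable has a seasonal cycle, AR(1) noise, and
a linear secular trend, with one seeded RNG stream per variable so
adding or regenerating one never perturbs the others:

* temperature: mean 3 °C, seasonal semi-amplitude 18 °C (late-July
  peak), AR(1) sd 3.5 °C / φ 0.75, default trend **+4 °C per century**;
* relative humidity: mean 70 %, summer depression 12 %, coupled to the
  temperature noise anomaly at −1.2 % per °C (warm anomalies are dry),
  default trend −5 % per century, clamped to [2, 100];
* wind: mean 12 km h⁻¹, winter maximum, non-negative;
* rainfall: two-state wet/dry occurrence chain (persistence 0.55 / 0.25)
  with gamma wet-day amounts, summer maximum — dry spells, not drizzle,
  which is what the FFMC responds to;
* lightning: a heterogeneous lognormal cell climatology (median
  1.2 strikes km⁻² yr⁻¹) sharply concentrated in mid-summer, with unit-mean
  lognormal daily noise and default trend **+50 % per century**;
* population density: static lognormal field (median 0.02 persons
  km⁻², log-sd 2.5), optional multiplicative trend;
* a carrying-capacity multiplier trend stands in for CO₂
  fertilization's effect on biomass.

These defaults are chosen to put a boreal-like landscape in a regime
where summer dry spells reach FFMC ≈ 85–90 and a fraction of a percent
of the domain burns per year.  A minimal fuel dynamic closes the
fire–fuel feedback: pools relax exponentially toward carrying capacity
(e-folding 20–25 yr for tree live pools, 1 yr for grass, 10/100 yr for
litter/soil).  What the generator does **not** emulate: real spatial
correlation structure of weather, orography, fire-front weather
feedbacks, land-cover change, and observed forcing archives — so green
tests demonstrate correctness of the mechanisms, not skill against
observations, and the Mha-scale historical and future projections of the
source study are out of reach at this scale by design.

Factorial experiments hold a driver at its reference (first-year) level
by suppressing its trend while leaving every noise stream bit-identical;
that is exactly the contract `factorial_attribution()` relies on.

## Bias correction

`delta_correct_multiplicative()` rescales a lightning series per cell so
its long-term mean matches a target climatology — preserving relative
variability and conserving the cumulative total exactly, which is the
property the delta method is used for.  Cells with zero source
climatology but nonzero target cannot be rescaled and are flagged, not
guessed.  `delta_correct_additive()` offsets the mean instead and clamps
negative strike densities at zero, reporting the clamped mass.

# Experiments

`run_simulation()` spins up by looping the first years of forcing
(default 5 years, one loop — the FWI codes equilibrate within weeks and
pools start at capacity), then runs the transient period, accumulating
domain-wide annual burned area (km², Mha) and fire CO₂ (kg, Pg).

`factorial_attribution()` compares a full run against runs with one
driver fixed; driver contributions are
$(\Delta_{full}-\Delta_{fixed(d)})/\sum_d(\Delta_{full}-\Delta_{fixed(d)})$
with $\Delta$ the end-window minus reference-window mean (11-year
windows by default, mirroring decade-scale averaging).  A near-zero
denominator is flagged undefined rather than normalized.

`sensitivity_curves()` pools annual values across runs and reports, per
driver, the scatter, a tri-cube locally weighted smooth (span 0.75, the
conventional default — the source does not state one), and a linear
slope with confidence interval.  `ensemble_change_test()` applies
two-sided, *unpaired* two-sample t-tests per cell across ensemble
members (the pairing convention is not stated in the source; unpaired is
the conservative choice) and masks cells with p > α as "no change".
`partition_uncertainty()` splits projection variance across a two-factor
run matrix by ANOVA sums of squares (factor main effects, interaction,
residual).

# Numerical choices and edge cases

* BUI is zero when DMC is zero; for very small DMC with DC ≈ 0 the
  standard second branch can clamp to zero as well — we follow the
  standard rather than forcing strict positivity.
* Tree BUI scalars slightly exceed 1 between their reference BUI and
  infinity (by ≤ 4 × 10⁻⁶ / 2 × 10⁻⁵); we keep the printed equations
  rather than capping.
* The extinction exponent $v$ is precomputed once per parameter set; at
  population densities far above $p_{d,max}$, $q \to 1$ at double
  precision and the duration multiplier is exactly 0.
* Division by the PFT extent when converting burned area to burned
  fraction is guarded for zero-cover PFTs.
* Non-finite forcing anywhere aborts the run naming the variable, day,
  and cell.
* The simulator uses a 365-day no-leap calendar.

# Problem sizes

The test suite exercises the full study conditions (20 × 20 cells, 50
years, ~11 simulation runs) in its end-to-end checks and small grids
(2 × 2 to 4 × 4, 1–30 years) everywhere else; a single 50-year,
400-cell run takes well under a minute on one core.  These sizes were
chosen so the whole suite documents the package's behavior at realistic
scale while remaining comfortably runnable on a laptop.

# Known limitations

No crown/surface fire distinction, slope effects, sub-daily fire
growth, overwintering drought-code carryover, peat smoldering or
non-CO₂ species; vegetation dynamics are a single-pool relaxation, not
succession; the ignition combination rule, human-ignition exponent,
upwind fraction, and ellipse elongation constants are configurable
stand-ins pinned only by their endpoint behavior; and the combustion
parameter table is a labelled placeholder.
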