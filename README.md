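# borealfire

`borealfire` is an R package for process-based simulation of wildfire in
boreal and temperate landscapes: daily fire weather, fire occurrence,
elliptical fire spread, burned area, and fire carbon emissions on a
regular grid.  It is aimed at fire ecologists and carbon-cycle modellers
who want a transparent, testable, desk-scale implementation of an
FWI-driven fire module — for studying mechanisms, driver attribution,
and sensitivity — without coupling to a full land-surface scheme or
downloading forcing archives.

## The model in brief

Fuel dryness comes from the Canadian Forest Fire Weather Index (FWI)
system: the moisture codes FFMC, DMC, DC are stepped daily from maximum
temperature, relative humidity, wind, and rainfall, and combined into
the indices ISI (spread) and BUI (fuel buildup).

The daily probability of fire in a representative area
(a_rep = 800 km²) is the product of three conditional probabilities

    P_f = P_b · P_i · P_m

where P_b ramps linearly in aboveground biomass (0.2–1.0 kg C m⁻²),
P_m = logit⁻¹(−25.2 + 0.34·FFMC), and P_i combines a lightning ramp
(0.25–10 strikes km⁻² yr⁻¹) with a population-density ignition term
saturating at 300 persons km⁻².

Fires spread downwind at a PFT-specific rate
v_d = v_d,max · f(ISI) · g(BUI) (grass: ISI only, with a cured-grass
asymptote of 1.3·v_d,max), grow as ellipses with wind-dependent
elongation, and are extinguished each day with probability
q(p_d) ∈ [0.5, 1) driven by population density.  Expected area per fire
is a_r = a_1(1−q)(2−q)/q², and per-PFT burned area is
A_b = P_f · a_r · (A_g f_α)/a_rep.  Burned fractions combust carbon
pools (leaf, stem, root, litter, soil) with per-pool emission fractions
and transfer fire-killed biomass to litter; CO₂ = 44/12 × emitted C.

A seeded synthetic forcing generator (seasonal cycles, AR(1) noise,
secular trends, heterogeneous lightning/population fields) defines
reproducible study conditions; delta-method bias-correction utilities
(multiplicative and additive) adjust lightning series to a target
climatology; and experiment helpers run factorial driver attribution,
driver-sensitivity curves, per-cell ensemble t-tests, and ANOVA-style
variance partitions.  See the methods vignette
(`vignettes/borealfire-methods.Rmd`) for the full model description.

## Worked example

One hot, dry, windy July day from the conventional start-up codes:

```r
library(borealfire)
st <- fwi_step(fwi_initial(), tmax_c = 28, rh_pct = 35, wind_kmh = 18,
               rain_mm = 0, month = 7)
round(unlist(st), 2)
#>  ffmc   dmc    dc   isi   bui
#> 90.84 10.44 23.74 11.96 10.40
```

The fine fuel dries from FFMC 85 to 90.8 (P_m ≈ 0.997: moisture no
longer limits fire), and ISI ≈ 12 with BUI ≈ 10 gives a needleleaf
spread rate `spread_rate(11.96, 10.4, "needleleaf", 2.3)` ≈ 0.043 km/h
— fuel buildup is still low this early in the season.

A ten-year simulation on a small grid:

```r
cfg <- scenario_config(nx = 6, ny = 6, years = 10, seed = 42)
run <- run_simulation(cfg, spinup_years = 3)
run
#> <fire_run> 6 x 6 cells, years 2000-2009
#>   mean annual burned area: 0.1301 Mha;  mean fire CO2: 0.002163 Pg
head(tidy(run)[, c("year", "burned_area_mha", "co2_pg", "tmax_mean")], 3)
#>    year burned_area_mha  co2_pg tmax_mean
#> 1  2000           0.105 0.00179      2.92
#> 2  2001           0.117 0.00199      2.80
#> 3  2002           0.135 0.00224      2.84
```

About 0.13 Mha of the 20 736 km² domain burns per year (~0.6 % yr⁻¹, a
high-fire boreal regime) emitting ~0.002 Pg CO₂ yr⁻¹; interannual
variation follows the weather and lightning noise.  `autoplot(run)`
plots the annual series, `plot_burned_area_map(run)` maps mean burned
fraction, and `glance(run)` gives one-row totals including emission
intensity (kg CO₂ per m² burned).

Driver attribution compares a full transient run against runs with one
driver held at its reference-year level:

```r
full  <- run_simulation(cfg)
fixed <- list(
  climate   = run_simulation(cfg, fixed = "climate"),
  lightning = run_simulation(cfg, fixed = "lightning")
)
tidy(factorial_attribution(full, fixed))
```

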