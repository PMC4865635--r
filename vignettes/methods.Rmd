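---
title: "Simulating crop production and nitrate leaching in a maize-wheat double rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating crop production and nitrate leaching in a maize-wheat double rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropnsim)
```

## What the package models

`cropnsim` is a one-dimensional daily soil-vegetation-atmosphere simulator
for the intensive summer maize - winter wheat double crop rotation on the
deep silty loam soils of the North China Plain (NCP), where annual urea
dressings of 0-600 kg N/ha combine with 240-400 mm of irrigation on top of a
semi-arid monsoonal climate (330-600 mm rain, roughly 70% of it in
June-September).  The question the model serves is the classic
agro-environmental trade-off: how much fertiliser buys how much yield at
what cost in nitrate leached below the root zone.

One simulated column couples five process groups on a daily loop:

1. **Soil water** - Richards-equation flow on a finite-volume grid (2 cm
   cells to 60 cm, 5 cm to 170 cm, 10 cm to 210 cm), van Genuchten retention
   and Mualem conductivity per horizon, free-drainage ("deep groundwater")
   lower boundary, FAO-56 Penman-Monteith reference evapotranspiration
   partitioned between soil evaporation and crop transpiration by canopy
   cover.
2. **Soil temperature** - an analytic damped annual sinusoid (see
   "Numerical choices").
3. **Crop** - development stage DS (0 emergence, 1 flowering, 2 maturity)
   driven by temperature-modified daily rates; a saturating leaf
   light-response curve integrated over canopy layers and daylight hours;
   maintenance and growth respiration; DS-dependent assimilate partitioning;
   exponentially distributed roots; N uptake limited by root length, soil
   mineral N and DS-dependent organ N targets.
4. **Soil organic matter and N** - seven pools per cell (slow/fast native
   SOM plus an inert pool, slow/fast microbial biomass, slow/fast added
   organic matter) turning over by first-order kinetics with temperature,
   moisture and clay modifiers; mineralisation and immobilisation emerge from
   the C/N ratios of donor and receiver pools; nitrification with a small
   N2O by-product; denitrification scaled by the calibrated water-response
   table; ammonia volatilisation as a dressing-size-dependent fraction of
   applied urea.
5. **Solute transport** - implicit upwind convection-dispersion of NH4 and
   NO3 with linear NH4 sorption; the flux past the 2 m reference depth is
   the simulated nitrate leaching.

Alongside the simulator the package ships the two classical field
estimators (interval water-balance drainage `D = P + I + dSW - AET` and
concentration-weighted nitrate leaching `sum(D_i * c_i)`), the four
goodness-of-fit statistics (RMSR, mean deviation, Nash-Sutcliffe ME, R2),
one-at-a-time (plus/minus 10%) sensitivity analysis, and the
fertiliser-ladder scenario machinery that regresses post-harvest 0-2 m
soil mineral N against years to detect residual-N accumulation.

## Parameter provenance

The packaged "NCP" parameter set (`default_ncp_parameters()`) carries a
provenance tag on every component.  Values tagged `measured` or
`calibrated` come from the published field parameterisation (soil hydraulic
horizons for fields A and B, crop photosynthesis/partitioning scalars,
organic-matter fractions, deposition, the volatilisation set points).
Values tagged `default` are package choices for quantities the published
tables do not contain; they are all overridable in the config files.  The
important defaults, and why:

* **Pool rate coefficients and flow network.** The turnover network
  topology follows the standard slow/fast/microbial scheme of this model
  family.  Rates were fixed once so that a bare 1.5%-organic-matter topsoil
  column yields an annual net mineralisation of roughly 200 kg N/ha and
  heterotrophic respiration near 2 t C/ha - the magnitudes reported for
  comparable NCP silty loams - with the slow SOM pool on a multi-decade
  timescale and residues (AOM) on weeks to years.
* **DSRate2** (development rate after flowering) is not published; 0.020/d
  (maize) and 0.028/d (wheat) give maturity 6-8 weeks after flowering under
  NCP temperatures.
* **Organ N concentration targets** decline with DS (e.g. maize leaf 5.0%
  to 1.5% N) so that simulated harvest N falls in the observed 100-260
  kg N/ha range across the fertiliser ladder.
* **Soil C/N by horizon** is printed as ranges ("8-12"); single mid-range
  values (10, 11, 12, 12) are shipped.
* **Bulk density** (1.4 g/cm3) is typical for these silty loams and sets
  the absolute size of the organic pools.
* **Winter wheat over winter**: the development temperature response is
  zero below the base temperature, which stalls DS through the cold months
  and stands in for an explicit vernalisation model.

## Numerical choices

The Richards solver uses the mass-conservative mixed form with modified
Picard iteration and adaptive sub-daily stepping (initial 2 h, bounds
1e-4 h to 6 h, halving on failure).  Several choices matter for this
particular profile, whose saturated conductivity contrast spans a factor of
nearly 200 between the 40-110 cm horizon (22.3 cm/h) and the deep horizon
(0.12 cm/h), and whose van Genuchten `n` values (1.19-1.33) are low:

* **Chord-slope (secant) capacity** instead of the analytic derivative,
  robust across the saturated/unsaturated switch.
* **Geometric-mean interface conductivity**, stable under strong layer
  contrasts.
* **Air-entry regularisation of K** (solver-internal only): the Mualem
  curve for low `n` drops almost vertically just below saturation, which
  makes fixed-point iterations cycle; K is rescaled to reach its saturated
  value at h = -2 cm.  The exported `vg_conductivity()` is the exact
  closed form.
* **A small specific storage (1e-5 per cm) above saturation**, giving a
  strictly monotone head-storage relation.  Monsoon events perch a
  saturated mound on the deep low-K horizon with tens of cm of positive
  pressure; without genuine storage the pressure there is numerically
  indeterminate.
* **Implicit surface-limit treatment**: when the infiltration or
  exfiltration capacity binds, its derivative with respect to the surface
  head enters the matrix; treating it explicitly produces a flip-flop at
  ponding.
* **Flux-form water content update**: accepted substeps update stored
  water from the inter-cell fluxes themselves, so the discrete water
  balance closes to round-off by construction (verified to ~1e-13 mm/day),
  and heads are re-derived from storage so the state stays on the
  retention curve.  Head tolerance is 1e-6 cm with a 0.05 cm "soft accept"
  after the iteration limit - mass closure is unaffected by the tolerance,
  only the implicitness of the flux linearisation.

Solute transport is implicit upwind finite-volume with
dispersivity-times-velocity plus molecular diffusion; infiltrating water
enters solute-free (deposition is added to the surface cell explicitly) and
evaporating water leaves its solutes behind.  Upwind differencing adds
numerical dispersion of order half a cell width, which is small against the
5 cm dispersivity; the centre of mass of a pulse travels at the pore-water
velocity to within 2% (tested).

The soil temperature profile is the classical damped-sinusoid solution of
the conduction equation rather than a discretised PDE: its only consumers
are the turnover rate modifiers, which need the annual cycle and its damped,
phase-lagged propagation to depth, not day-to-day transients.  The damping
depth default (180 cm) is typical of moist loam.

Tillage mixes pools and mineral N uniformly over the tilled depth.
Irrigation enters the surface flux identically to rain.  Ponding excess
that cannot infiltrate is reported as runoff, never silently dropped
(the water-balance estimator's "no surface runoff" assumption is the
field's, not the simulator's).

## The synthetic weather generator

No daily station series is distributable, so fixtures pair the recorded
management patterns with a seeded synthetic generator that emulates the
station climate: annual totals drawn uniformly from 330-600 mm with fixed
monthly fractions placing 72% in June-September, wet-day occurrence and
gamma amounts rescaled to the drawn monthly totals, a sinusoidal
temperature cycle (annual means 11.8-13.2 degC, amplitude 14.5 degC,
peak mid-July) with AR(1) daily noise, radiation as clear-sky
transmissivity reduced on wet days, and higher humidity on wet days.  What
it does not reproduce: multi-day synoptic persistence, dry spells with
realistic duration statistics, extreme single-day storms beyond the gamma
tail, or any correlation between years.  Passing tests therefore show the
process chain behaves correctly under realistic forcing statistics, not
that any specific observed year is reproduced - the published daily
validation statistics depend on unpublished station data and are out of
scope here.

## Study conditions used by the shipped checks

The conservation and pattern checks run a 2-year field-A rotation (N400,
80% straw incorporation, synthetic weather seed 7); the fertiliser ladder
uses 6 rates from 0 to 600 kg N/ha over 5 years (seed 11).  The Richards
inner loop is compiled (Rcpp); these sizes keep a full check run on a
single CPU within a few minutes while spanning
two full rotation cycles and a trend long enough for the residual-N
regression (10 post-harvest samples per scenario).  The warm-up facility
(`warmup_years`) exists because net mineralisation is sensitive to the
initial pool distribution; the warm-up effect is itself verified by a test.
By default warm-up years run the same cropped management; the published
annual warm-up C inputs (1550/800 kg C/ha/y) can be switched on instead
(`warmup_c_input = TRUE`) for bare warm-ups - applying both would double
count residue carbon.

## Known limitations

* No macropore or preferential flow, no hysteresis, no 2-D effects; a
  single calibrated retention curve set serves both fields.
* The crop model has no photoperiod response, pests, or CO2 response;
  vernalisation is only implicit.
* Organic pools use fixed receiver C/N targets (horizon C/N for native SOM,
  4.8 for microbial biomass); donor pools carry their actual C/N.
* Ammonium concentrations in leachate are small but not identically zero;
  the leaching output follows nitrate, as the field estimator does.
* The regional upscaling of the original study (gridded soils, county
  yields) is out of scope.
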