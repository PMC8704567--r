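---
title: "Reconstructing wind-borne moth migration: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing wind-borne moth migration: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothwind)
```

## The problem

Fall armyworm moths (and noctuids generally) migrate at night by climbing to
a few hundred to a couple of thousand metres, where a low-level jet carries
them downwind at 10 m/s or more. When such a pest is first trapped on an
island, the origin of the immigrants can be inferred by integrating the
flight *backwards* through a gridded reconstruction of the atmosphere,
subject to what is known about the insect's behaviour. `mothwind` packages
that inference: a meteorological-field container and interpolator, the
behavioural rules as pure functions, a forward/backward trajectory engine
with stepping-stone chaining, an endpoint-validity filter with per-migration
summaries, and a nocturnal wind climatology with downdraft diagnostics.

## The transport model

The moth is treated as a point particle whose ground velocity is the local
wind plus a fixed self-powered airspeed aligned exactly downwind (no heading
offset):

$$\mathbf{v}_g = \mathbf{v}_w + a\,\hat{\mathbf{v}}_w, \qquad a = 3.0\ \mathrm{m\,s^{-1}}.$$

In near-calm air (wind speed under `calm_threshold`, default 0.1 m/s) the
downwind heading is undefined, so the self-powered vector is suppressed
rather than given an arbitrary direction. Backward integration negates the
*full* ground velocity - the assumption being that the moth also flew
downwind in the past.

Positions advance with a midpoint (second-order Runge-Kutta) step, default
`step_s = 300` s, converting metres to degrees on a sphere of radius 6371 km
with the cos-latitude metric. Altitude is held constant above ground level
for a whole leg: launch altitude is treated as a parameter of the candidate
set, not a dynamical variable, and vertical air motion is carried only as a
diagnostic (see "Downdrafts" below). The atmosphere is sampled by
quadrilinear interpolation - trilinear in (level, latitude, longitude),
linear in time between the two bracketing frames - with *no extrapolation*:
a query outside the grid is an explicit signal that the engine records as a
`domain_exit` termination rather than a silent clamp.

The integrator was checked against closed forms (a 10 h flight in a uniform
10 m/s wind must cover 13 m/s x 36 000 s = 468 km along the wind) and
against forward/backward inversion on smooth fields; the test suite runs
both, plus a step-halving convergence check.

## Behavioural rules and their constants

All constants live in `flight_params()` and are surfaced through the YAML
config, so the standard parameterisation is the zero-config behaviour:

| parameter | default | meaning |
|---|---|---|
| `airspeed` | 3.0 m/s | self-powered flight speed, added downwind |
| `t_min` | 13.8 °C | flight prohibited strictly below this temperature |
| `takeoff_local` | 19:00 | dusk take-off, local mean solar time |
| `dusk_local`, `dawn_local` | 20:00, 05:00 | nocturnal window used for release hours and climatology |
| `nightly_max_h` | 12 h | cap on continuous over-land flight per night |
| `max_nights` | 3 | consecutive flight nights (bookkeeping limit) |
| `oversea_max_h` | 36 h | hard cap on a single over-sea flight |
| `max_legs` | 2 | chained flights in the stepping-stone reconstruction |
| `altitudes_m` | 500…2250 m | eight candidate launch altitudes |
| `takeoff_tolerance_h` | 1 h | half-width of the accepted departure-time window |
| `step_s` | 300 s | integration step |

Three readings deserve justification:

**The temperature boundary is inclusive.** The gate prohibits flight when
the air *falls below* 13.8 °C; equality therefore permits flight. The gate
is applied pointwise at every step, and a leg that would enter colder air
terminates at the last warm point with reason `"cold"` - no recorded
in-flight point is ever below the gate.

**Nightly duration over land.** The rules state both a 12 h nightly flight
capacity and a dusk-to-dawn (~10 h) window. We reconcile them as: over land,
flight ends at min(nightly cap, dawn). With the default constants the dawn
window binds; the 12 h cap matters only for configurations that suspend dawn
landing (both constants remain settable, so either reading is obtainable).

**Local mean solar time, carried with the moth.** Clock times use
`local = UTC + lon/15 h` rather than civil zones, because trap sites and
candidate sources span several zones while the behavioural rules are stated
as round local clock times. More subtly, dusk and dawn are evaluated at the
moth's *current* longitude: a moth flying east meets dawn early, one flying
west meets it late. This makes the forward dawn-landing rule and the
backward take-off rule exact mirrors (the backward integrator stops at the
instant the local clock at its position crosses 19:00 over land), which in
turn makes forward and backward reconstructions of the same flight agree.
When a leg crosses a dusk/dawn instant, the engine takes an exact partial
step onto the crossing time, so endpoint positions converge at second order
in the step instead of inheriting O(step) quantisation; durations are
reported from actual timestamps.

## The backward reconstruction

For an arrival site and arrival night, `run_backward_fan()` launches one
backward leg per nocturnal release hour (hourly, 20:00-05:00: 10 hours) and
candidate altitude (8), i.e. 80 candidates per night. Release time is a
*landing* hypothesis: the moth is assumed to have been at the trap site at
that hour.

Each backward leg integrates until it reaches a 19:00-local crossing over
land (reason `dawn_landfall`, the take-off boundary), or fails through the
cold gate, the 36 h cap, or a domain exit. `run_multileg_backward()` then
treats every leg whose endpoint is a plausible take-off (on land within
±1 h of 19:00 local) as the landing site of a *previous* flight, groups such
endpoints by mask grid cell, and launches one second backward fan per cell
across the preceding night's hourly landing times. Chaining stops at
`max_legs` (default 2, the archipelago mode).

Endpoint validity (`endpoint_valid()`) requires: (a) a terrestrial endpoint,
with a two-tier host flag - the default lenient tier accepts any land, the
strict tier requires the host-crop raster, reflecting the disjunctive "host
planting region or at least terrestrial" criterion; (b) departure time
within the tolerance of 19:00 local; (c) a termination other than `cold` or
`domain_exit`. Counts of valid trajectories are counts of distinct
(release hour, altitude) pairs per leg - and per stopover cell for chained
legs. Legs are *named* chronologically: the leg nearest arrival is the
"second migration", the preceding leg the "first", matching how a two-wave
event is described even though the arrival leg is computed first.

Duration summaries report the arithmetic mean and the sample (n−1) standard
deviation; the dispersion estimator behind "±" values is a convention choice,
so the standard error is exposed alongside. A single valid leg reports SD 0
with a `degenerate` flag.

## Synthetic weather and ground truth

Nothing in the pipeline requires external data. The generator module builds:

- **uniform fields** (every sample a constant - the oracle substrate),
- **layered fields** (level-wise constant winds, linearly blended between
  levels, with an optional cold cap above a given height),
- **downdraft fields** (ω equal to a peak value inside a time window over a
  mid-level band, zero outside),
- **monsoon scenarios**: a steady jet from a circular source island towards
  an arrival site, optionally through a stopover island, plus the implied
  ground truth (take-off time, expected arrival night, leg count).

Scenario winds are *smooth*: a steady jet with ±2 % vertical shear, a short
monsoon-onset ramp confined to the first hours of the field (before any
simulated flight), and one small-amplitude (0.15 m/s) seeded space-time
sine mode per component. Smoothness is deliberate - the inference operates
on synoptic-scale flow, and smooth fields admit closed-form oracles. The
generators are pure functions of their arguments including the seed.

Scenario geometry is chosen so the truth is *feasible by construction*: the
islands sit at the nominal dawn positions of each night's flight, where a
night's range is `(jet + airspeed) x window / clock_rate` - the clock-rate
factor accounts for the moving-dawn convention (an eastbound moth's night is
slightly shorter than 10 h). The corridor defaults to a Torres Strait-like
arrival at (142.6°E, 9.4°S) with the source a few hundred kilometres upwind,
so desk-scale runs finish in seconds to tens of seconds. Island radii are
kept *below one release-hour of drift* (25-35 km against ~54 km/h ground
speed); larger islands would let a backward leg stop one hour out on the
very island it was released over, manufacturing spurious short "migrations".
Explicit geometries are validated against the flight caps and rejected as
infeasible otherwise.

What the scenarios do **not** emulate: mass-conserving/balanced flow,
turbulence, tropical-cyclone structure, rain fields, terrain (the surface is
flat; AGL equals altitude above a reference plane), and civil time zones.
Passing the recovery tests therefore shows the *inference machinery* is
correct under the stated behavioural model - not that real reanalysis fields
or real moths satisfy the model's assumptions.

## Climatology and downdrafts

The nocturnal wind climatology samples each site at the heights of the
800-900 hPa levels (hypsometric conversion with a 288 K layer-mean
temperature, the same default used to map pressure-level input files onto
the canonical height coordinate; 850 hPa sits near 1.5 km). For each
(site, level, nightly hour, year, month) stratum the wind *vector* is
averaged over the month's nights and yields one sample, so a monthly
histogram over 3 sites x 5 levels x 10 hours x 10 years holds exactly 1500
points; raw per-night sampling is available behind `monthly_mean = FALSE`.
Directions follow the meteorological from-convention
(`atan2(-u, -v)`, westerly = 270°) and fall into sixteen half-open 22.5°
bins centred on the compass points, boundaries promoting to the higher
sector. "Westerly" style groups are configurable sector sets
(`sector_group_stats()`), since a pooled WSW/W/WNW reading and a single-W
reading are both defensible.

Vertical pressure velocity ω (Pa/s, positive descending) is profiled on a
time x level grid and scanned for downdraft events: maximal intervals where
any level meets the threshold, 0.3 Pa/s by default and *inclusive* at the
boundary (with a 1e-9 numerical guard). Each event converts its peak to a
vertical air speed via the hydrostatic relation
$w = -\omega R_d T/(p g)$; at 850 hPa and 288 K, ω = 0.5 Pa/s gives
|w| ≈ 0.05 m/s, two orders below the 3 m/s airspeed, which is the
quantitative form of the conclusion that downdrafts of this size cannot
force a moth down.

## Numerical choices and problem sizes

- Interpolation indices are computed arithmetically on regular axes and via
  `findInterval` otherwise; the two paths are tested against a brute-force
  cell-local oracle.
- The land mask is queried nearest-cell at every step; mask resolution
  matches the met grid (0.25° in the scenarios).
- Ties and boundaries: 13.8 °C permits flight; ω exactly at threshold is an
  event; a direction on a sector boundary belongs to the higher sector;
  release exactly at a clock instant does not immediately terminate a leg.
- Degenerate inputs fail loudly: non-monotone coordinates, degenerate
  extents, infeasible scenario geometry, empty duration summaries.
- Test problem sizes were chosen to keep the default suite in tens of
  seconds on one core: scenario grids of ~0.25° x ~100 hourly frames x 10
  levels, 80-leg fans, 100-trial inversion checks at a 60 s step, and
  ten-year climatology fixtures built from uniform January fields.

## Known limitations

- Altitude is constant per leg; moths choosing or changing flight height,
  and vertical advection by ω, are out of scope (ω is diagnostic only).
- Rain is carried in the data model but no quantitative rain-landing rule is
  applied.
- The hypsometric pressure/height mapping uses a constant layer-mean
  temperature (configurable), not the field's own temperature profile.
- Backward validity counts depend on the mask resolution through the
  nearest-cell surface lookup and the stopover cell grouping.
- Local mean solar time is an idealisation of dusk/dawn; civil twilight at
  these latitudes differs by some tens of minutes, absorbed in practice by
  the ±1 h take-off tolerance.
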