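---
title: "Building Holocene-to-2100 climate drivers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building Holocene-to-2100 climate drivers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoclim)
```

`holoclim` assembles a continuous climate driver — precipitation,
temperature, potential evapotranspiration (PET) and net rainfall at
monthly or weekly resolution — spanning 12,000 historical years and a
100-year projection horizon, for use as driving data in peatland
ecohydrological models. This vignette explains the statistical model at
each stage, the parameters that matter, the numerical choices, and what
the package's tests do and do not demonstrate.

## Timeline and calendar

Year 1 of a default driver is 10,000 BCE and year 12,100 is 2100 CE;
2000 CE (series year 12,000) is treated as the present, and paleo ages
are counted back from it (0 BP = 2000 CE). Calendar years in driver
files use astronomical numbering, so BCE years are negative.

All simulated years have 365 days. Leap days would complicate a
12,100-year bookkeeping for no benefit at this resolution, and the
day-length scaling of PET assumes a 365-day Julian cycle anyway.
Observation records, in contrast, carry real dates: leap days are
folded onto February 28 when days are mapped to the 365-day seasonal
phase, and observed days are grouped by their true calendar month.

The weekly calendar is fifty-one 7-day weeks plus a final 8-day week.
The alternative — discarding day 365 — would silently lose
precipitation; with this construction interval day counts sum to 365
and annual precipitation totals are conserved exactly (to floating-point
rounding) under aggregation. For even-length intervals the lower middle
day serves as the median Julian date, a deterministic tie-break.

## The stochastic weather generator

The generator follows the semi-empirical histogram tradition of station
weather generators.

**Occurrence.** A day is wet when precipitation exceeds
`wet_threshold_mm` (default 0.1 mm, the usual trace-rain convention;
the threshold is configurable because station practice varies). The wet
record is decomposed into alternating dry and wet spells; each spell is
attributed to the month in which it starts, and per-month spell-length
distributions are stored as histograms with up to 23 bins. When a month
exhibits at most 23 distinct spell lengths each length gets its own
unit-width bin, making the histogram exactly the empirical
distribution; otherwise 23 equal-width bins cover the range and
sampling is uniform within a bin, rounded back to whole days.
Simulation draws alternating spells from the distributions of the
current day's month, so simulated occurrence reproduces the monthly
wet-day climatology without modelling day-to-day persistence beyond the
spell structure.

**Amounts.** Wet-day precipitation is drawn from a per-month empirical
quantile function: linear interpolation between order statistics at
plotting positions `(i − 0.5)/n`, clamped at the extremes. This scheme
preserves the training sample's mean exactly in expectation and never
extrapolates beyond the observed range. A month whose spells were all
inherited from neighbouring months (no wet day of its own) falls back
to the all-month distribution.

**Temperature.** tmin and tmax are modelled as normal with seasonal
mean and standard deviation conditioned on the day being wet or dry.
Seasonal means are third-order finite Fourier series (a constant plus
three cosine and three sine harmonics) fitted by least squares to the
conditioned daily data. Seasonal standard deviations are fitted the
same way but on month-grouped residual standard deviations evaluated at
month mid-dates, then smoothed by the same order-3 basis — daily
residual spread is too noisy to fit directly, monthly grouping is not.
The sd curve is clamped below at 0.05 °C so it stays strictly positive.
Residuals are standardised and given an AR(1) structure with the fitted
lag-1 autocorrelation; tmin and tmax innovations are drawn jointly with
their fitted cross-correlation. If a draw still yields tmin > tmax the
day's innovations are redrawn (up to 100 times, then the pair is
swapped). Redraws are day-local: the AR state consumed by subsequent
days is the original chain, which keeps simulation vectorised; because
the residual cross-correlation is typically high, violations are rare
and the approximation is negligible.

**Degenerate inputs.** An all-dry record yields an all-dry generator. A
month with zero wet days across all years triggers a warning and a
point-mass dry model: no wet spell ever starts there (spells from
adjacent months may still run a few days in). Constant-temperature
records fall back to constant curves with a floor on the sd.

**What is not modelled.** Cross-variable correlation beyond wet/dry
conditioning (e.g. amount–temperature dependence), multi-day amount
persistence, and any variable beyond precipitation and temperature.
These omissions match the driver's purpose: peatland models consume
interval aggregates, which are insensitive to sub-monthly fine
structure.

## Scenario modulation

Per-interval scalers between the baseline climatology and a future
period's climatology are additive for temperature and relative for
precipitation — the only dimensionally consistent reading, since a
relative precipitation delta must multiply. The temperature delta is
signed: a literal absolute difference would forbid projected cooling,
and nothing downstream requires it.

Scaler sets for successive periods (conventionally decade-stepped
20-year windows, 2021–2040 … 2081–2100, which overlap by construction)
are interpolated across projection years with an interpolating natural
cubic spline per interval: a zero-valued anchor at projection year 0
(2000 CE) enforces a smooth ramp out of the unmodulated baseline, each
period contributes a knot at its midpoint year, knots are reproduced
exactly (zero smoothing, so the knot property is testable), and beyond
the last midpoint the trajectory is held constant. With fewer than four
knots the natural spline degenerates gracefully towards a line, so
sparse scaler tables are interpolated at reduced order rather than
rejected. The trajectory is evaluated once per projection year and held
constant within the year for each interval; evaluating per sub-annual
step would imply sub-annual knot information the scaler tables do not
contain. Each interval is interpolated independently, so the projected
reshaping of seasonality survives interpolation. Spline overshoot that
would drive a relative precipitation delta to −1 or below is clipped to
−0.999 with a warning, preserving non-negative precipitation.

## Paleoclimate modulation

The site's anomaly series is the one whose 1° grid cell contains the
site coordinates, half-open on the upper edges so a site exactly on a
lower-left corner belongs to that cell; neighbouring sites in one cell
share a series. The 13 millennial knots are downscaled to yearly
resolution with the same natural-spline interpolator (smoother than a
linear interpolation, exact at knots). The anomaly is treated as
annual: every interval within a year receives the same value, because
millennial-scale pollen reconstructions carry one anomaly series per
variable, not a seasonal cycle. Temperature anomalies add directly.
Daily precipitation anomalies (mm day⁻¹) are converted per interval by
the interval's day count `D_n` — rather than a flat 365/N — so a
constant anomaly adds exactly 365 × dP mm over any year regardless of
the calendar. Modulated precipitation is floored at zero and the number
of floored cells is reported; with realistic anomaly magnitudes floors
touch only the driest cells of the early Holocene.

## Potential evapotranspiration

The Thornthwaite formulation needs only temperature, which is the
decisive advantage at Holocene time scales where radiation, humidity
and wind are unavailable. The annual heat index is computed from each
calendar year's own interval temperatures (the series is year-resolved;
a climatology-based index would smooth interannual PET variability),
with the `12/N` factor making the index independent of the interval
count. Sub-zero interval temperatures contribute nothing to the heat
index and produce zero PET, the standard convention for cold-climate
applications of the method — without it, Holocene winters would make
the equations undefined. The day-length correction uses the degree-form
solar declination approximation; the arccos argument is clamped to
[−1, 1] so polar latitudes yield 0 h or 24 h days instead of domain
errors.

One numerical subtlety: annual PET is strictly increasing when a whole
year warms uniformly, but warming a *single* interval can decrease
annual PET by a hair (well under 0.1 %), because the larger heat index
slightly deflates the other intervals' PET. This is a property of the
Thornthwaite equations themselves, not of the implementation; the test
suite asserts the uniform-warming monotonicity strictly and bounds the
single-interval effect.

## Pipeline, seeding and provenance

The assembled driver simulates the baseline in one continuous run, then
modulates years 1–12,000 with the paleo anomaly and the final 100 years
with the scenario trajectory. The junction is continuous by
construction: the anomaly's 0 BP knot is (by convention of anomaly
products) approximately zero, and the scaler trajectory is
zero-anchored at the same epoch. PET is computed after all modulation —
from the climate the peatland model will actually see — and net
rainfall is the elementwise difference.

The baseline simulation is the pipeline's only stochastic stage and
consumes the run seed directly, so an assembled driver is bit-identical
to chaining the stages by hand with the same seed, and a driver file
plus its YAML sidecar (site, seed, configuration) suffices to reproduce
the run. Fitting, interpolation and PET are deterministic.

## The synthetic fixtures

The observation fixture draws per-month Bernoulli wet days, gamma
wet-day amounts and a sinusoidal seasonal temperature cycle with iid
normal noise and a constant diurnal range, on the real calendar.
Defaults emulate a wet oceanic Scottish Highlands climate: annual mean
8.5 °C, seasonal amplitude 5.5 °C, winter-wet occurrence (0.44–0.62),
gamma amounts averaging 4.7–7.4 mm, diurnal range 6 °C, daily noise
1.5 °C — about 1150 mm of precipitation per year. Every monthly
statistic is analytic, so generator fits can be scored against known
truth. What the fixture deliberately lacks: heavy-tailed extremes,
amount autocorrelation, wet/dry temperature contrasts and
interannual modes. Passing recovery tests therefore demonstrates that
the fitting and simulation machinery is unbiased for a climate with
known structure — not that the generator captures every property of
real station records. Tiny wet amounts are lifted to just above the
0.11 mm floor so the fixture's wet days coincide with the generator's
default threshold; the effect on monthly means is well below the test
tolerances.

The anomaly fixture's `"holocene_like"` preset follows the qualitative
shape of northern-European pollen reconstructions — about −4.3 °C and
−0.9 mm day⁻¹ in the early Holocene, a mid-Holocene wet period peaking
near 3–4 ka BP, near-zero at present. The scaler fixture ramps linearly
from zero to a configurable end state across seven decade-stepped
periods.

## Test problem sizes and tolerances

The recovery and consistency tests use a 20-year training fixture,
1000-year evaluation simulations, and one full 12,100-year monthly run
for the null-modulation identity — sizes at which Monte-Carlo error is
comfortably below the asserted bounds while the whole suite runs in
about a minute. Simulated-versus-training comparisons use the bounds
2 percentage points (monthly wet-day frequency), 5 % (mean wet-day
amount) and 0.3 °C (monthly mean temperature); recovery of the
fixture's true parameters is asserted at 3-sigma Monte-Carlo bounds
that account for the 20-year record's own sampling noise, which
dominates the error budget for occurrence and amounts. Spline knot
reproduction is exact to 1e−12 and linear-knot reproduction to 1e−9;
PET components match independent re-evaluations to 1e−9 relative
error.

## Known limitations

- Temperature-only PET inherits the Thornthwaite method's biases
  outside temperate oceanic climates, and its fixed empirical constants.
- The paleo anomaly is annual; any Holocene change in seasonality is
  not represented.
- The generator assumes stationarity of spell structure and residual
  variance across the whole run; only means are modulated.
- Past and future modulations are interpolated separately and joined at
  2000 CE; a single interpolation across the junction would guarantee
  smoothness of derivatives as well as of values.
- The grid-cell lookup is containing-cell only; no spatial interpolation
  between anomaly cells is attempted.
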