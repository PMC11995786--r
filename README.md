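# holoclim

Continuous, site-specific climate driver series for peatland
ecohydrological models — 12,000 years of Holocene climate plus 100 years
of projected future climate, at monthly or weekly resolution.

Process-based peatland models (DigiBog, HPM, MPEAT and relatives) need
gap-free series of precipitation, temperature and potential
evapotranspiration (PET) from a peatland's initiation to the end of a
future scenario. Such combined past-and-future site-specific data is not
available off the shelf. `holoclim` builds it from three inputs a
practitioner can actually obtain:

1. **Daily station observations** (date, precipitation, min/max
   temperature) — at least one year, ideally ten or more;
2. **A gridded Holocene anomaly table** (1° cells, 1000-year knots of
   temperature and daily-precipitation anomalies, 0–12 ka BP), such as a
   pollen-based European reconstruction;
3. **Per-period delta-change scaler tables** for future scenarios
   (e.g. SSP-based decadal periods 2021–2040 … 2081–2100), either
   computed from baseline/future climatologies or supplied directly.

A synthetic-fixture module emulates all three, so the full pipeline runs
and is tested without any download.

## Method

**Stochastic baseline.** A weather generator in the semi-empirical
histogram tradition is fitted to the daily record: per-month dry- and
wet-spell length distributions (23-bin histograms, a spell belonging to
the month it starts in), per-month empirical quantile functions for
wet-day amounts, and wet/dry-conditioned normal models for tmin and tmax
whose seasonal mean and standard deviation follow third-order finite
Fourier series over the 365-day year, with lag-1 autocorrelated
residuals. Simulation alternates dry and wet spells and draws
temperatures jointly, producing arbitrarily many 365-day years with the
training record's statistical structure.

**Sub-annual aggregation.** Daily series are reduced to `N = 12` months
or `N = 52` weeks (fifty-one 7-day weeks plus one 8-day week, so the
year's 365 days — and its precipitation mass — are conserved exactly):
precipitation is summed, temperature `(tmin + tmax)/2` is averaged.

**Paleoclimate modulation (years 1–12,000).** The anomaly series of the
1° cell containing the site is downscaled from its 13 millennial knots
to yearly resolution with an interpolating natural cubic spline (knots
reproduced exactly), then added piecewise: temperature additively,
precipitation as `dP · D_n` mm per interval (floored at zero), with
0 BP identified with 2000 CE.

**Scenario modulation (years 12,001–12,100).** For each sub-annual
interval `n`, scalers are computed between the baseline climatology
`X̄_n` (the per-interval mean over years) and each future period's
climatology:

- temperature: `ΔT_n = T̄_n,future − T̄_n,base` (additive, signed);
- precipitation: `ΔP_n = (P̄_n,future − P̄_n,base) / P̄_n,base` (relative).

The per-period scalers are spline-interpolated across projection years
(zero-anchored at year 0 = 2000 CE, one knot per period midpoint, held
constant past the last knot) and applied elementwise to the final 100
baseline years: `T′ = T + ΔT`, `P′ = P · (1 + ΔP)`. Interpolating each
interval independently preserves the projected change in seasonality.

**PET and net rainfall.** PET uses the Thornthwaite method generalised
to arbitrary intervals: annual heat index
`I = Σ (max(t_n,0)/5)^1.514 · (12/N)`, exponent
`a = 675·10⁻⁹I³ − 771·10⁻⁷I² + 1792·10⁻⁵I + 0.49239`, unscaled
`PET_n = 16 (10 t_n / I)^a`, corrected by day length and interval length
`PET′_n = PET_n · (L_n/12) · (D_n/30)`, where
`L_n = (24/π) arccos(−tan lat · tan δ_n)` and
`δ_n = 23.45 sin((J_n − 81) · 360/365)` at the interval's median Julian
date. Net rainfall is `precipitation − PET`, the water-balance driver
peatland models consume.

## Worked example

```r
library(holoclim)

params <- synth_weather_params()                    # oceanic Highland-like fixture
obs    <- make_synthetic_obs(params, n_years = 20, seed = 42)
site   <- site_meta("Altnaharra", lat = 58.288, lon = -4.442, elevation_m = 81)
grid   <- list("-5,58" = make_synthetic_anomaly("holocene_like", cell = c(-5, 58)))
scalers <- make_synthetic_scalers(dT_final = 2.4, dP_rel_final = -0.036)

driver <- assemble_driver(obs, site, grid, scalers, seed = 1)
print(driver)
#> <climate_driver> Altnaharra: 12100 years x 12 intervals (-9999 to 2100, seed 1)
#>   annual means: precip 1185 mm, temp 7.75 C, PET 603 mm, net 581 mm

write_driver(driver, "altnaharra_ssp245.csv")       # + .meta.yaml sidecar
```

The driver spans year 1 = 10,000 BCE to year 12,100 = 2100 CE. The
whole-run annual means reflect the full Holocene: temperature sits below
the modern 8.5 °C fixture mean because the early Holocene is up to
4.3 °C colder, and PET (603 mm yr⁻¹) tracks temperature. The final
century responds to the scaler ramp — here +2.4 °C and −3.6 %
precipitation by 2081–2100:

```r
mean(rowSums(driver$pet$values[11901:12000, ]))     # recent century: 620.7 mm/yr
mean(rowSums(driver$pet$values[12091:12100, ]))     # 2090s: 677.1 mm/yr (+9.1 %)
```

A command-line interface (`inst/scripts/holoclim`) exposes every stage
(`fit`, `generate`, `scalers`, `scenario`, `paleo`, `pet`, `pipeline`)
over delimited text files with a YAML config; see `?cli_main`.

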