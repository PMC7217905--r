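# coralba

Reconstructing terrigenous **sediment-load histories from massive coral
cores**, for coral sclerochronologists and coastal paleo-environmental
scientists. Skeletal Ba/Ca in *Porites* tracks dissolved barium, which in
river-fed bays is dominated by Ba²⁺ desorbed from fluvial sediment in the
low-salinity estuary; skeletal Sr/Ca tracks SST and supplies the clock.
From depth-resolved proxy profiles the package builds the full analysis
chain:

1. **Chronology** — winter/summer tie points pair Sr/Ca extrema with SST
   extrema (Sr/Ca maximum ↔ coolest month; February/August climatology
   before the instrumental record); a piecewise-linear age model
   (constant growth between ties) resamples every proxy to a monthly grid.
2. **Decomposition** — a Gaussian frequency-domain filter,
   W(f) = exp(−ln2 (f/b)²) with b = 0.00137 cycles/day (half amplitude at
   a 2-year period), splits the Ba/Ca series into a low-pass
   (multidecadal) component and its exact complement, the detrended
   (< 2-year) component, after excluding the tissue layer (4.1 mm ≈ 5.1
   months at 9.6 mm/yr).
3. **High-peaks** — months where the detrended series exceeds the mean of
   its mean seasonal cycle (MSC), runs collapsed to their highest month,
   matched against documented flood/typhoon catalogues with lags of 0–4
   months, and counted per period.
4. **SiZer** — Gaussian-kernel local-linear slopes across 2–25-year
   bandwidths classify each (bandwidth, year) cell as significantly
   increasing/decreasing and extract multidecadal trend-shift intervals.
5. **Growth** — annual extension (distance between successive Sr/Ca
   maxima), annual mean density, calcification = extension (cm) × density
   (g/cm³), and their per-period correlation with the low-pass Ba/Ca.
6. **Mixing** — the estuarine Ba–salinity line (river and marine
   endmembers) and the coral Ba/Ca ↔ seawater Ba conversion
   (Ba_sw = Ba/Ca × 10.28 mmol/kg Ca; 3.8 μmol/mol ↔ 39.1 nmol/kg).

A forward simulator (`simulate_core()`) generates virtual 46-year cores —
seasonal SST, thermometer proxies, a rise–fall–rise multidecadal Ba
forcing with a mid-1990s trough, September-peaking seasonality, lagged
exponential flood spikes, and instrument-level noise (RSD 2.24 % Ba/Ca,
0.17 % Sr/Ca, 0.73 % Mg/Ca) — with a truth bundle, so every stage is
validated against known answers. See `vignettes/coralba-methods.Rmd` for
the model details and design choices.

## Worked example

```r
library(coralba)
p <- run_pipeline(list(simulate = TRUE), seed = 42)
p
#> coralba pipeline result
#>   tie points: 92 (mean extension 9.66 mm/yr)
#>   high-peaks: 76 (A: 44, B: 32)
#>   consensus trend shift: 1992-1998 (decrease_to_increase, 13 bandwidths)
#> Ba-salinity mixing fit: Ba = 119.64 -2.308 * S (nmol/kg)
#>   r = -0.993, p = 1.67e-12, n = 14; marine endmember (S=35) = 38.9 nmol/kg
```

92 tie points date 46 years of skeleton; the recovered mean extension
(9.66 mm/yr) sits within noise of the simulated 9.6 mm/yr. Of the 76
detected high-peaks, 44 fall in the A-period (pre-1996) and 32 in the
B-period. The SiZer consensus places the one unambiguous trend shift —
significant decrease turning into significant increase — in the 1992–1998
interval, bracketing the simulated 1995/96 trough. The water-sample fit
recovers the simulated mixing line (slope −2.3 nmol kg⁻¹ per salinity
unit, river endmember 120 nmol/kg), and its marine endmember (38.9
nmol/kg) agrees with the coral-derived seawater Ba
(`coral_to_seawater_ba(3.8)` = 39.1 nmol/kg).

Matched events show the configured lags, e.g. the simulated October 2010
flood appears as a February 2011 peak (4-month lag):

```r
tidy(p$event_matches)[, c("event_year", "event_month",
                          "peak_year", "peak_month", "lag_months")]
#>   event_year event_month peak_year peak_month lag_months
#> 1       1977           6      1977          9          3
#> 2       1990           9      1990          9          0
#> 3       1991           8      1991         10          2
#> 4       2010          10      2011          2          4
```

Individual stages are plain functions on tibbles and chain with the pipe —
`read_depth_series()`, `detect_extrema()`, `build_tiepoints()`,
`build_age_model()`, `resample_monthly()`, `decompose_monthly()`,
`mean_seasonal_cycle()`, `detect_high_peaks()`, `sizer_map()`,
`annual_extension()`, `calcification_rate()`, `ba_salinity_fit()` — and
`autoplot()` works on decompositions, MSCs and SiZer maps.

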