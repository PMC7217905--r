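---
title: "Methods: coral Ba/Ca sediment-load reconstruction with coralba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coral Ba/Ca sediment-load reconstruction with coralba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralba)
```

## The problem

Massive *Porites* corals lay down aragonite continuously for decades, and
the trace-element chemistry of each skeletal layer records the seawater it
grew in. Two ratios matter here. **Sr/Ca** varies inversely and linearly
with sea-surface temperature (SST), so its annual cycle provides both a
thermometer and a clock. **Ba/Ca** tracks dissolved barium, which in
embayments fed by rivers is dominated by Ba²⁺ desorbed from river-borne
sediment particles in the low-salinity estuary; skeletal Ba/Ca is therefore
a proxy for terrigenous sediment load. Given a depth-resolved core
(microsampled at 0.25 mm, roughly 0.3 months of growth at a typical
9.6 mm/yr extension rate), the pipeline answers four questions:

1. **When** was each depth deposited (tie-point age model from Sr/Ca)?
2. What are the **multidecadal** and **event-scale** components of the
   Ba/Ca history (Gaussian low-pass / notch decomposition), and where does
   the multidecadal trend **shift** (SiZer)?
3. Which **discrete events** (floods, typhoons, landslides) left spikes in
   the record, and with what lag?
4. How did **growth** (extension, density, calcification) co-vary with
   sediment load, and what does the water-column **Ba–salinity** relation
   say about the endmembers?

Because no public data deposit exists for records of this kind at the time
of writing, the package ships a forward simulator (`simulate_core()`) that
generates virtual cores with known truth; every downstream stage is
validated against that truth.

## Chronology

Winter tie points pair each Sr/Ca **maximum** (depth domain) with the
**coolest** month of the corresponding instrumental-SST cycle; summer tie
points pair minima with the warmest month. Before the instrumental record,
the climatological coolest/warmest months (February/August for the
subtropical north-west Pacific; configurable) are used. Between tie points
growth is assumed constant, giving a piecewise-linear, strictly monotone
depth→time map; proxies are then linearly interpolated at the depth of
each month's midpoint (the 15th — a fixed convention, as the choice is
arbitrary at monthly resolution).

Extrema detection has three numerical safeguards, all tunable:

* a centred moving-average presmooth of about one month of growth
  (`smooth_mm = 0.8`) to suppress sample-to-sample analytical noise;
* a minimum separation of six months of growth (`min_separation_mm = 4.8`)
  plus a **topographic prominence** floor (10 % of the profile range):
  annual cycles have prominence near the full seasonal amplitude, noise
  bumps one to two orders of magnitude lower, so the floor separates them
  without touching real extrema;
* **quadratic vertex refinement** (`refine_mm = 2.4`): a parabola is fit to
  the raw profile within ±3 months of growth of the detected sample and
  its vertex taken as the extremum depth. This averages noise across ~19
  samples and localizes extrema well below the sampling interval, which is
  what makes annual extension rates (differences of successive winter
  depths) accurate to a fraction of a sampling interval.

On noise-free simulations the recovered tie dates are exact and winter
depths land within one sampling interval of truth; under the default
analytical and SST noise, the test suite requires ≥95 % of tie dates
within ±1 month and ≥95 % of annual extensions within 0.25 mm.

## Decomposition

The monthly Ba/Ca series is split into a low-pass (multidecadal) and a
notch (detrended, sub-biennial) component with a Gaussian frequency-domain
filter:

$$W(f) = \exp\left(-\ln 2 \, (f/b)^2\right), \qquad b = 0.00137\ \text{cycles/day},$$

so the amplitude response is 1 at DC and exactly ½ at the bandwidth. With
months of 365/12 days, a 2-year period is \(1/730 = 0.00137\) cycles/day —
the half-amplitude point sits at 2 years, which is what "isolating the
>2-year trend" means operationally. The notch component is the exact
complement (`input − lowpass`), so the two always sum to the input.

Numerical choices: the series mean is removed before transforming (avoids
DC leakage into the notch), the series is mirror-padded by one series
length on each side (controls endpoint transients; for a pure cosine the
endpoint error stays below 5 % of amplitude), and the measured amplitude
response on single-frequency inputs matches \(W(f)\) to well under 1 %
for periods from 6 months to 20 years on a 46-year series. The exact
window of the desktop program historically used for such filtering is
undocumented; this package fixes the transfer function above and verifies
against its own closed form rather than chasing bit-level agreement.

Before filtering, the youngest months are dropped: the tissue layer
carries anomalously high trace-element values. At 9.6 mm/yr a 4.1 mm
tissue layer is 5.1 months, so 5 months are excluded by default (derived
from the record's own mean extension when not set explicitly).

## Mean seasonal cycle and high-peaks

The MSC is the 12-month climatology (mean, SE, n per calendar month) of
the detrended series. High-peak detection follows the literal rule:
candidate months are those where the detrended value exceeds the overall
MSC mean, runs of consecutive candidates collapse to their single highest
month (ties to the earlier month), so no two reported peaks are adjacent.
Because the literal threshold flags many months on noisy data, a
robustness parameter `k_sigma` raises the threshold by multiples of the
residual (about-MSC) standard deviation; raising it can only reduce the
peak count. Event matching is greedy event-first: each catalogue event
takes the earliest unused peak with lag in [0, `max_lag_months` = 4].
Period counts split at January of the boundary year (A-period through
December 1995, B-period from January 1996, matching the trend-shift
convention).

## SiZer trend shifts

The annual means of the low-pass component are scanned with a
reimplementation of SiZer: at each (bandwidth h, year t) cell a
Gaussian-kernel (\(w_i = e^{-(x_i-t)^2/2h^2}\)) local linear regression
gives a slope and standard error (weighted residual variance with the
weighted hat-matrix correction, sandwich form for the variance); cells are
classed *increasing* / *decreasing* / *not significant* by pointwise
two-sided Gaussian quantiles at `alpha = 0.05`, or *insufficient data*
when the effective sample size \((\sum w)^2/\sum w^2\) falls below 5 (the
SiZer convention). Pointwise rather than simultaneous quantiles is a
deliberate simplification — documented, and tested to keep the significant
fraction on white noise below 2α. The bandwidth grid defaults to 21
log-spaced values from 2 to 25 years, reflecting the sub-25-year filter
widths of interest for multidecadal records of this length.

A shift point is a transition between significant slope signs along a
bandwidth row with only not-significant cells between, attributed to the
interval between the last cell of the old sign and the first of the new.
Intervals supported by both directions at different bandwidths are flagged
**ambiguous** and are not used to split a record. `consensus_shift()`
reports the unambiguous interval with the most bandwidth support (pooling
intervals whose midpoints are within a year). On tent-shaped test series
(break at year 28 of 46, signal-to-noise 5) the consensus midpoint must
land within ±1 year of the break in ≥90 % of seeded replicates.

## Growth and calcification

Annual extension is the distance between successive winter tie points,
labelled with the calendar year of the deeper tie (the year containing the
interval's summer — the labelling convention is ours, fixed and
documented). Annual density averages a calibrated density profile over the
samples dated within each complete calendar year, weighting by the time
each sample spans (depth-weighted averaging is available as an option;
densitometry itself — converting radiographs to g/cm³ — is out of scope
and density is consumed as a profile). Calcification is
extension (cm) × density (g/cm³), an exact identity in the emitted
records. Per-period association with the low-pass Ba/Ca annual means is
reported as Pearson r/p/n plus the OLS slope ± SE for both extension and
calcification.

## Ba–salinity mixing

Estuarine barium mixes conservatively: a high-Ba, low-salinity river
endmember (desorption from suspended sediment) against low-Ba marine
water. `ba_salinity_fit()` fits Ba (nmol/kg) on salinity by OLS; the
intercept is the river endmember and the value at salinity 35 the marine
endmember. Coral Ba/Ca converts to seawater Ba via
\(\mathrm{Ba_{sw}} = \mathrm{Ba/Ca} \times \mathrm{Ca_{sw}}\) with the
salinity-35 calcium reference 10.28 mmol/kg and a distribution coefficient
of 1 (configurable): 3.8 μmol/mol ↔ 39.1 nmol/kg.

## The synthetic core generator

`synth_config()` encodes the study conditions as defaults: 46 years of
growth ending at an October 2014 collection; mean extension 9.6 mm/yr with
lognormal year-to-year variability (sdlog 0.08, a realistic ~8 % spread);
0.25 mm sampling; SST mean 25 °C, amplitude 4 °C (warmest August, coolest
February — subtropical north-west Pacific climatology), monthly noise
0.3 °C; Sr/Ca = 10.5 − 0.06·SST mmol/mol and Mg/Ca = 3.2 + 0.04·SST
(typical *Porites* thermometry); analytical RSDs 2.24 % (Ba/Ca), 0.17 %
(Sr/Ca), 0.73 % (Mg/Ca) applied as multiplicative Gaussian noise. The
seawater Ba/Ca forcing is a 3.8 μmol/mol baseline (≈39 nmol/kg seawater
Ba), a piecewise-linear multidecadal anomaly through knots at
1968 → 1980 (rise to +0.25), → 1995 (fall to −0.05), → 2014 (rise to
+0.35) — a rise–fall–rise shape with its trough shift at 1995/96 — a
seasonal term of amplitude 0.15 μmol/mol peaking in September (the
typhoon/heavy-rain season), and lagged exponential spikes. The default
four spikes mirror documented flood events (June 1977, September 1990,
August 1991, October 2010) with onset lags of 3, 0, 2 and 4 months and
magnitudes 0.8–1.5 μmol/mol (the largest chosen so the record maximum is
roughly 1.4× the baseline). The spike kernel is
\(m \cdot e^{-k/\tau}\) from the lagged onset — the exact shape of real
post-flood Ba releases is not known, so the kernel is configurable and
only its additivity and onset timing are treated as truth. Growth is
uniform across months by default (matching the constant-growth-rate
assumption of the age model); a winter-slowdown profile is available to
stress-test chronology robustness against cool-season growth cessation.

What the generator does **not** emulate: mechanistic mangrove
trapping/tidal hydrodynamics (the seasonal term and spikes are
phenomenological), depth-dependent smoothing of the geochemical signal by
bioturbation or sampling-groove overlap, dating error from missed or
double bands, and vital effects on the thermometers. Passing tests
therefore demonstrate that the algorithms recover what they are designed
to recover under realistic noise — not that every feature of a real core
is handled.

## Degenerate inputs and error policy

Monthly series must be contiguous: single gaps up to 3 months are filled
by linear interpolation on read (and reported), longer gaps are rejected —
frequency-domain filtering needs a complete grid and longer interpolation
would fabricate structure. Duplicate depths, non-alternating extrema,
non-monotone tie dates, overlap shorter than 24 months for thermometer
calibration, fewer than 3 water samples or constant salinity, and
non-positive inputs to the Ba conversion all raise classed errors
(`coralba_*_error`) rather than warnings. Correlation p-values are
reported exactly and two-sided (the convention when sidedness is
unstated); threshold styling ("p < 0.05") is left to the caller.

## Problem sizes used by the test suite

The suite exercises 46-year monthly records (552 months, ~1 770 depth
samples), 20-replicate seeded ensembles for chronology, peak, SiZer and
growth-slope recovery, and 14-sample water sets — sizes chosen to match
the emulated study design while keeping the default test run fast. The
acceptance script (`scripts/acceptance.R`) recomputes all headline
quantities from scratch at these sizes.

## Known limitations

* The age model assumes constant growth between ties; strong intra-annual
  growth modulation biases monthly placement by up to about a month
  (the winter-slowdown simulator profile exists to quantify this).
* The tissue-layer exclusion is a month count, not a geochemical
  detection of the tissue boundary.
* SiZer inference is pointwise; simultaneous (row-wise) bands would be
  more conservative and are out of scope.
* The high-peak rule is threshold-based; it does not model event
  magnitude or deconvolve overlapping spikes (a run containing two true
  events yields one representative peak).
* Seawater Ca is fixed (optionally salinity-scaled) in the Ba conversion;
  real estuarine Ca varies with salinity.
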