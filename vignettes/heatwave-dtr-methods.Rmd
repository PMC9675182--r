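---
title: "Detecting and projecting heatwaves with a health-based DTR threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and projecting heatwaves with a health-based DTR threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtrheat)
```

## The problem and the exposure metric

Most heatwave definitions are purely climatological (e.g. exceedance of a
high percentile of daily maximum temperature). This package implements a
*health-based* definition for South African district municipalities: the
exposure metric is the **diurnal temperature range** (DTR, daily maximum
minus daily minimum temperature), which has been linked to all-cause
mortality, and the alert level is a fixed national threshold of
**12.8 °C** above which mortality increases. A **heatwave** is at least
`min_duration = 2` consecutive days with DTR above that threshold, counting
only days whose daily mean temperature is at or above the district's
**minimum mortality temperature** (MMT) — the mean temperature at which
mortality is lowest, ranging roughly 18.5–39 °C across districts. Days below
MMT are excluded per day, before run detection: they are days on which the
population is not at elevated heat-mortality risk, whatever the DTR.

Both the 12.8 °C threshold and the district MMTs are *inputs* here; their
epidemiological derivation is prior work and out of scope.

## Detection model

For one district with daily records $(T^{max}_d, T^{min}_d)$:

* $DTR_d = T^{max}_d - T^{min}_d$, $\bar T_d = (T^{max}_d + T^{min}_d)/2$.
  The midrange is the only "mean temperature" computable from daily max/min
  alone; MMT masking applies to it.
* A day **qualifies** iff both values are present, $DTR_d > 12.8$ °C
  (strict by default; `strict_exceedance = FALSE` gives $\ge$) and
  $\bar T_d \ge \mathrm{MMT}$.
* **Events** are the maximal runs of qualifying days of length $\ge 2$.
  There is no gap-joining by default (`max_gap = 0`): marine-heatwave
  conventions bridge short gaps, but the definition implemented here is a
  plain consecutive-day exceedance, so one non-qualifying day ends an event.
  A missing-data day also ends an event — the conservative reading of
  "missing values excluded from analysis"; bridging missing days could
  fabricate long durations and is deliberately not offered.
* Each event reports duration (inclusive day count), the **peak** day (day
  of maximum DTR, the detection metric; earliest day on ties, for
  determinism; the day of maximum tmax is reported as an auxiliary field),
  mean DTR, and cumulative exceedance $\sum_d (DTR_d - 12.8)$ in °C·days.
  Events are attributed to the austral season (DJF summer, MAM autumn, JJA
  winter, SON spring) and year of their *start* date, so a multi-month
  event is counted once.

Missing data are kept as explicit missing records and never interpolated —
interpolation would manufacture exposure days. Rows with
$T^{max} < T^{min}$ are treated as sensor error: both values are set
missing, flagged in the QC report, with a warning.

## Descriptive statistics

Per-district summaries (mean, SD, 95th percentile of tmax, tmin, DTR) use
the sample SD ($n-1$) and a percentile with linear interpolation between the
closest order statistics (`stats::quantile` type 7). Other quantile
definitions exist (notably the default of some commercial statistics
packages); the choice is exposed via `quantile_type` and recorded here.
Statistics are computed over all non-missing days of the period; a
date-range filter can be applied upstream by subsetting the series.
"Hot days" are counted with the same strict-exceedance convention as
detection.

## Projection by the delta-change method

Future series are `observed + anomaly`: additive scenario deltas for tmax
and tmin are applied separately (additive application is the standard
delta-change reading; multiplicative scaling is not offered). The observed
2014–2019 calendar is cycled over the 2020–2039 target, aligning by month
and day; 29 February in a future leap year maps from 28 February when the
source year lacks it. Deltas may be year-round or monthly (broadcast to all
days of the month); gridded anomaly fields (e.g. 1°×1° GCM products) are
bilinearly interpolated to district centroids once and then treated as
district deltas. Interpolation is strict: a centroid outside the grid's
bounding box is an error, never an extrapolation. A projected day whose
perturbed tmax falls below its perturbed tmin is set missing with a
warning.

MMTs are held fixed in future scenarios — no acclimatisation adjustment —
which likely *overestimates* future events; a stationary health threshold
is a standard simplification and a known caveat.

Comparison tables report event counts and event-days as separate measures
(published scenario summaries are ambiguous about the unit), with percent
change rounded to the whole percent alongside the raw value; a zero
observed count makes percent change undefined (`NA`), never infinite.
Note the observed and projected windows differ in length (6 vs 20 years);
the comparison is of raw totals, the convention the percent-increase
figures assume.

The anomaly magnitudes used in `analysis/04_project_scenarios.R`
(+1.0/+0.8 °C for the moderate pathway, +1.4/+1.1 °C for the high one) are
plausible near-term deltas chosen once as package defaults for the worked
analysis; real use supplies model-derived fields via `read_anomaly_csv()`
or `anomaly_from_grid()`.

## What the synthetic generator emulates — and what it does not

The station data behind the original analysis are not redistributable, so
the package ships a generator that reproduces the *structure* the pipeline
assumes, with known ground truth:

* seasonal cosine with austral phase (peak day-of-year 15, mid-January);
* AR(1) day-to-day noise (default coefficient 0.7) rather than i.i.d.
  noise, because heatwaves are persistent multi-day phenomena and i.i.d.
  noise would make ≥2-day runs unrealistically rare;
* coastal vs inland DTR regimes (baseline DTR ≈ 9.5–11 °C coastal,
  16.5–18 °C inland, matching the printed descriptive ranges of roughly
  8–19.4 °C);
* i.i.d. daily missingness at 16%, the study's aggregate rate (block
  missingness is available for stress tests).

Construction detail: tmin is generated as seasonal curve + AR(1) noise, DTR
as its own process (baseline + amplitude-difference seasonal term + AR(1)
noise, floored at 0.2 °C), and tmax = tmin + DTR. Generating tmax and tmin
independently cannot guarantee tmax ≥ tmin; this construction makes the
ordering structural while preserving the stated moments (mean DTR equals
the baseline up to the truncation and the near-zero mean of the seasonal
term over whole years; with zero noise and equal amplitudes the DTR is
exactly constant).

`plant_events()` writes ground-truth events into a series: planted days get
a triangular DTR profile above threshold with a strictly unique peak day
(a small monotone tie-breaker keeps the peak unique through floating-point
round-trips), tmin raised just enough that the day clears MMT, and the
days adjacent to each window depressed below threshold. On a noiseless
sub-threshold background (`planted_fixture()`), detection recovers planted
events exactly — count, boundaries and peak days. Planted windows may not
touch: adjacent windows would merge into one run, so adjacency is rejected
(overlap too); a one-day gap is fine.

The generator does **not** emulate ENSO-scale interannual variability,
spatial correlation between districts, station relocation artifacts, or the
true spatial field of MMTs. Passing tests therefore demonstrate the
correctness of the *algorithms* under the stated statistical structure, not
that the synthetic series are statistically indistinguishable from the real
network. Headline published counts that depend on the restricted data
(e.g. national event totals) are not reproduction targets.

## Numerical and design choices

* **Strict exceedance** (`>`): "exceedance of 12.8 °C" reads as strict;
  printed counts cannot adjudicate it, so it is configurable and logged.
* **Duration** is the inclusive day count (leap-aware); the 2014–2019
  period is 2191 days, and the worked example 29 Oct 2015 → 13 Jan 2016 is
  77 days.
* **Ties** for the peak day go to the earliest day.
* **Degenerate inputs**: fewer than two non-missing values make
  descriptive statistics an error; an empty qualifying set yields a
  zero-row event table with full column structure, and summaries zero-fill
  absent groups (max peak DTR is `NA` for an empty group — there is no
  temperature to report).
* **Aggregation**: one series per district is assumed; combining multiple
  stations into a district series is left upstream, as the source data were
  already district-aggregated.
* **Problem sizes** used by the shipped analysis and checks: 6 districts ×
  2191 days (a "full-scale" 50-district profile exists for shape testing),
  1000 random sequences for the detection/oracle equivalence suite, and
  100 seeds for missingness calibration. These sizes were chosen so the
  whole analysis re-runs in about a minute on a laptop while leaving every
  property at full study-period length.

## Reproducibility

Every stochastic function takes an explicit seed; `generate_all_series()`
derives per-district seeds deterministically from one master seed. The
pipeline stages write a `manifest.json` (configuration plus an MD5 hash of
it), and re-running a stage from the same inputs is byte-identical.
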