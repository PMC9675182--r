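# dtrheat

Heatwave detection and climate-scenario projection for daily district
temperature series, using a **health-based diurnal temperature range (DTR)
threshold** with **minimum mortality temperature (MMT)** masking.

Heat-health warning systems need a trigger tied to mortality risk, not just
to climatology. For South African district municipalities, all-cause
mortality rises when the diurnal temperature range — daily maximum minus
minimum, `DTR = Tmax − Tmin` — exceeds a national threshold of 12.8 °C, and
days are only health-relevant when the daily mean temperature
`T̄ = (Tmax + Tmin)/2` is at or above the district's MMT (the mean
temperature of lowest mortality). This package implements the full analysis
pipeline around that definition, for epidemiologists and climate-health
analysts:

* **weather I/O & QC** — long CSV ingestion with duplicate rejection,
  `tmax < tmin` sanitisation, gap filling with explicit missing records, and
  per-district missingness reporting (`read_daily_csv()`,
  `read_district_meta()`);
* **daily metrics** — DTR, daily mean, per-district mean/SD/p95 tables,
  hot-day counts, austral season labels (`derive_daily()`,
  `descriptive_table()`, `count_hot_days()`, `season_of()`);
* **event detection** — heatwaves as maximal runs of ≥ 2 consecutive days
  with `DTR > 12.8 °C` and `T̄ ≥ MMT`, with duration, peak day, mean DTR and
  cumulative exceedance per event (`detect_events()`, `summarise_events()`);
* **projection** — delta-change scenarios: additive tmax/tmin anomalies
  (per-district or bilinearly interpolated from a 1° grid) applied to the
  observed series cycled over 2020–2039, detection re-run, observed vs
  future compared (`apply_anomaly()`, `compare_scenarios()`);
* **synthetic data** — a seeded generator with seasonal cycle, AR(1)
  persistence, coastal/inland DTR regimes, 16 % missingness and plantable
  ground-truth events, so the pipeline is fully testable without the
  restricted station data (`generate_series()`, `plant_events()`,
  `planted_fixture()`).

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated 6-district (3 coastal, 3 inland) dataset, 2014-01-01 to
2019-12-31 (2191 days), with 16 % missing days:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_describe.R
Rscript analysis/03_detect_heatwaves.R
Rscript analysis/04_project_scenarios.R
```

Stage 2 and 3 print, among other tables:

```
mean DTR: coastal 9.4-11.0 degC, inland 16.6-17.7 degC

detected 305 heatwave events, 1207 event-days

by season (events / event-days):
  group n_events event_days max_duration max_peak_dtr
 summer      199        870           29     24.37393
 autumn       47        159           11     25.36023
 winter        2          4            2     14.30354
 spring       57        174            9     24.00541

longest event: I03, 2015-12-29 to 2016-01-26 (29 days), peak DTR 21.9 degC on 2016-01-14
```

Read: inland districts have roughly 7 °C more diurnal range than coastal
ones, so they carry most events; events cluster in austral summer (DJF);
the longest simulated event runs 29 days across the 2015/16 new year. Stage
4 applies two scenario deltas (+1.0/+0.8 °C and +1.4/+1.1 °C on tmax/tmin)
over 2020–2039 and prints observed vs projected event counts per scenario;
per-season and per-district comparison tables (events and event-days, with
raw and rounded percent change) land in `results/projection/`.

Equivalent single calls from R: `run_detection()` and `run_projection()`
write the same artifacts plus a reproducibility manifest.

## Scope notes

Published national event totals (e.g. 270 events across 50 districts)
depend on non-public weather-service data and are not reproduction targets.
The derivation of the 12.8 °C threshold and of district MMTs is prior
epidemiological work: both are inputs here. MMTs are held fixed under
future scenarios (no acclimatisation), which tends to overestimate future
events — see the methods vignette (`vignettes/heatwave-dtr-methods.Rmd`)
for this and other modelling choices.
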