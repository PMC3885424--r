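# coraltrack

Analysis toolkit for combined acoustic-array and satellite telemetry of
large mobile reef predators — the study design used for multi-year tiger
shark (*Galeocerdo cuvier*) monitoring across oceanic and coastal coral
reefs. It is written for movement ecologists who have acoustic detection
logs, Argos position files and archival depth–temperature records, and who
need the standard chain of residency, diel, network, filtering and space-use
analyses in one tested, reproducible package.

## What it computes

* **Residency**: monitoring windows bounded by battery life and array
  service, the Residency Index
  `RI = distinct detected days / potential monitoring days`, detection-day
  summaries, and the four-category occurrence classification
  (resident / pseudo-resident / transient / passer-by) based on detected
  months per year, an RI threshold of 0.30, and 31-day re-detection gaps.
* **Diel statistics**: day (06:00–17:59) vs night (18:00–05:59) detection
  counts in fixed-offset local time and the equal-expectation 1-df
  chi-square `X² = (day − night)² / (day + night)`.
* **Movement networks**: station visits (30-min gap rule), directed
  transitions, per-receiver detection proportions, and maximum linear
  (haversine, R = 6371 km) distances between detection sites.
* **Argos filtering**: classes 3/2/1 kept unconditionally, class Z
  dropped, classes 0/A/B kept only within a 3.5 km/h swim-speed reach of
  the most recent anchor (prior class 1–3 fix, capture location, or
  acoustic detection).
* **Track utilities**: bathymetric correction of geolocated positions
  against maximum daily dive depth, displacement from release, and
  depth–temperature archive summaries with half-metre modal bins.
* **3D kernel utilisation distributions**: product-Gaussian KDE over
  (easting, northing, depth) in km with per-axis Sheather–Jones plug-in
  bandwidths, and 50%/95% highest-density-region volumes in km³.
* **Synthetic telemetry**: a ground-truth generator emulating the whole
  observation process (four movement regimes, 50–130/40–80/30–90 s
  transmitter duty cycles, 400–800 m detection range, Argos class error,
  two-mode dive profiles) so every stage is validated end to end.

## Worked example

Simulate a year-round resident shark on a 7-receiver oceanic-reef array,
then run the residency and diel stages:

```r
library(coraltrack)

cfg <- sim_config(seed = 1, regime = "resident", duration_days = 432)
sim <- simulate_telemetry(cfg)

win <- monitoring_window(sim$tags, sim$receivers)
print(win)
#> monitoring window for SIM1: 2010-08-12T00:00:00.000Z to
#>   2011-11-17T00:00:00.000Z (462 potential days)

daily <- daily_detections(sim$detections, sim$receivers, win)
residency_index(daily, win)
#> [1] 0.9177489
classify_behaviour(daily, win)
#> [1] "resident"

head(diel_summary(sim$detections, utc_offset_hours = 11), 1)
#>   tag_id day_count night_count statistic     p_value p_label
#> 1   SIM1      6410        5738  37.17353 1.08071e-09  <0.001
```

The monitoring window ends at the array retrieval (462 potential days,
inside the 696-day battery life); the shark was detected on 424 of those
days (RI 0.92) and is classified resident. The day/night split of this
realisation happens to be imbalanced — autocorrelated movement produces
exactly the kind of spurious-looking diel signal the chi-square flags,
which is why per-shark diel results need cautious reading. The same
functions run unchanged on real CSV inputs via `read_detections()`,
`read_receivers()`, `read_tags()`, `read_argos()` and
`read_depth_series()`; `run_pipeline()` orchestrates all stages from one
config, and `inst/exec/coraltrack` exposes `simulate`, `run`, `residency`
and `diel` subcommands for shell use.

Fitting a 3D utilisation distribution:

```r
set.seed(1)
k <- fit_kud(matrix(rnorm(5000 * 3), ncol = 3), "normal_scale", grid_n = 48)
summary(k)
#> 3D kernel utilisation distribution (normal_scale bandwidth)
#>   n = 5000 points, grid 48^3, bandwidths (km): 0.295 0.286 0.281
#>   grid mass: 1.000000
#>   50% volume: 17.2 km^3
#>   95% volume: 100 km^3
```

For a standard trivariate normal in km the analytic 95% highest-density
region is a ball of volume 91.5 km³; the estimate above is within the
KDE's expected oversmoothing at this n.

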