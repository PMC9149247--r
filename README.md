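# driftnet

Directed, strength-weighted interaction networks between pollutant time
series measured at many monitoring sites.

## The problem

When fine particulate pollution (PM2.5) in one city repeatedly precedes the
same pollution pattern in another, the temporal order carries information
about atmospheric transport — which city's air is flowing toward which.
Chemical transport models can answer this mechanistically but demand
emission inventories, meteorological fields and substantial compute.
`driftnet` implements a lightweight statistical alternative that needs only
the concentration series themselves, aimed at air-quality researchers and
epidemiologists working with routine monitoring-network data.

## The method

For two hourly series X₁(t), X₂(t) the package scans the lag-adjusted
Pearson correlation over a grid of lags τ (±168 h by default, one synoptic
week):

    P(τ) = Corr(X₁(t), X₂(t − τ))
    P_max = max_τ P(τ),    T_delay = argmax_τ P(τ)

`P_max` measures the strength of a potential interaction; the sign of
`T_delay` its temporal order (negative: X₂ lags X₁, candidate direction
X₁ → X₂). Two gates guard significance: a t-test that `P_max` ≠ 0
(t = r√(n−2)/√(1−r²)), and a one-sided Fisher r-to-z comparison that
`P_max` exceeds the contemporaneous P(0)
(z = (atanh r₁ − atanh r₀)/√(1/(n₁−3) + 1/(n₀−3))). Surviving pairs are
passed to a bivariate Granger-causality F-test — does adding p lags of the
candidate source improve an AR(p) prediction of the target? — and only a
rejection in the lag-nominated direction produces a directed edge. Running
this over all city pairs per calendar month yields a monthly directed
network.

The package also ships the supporting machinery: agency-style CSV
ingestion, the standard hourly-PM quality screen (exact zeros, duplicate
records, values above 1000 µg/m³), station-to-city averaging, timezone
harmonisation, CSV/GeoJSON network export, and a synthetic advection
simulator with ground-truth transport lags for end-to-end validation.

## Worked example

Two simulated cities 600 km apart under a 50 km/h wind (a true 12 h
transport lag), the downwind city's records stamped in UTC+9 and
relabelled to UTC+8 before analysis:

```r
library(driftnet)
sites <- data.frame(city_id = c("coastal", "inland"), x_km = c(0, 600), y_km = 0)
wind  <- data.frame(year = 2018, month = 1, dir_deg = 90, speed_kmh = 50)
sim <- simulate(synthetic_scenario(sites, wind), seed = 2018)
qc  <- qc_filter(sim$records)
qc$report
#>     n_input   n_missing      n_zero   n_outlier n_duplicate  n_conflict  n_retained
#>        2929           0           5          10           5           0        2909

x1 <- average_stations(qc$records, "coastal", tz_offset_hours = 8)
x2 <- align_timezone(average_stations(qc$records, "inland", tz_offset_hours = 9), 8)
(r <- lag_correlation(x1, x2))
#> <lagcorr> coastal ~ inland
#>   P_max = 0.9272 at T_delay = -12 h (n = 729); P(0) = 0.6342 (n = 741)
#>   p_r = 2.64e-312; p_fisher = 2.79e-65; significant: TRUE
#>   candidate direction: coastal -> inland (|lag| = 12 h)

confirm_direction(r, x1, x2)
#> <direction_decision> coastal -> inland: CONFIRMED
#>   strength P_max = 0.9272, |lag| = 12 h; forward p = 1.552e-65, reverse p = 0.5671

build_network(list(coastal = x1, inland = x2), 2018, 1)
#> <driftnet_network> window 2018-01: 2 cities, 1 directed edges
#>   coastal -> inland  (P_max = 0.927, lag = 12 h, Granger p = 1.55e-65)
```

Reading the output: the correlation profile peaks at −12 h with
`P_max = 0.93` — the inland series is best aligned when the coastal series
is shifted 12 h later, so coastal air leads. Both gates pass (the lagged
maximum is overwhelmingly larger than the zero-lag correlation of 0.63),
the Granger test rejects in the coastal → inland direction only, and the
monthly network contains the single correct directed edge at the true lag.

A command-line wrapper with `simulate`, `qc`, `pairwise`, `network` and
`evaluate` subcommands is installed at
`system.file("exec", "driftnet.R", package = "driftnet")`; see the methods
vignette (`vignettes/transport-networks.Rmd`) for the model, its
assumptions, and every tunable.

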