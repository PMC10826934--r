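# gpsactivity

Quality control and validation of passively sensed smartphone GPS data for
activity-space research.

Activity-space studies track where people move through daily life by
recording geo-coordinates continuously from their phones over a study week,
usually alongside brief ecological momentary assessment (EMA) surveys.
Before such location streams can support substantive analysis, they need
systematic cleaning and validation: raw streams contain fixes recorded
outside the study period, "GPS jumps" (temporally adjacent fixes separated
by implausibly large distances), fixes implying impossible movement speeds,
and device-dependent differences in sampling density and accuracy.
`gpsactivity` implements that measurement pipeline end to end for
epidemiologists and social scientists working with urban and non-urban
cohorts:

- **Cleaning.** Study-window restriction, then removal of distance-gap
  outliers using a pooled threshold of *k*·SD (default *k* = 3) over the
  distribution of consecutive-fix distance gaps, then removal of fixes
  implying speeds above *v*<sub>max</sub> (default 250 m/s, the high end of
  commercial aircraft speed). For a pair of consecutive fixes
  (*p*<sub>i</sub>, *p*<sub>i+1</sub>) with time gap Δ*t* and haversine
  distance Δ*d*, the implied speed is Δ*d*/Δ*t*; the later fix of an
  offending pair is removed, and a gap whose earlier fix is already marked
  is skipped so a single displaced fix costs exactly one point.
- **Quality metrics.** Participant-level time gap, distance gap and
  accuracy statistics; participation days (local calendar days with ≥ 1
  fix); temporal coverage (fraction of study-window minutes containing a
  fix); grouped summaries by residence (RUCA codes 1–3 = urban, 4–10 =
  non-urban) and device OS; point-level outlier incidence (> 1 h time gaps,
  > 1 km distance gaps, > 1 km accuracy radii) by residence × activity-space
  setting.
- **Home geofencing.** At-home classification against the home building
  footprint and its 20/50/100 m outward buffers (metric Minkowski buffers
  computed in a local azimuthal-equidistant frame), and the proportion of
  wake time (08:00–20:30 local) spent at home, with group means and
  normal-approximation 95% confidence intervals
  (mean ± 1.96·SD/√n).
- **EMA concordance.** Matching of each EMA self-report to the GPS fix
  recorded in the same whole minute and 2×2 EMA-by-GPS contingency tables
  with column percentages per buffer and stratum, plus per-buffer
  minimum/mean diagonal agreement summaries.
- **Synthetic cohorts.** A generator that emulates the full study design —
  device-conditional log-normal cadence and accuracy, home-dwell-plus-trips
  routines, truthful thrice-daily EMA, per-day dropout, and labeled injected
  jump/teleport artifacts — so every stage is verifiable against ground
  truth without access to restricted study data.

## Worked example

```r
library(gpsactivity)

cfg <- cohort_config(n_urban = 3, n_non_urban = 2, days = 3,
                     sampling = list(ios = c(meanlog = log(15), sdlog = 0.6),
                                     android = c(meanlog = log(30), sdlog = 0.8)),
                     seed = 42)
coh <- simulate_cohort(cfg)
cleaned <- clean_trajectories(coh$points, coh$window)
cleaned$report
#> GPS cleaning report
#>   input points:        47646
#>   duplicate rows:      0
#>   outside window:      0
#>   distance outliers:   450 (threshold 26905.230 m = 3 x SD 8968.410 m)
#>   speed outliers:      88 (> 250 m/s)
#>   retained:            47108
```

The distance filter removed the 450 injected displaced fixes (their gaps
exceed three standard deviations of the pooled distance-gap distribution)
and the speed filter the 88 inserted fixes implying > 250 m/s; all labeled
artifacts are recovered and no clean fix is lost. Participant-level quality
metrics show the device contrast built into the design (denser, more
accurate iOS sampling):

```r
cohort_quality(cleaned$points, coh$window)[, c(1, 3, 10, 11, 12, 13)]
#>   participant_id time_gap_median accuracy_median n_days_participated temporal_coverage n_points
#> 1           P001            30.7           18.98                   3             0.800     6150
#> 2           P002            31.0           19.12                   3             0.806     6219
#> 3           P003            15.1            7.03                   3             0.991    14231
#> 4           P004            15.0            7.21                   3             0.991    14395
#> 5           P005            30.3           18.97                   3             0.793     6113
```

EMA/GPS concordance improves as the home geofence widens, because location
noise throws at-home fixes just outside a tight footprint buffer:

```r
tabs <- cohort_concordance(coh$ema, cleaned$points, coh$homes,
                           buffers = c(20, 50, 100))
agreement_summary(tabs)
#>   buffer min_at_home mean_at_home min_not_home mean_not_home
#> 1     20         100          100     76.19048      76.19048
#> 2     50         100          100     94.11765      94.11765
#> 3    100         100          100    100.00000     100.00000
```

And the proportion of wake time at home with its group interval:

```r
wt <- cohort_wake_time_at_home(cleaned$points, coh$homes,
                               buffers = c(0, 20, 50, 100),
                               window = coh$window)
group_proportion_ci(wt$proportion[wt$buffer == 50])
#>      mean   lower95   upper95         n
#> 0.5725510 0.5610427 0.5840593 5.0000000
```

The recovered mean (0.57) sits close to the generator's 0.60 wake-time
at-home schedule; the gap reflects noisy fixes near geofence boundaries.
`run_pipeline()` chains all stages and writes every table (cleaning report
JSON, participant and group quality CSVs, outlier incidence, wake-time
intervals, concordance tables) to an output directory, either from an
in-memory cohort or from CSV/GeoJSON inputs.

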