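---
title: "Methods: GPS activity-space quality control and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GPS activity-space quality control and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsactivity)
```

## The measurement problem

Passive smartphone location sensing produces a stream of fixes — timestamp,
longitude/latitude, an accuracy radius (the 68% confidence radius in
metres), and the device OS — per participant over a study window (seven
consecutive days by default here). Before the stream supports activity-space
analysis, three things must be established: that artifactual fixes have been
removed, that data density and accuracy are adequate (and understood as a
function of residence setting and device), and that the sensor-derived
location agrees with what participants themselves report. This package
implements that pipeline with every stage testable against a synthetic
cohort whose ground truth is known exactly.

All timestamps are stored in UTC; a single study-level IANA timezone
(default `America/New_York`, the single-timezone setting the defaults
emulate) converts to local clock time wherever the calendar matters:
participation days, the wake window, and minute-of-day logic.

## Cleaning model

Cleaning runs in a fixed order; counts are reported in a `cleaning_report`
that reconciles exactly.

1. **Normalization.** Points are sorted by time; exact duplicate
   (timestamp, lon, lat) rows collapse to one; same-timestamp ties with
   different coordinates keep the fix with the smallest accuracy value
   (the most certain one), a deterministic tie-break.
2. **Study-window restriction.** The window is half-open,
   `start <= t < end`, so a fix exactly at the start belongs to the window
   and one exactly at the end does not.
3. **Distance filter.** Distance gaps between consecutive fixes of the same
   participant are pooled across all participants; the removal threshold is
   `k * SD` of that pooled distribution (default `k = 3`). Pooling matches
   the use of one global cut-off for the whole cohort. An absolute
   threshold override is available because a published global cut-off can
   also be read as `mean + 3 SD`; the override reproduces either reading
   without guessing. If the SD is zero (all gaps identical) nothing can be
   an outlier and the filter is a no-op.
4. **Speed filter.** Gaps are recomputed on the surviving points and any
   gap with implied speed strictly above `v_max` (default 250 m/s — the
   high end of commercial aircraft speed) marks a removal. The boundary is
   strict: exactly `v_max` is retained.

**Which fix of an offending pair is removed, and the skip rule.** The later
fix is removed — the landing point of the jump, the common convention in
mobility cleaning. A single displaced fix, however, produces *two*
offending gaps (into and out of it). Removing the later fix of both would
delete the displaced fix *and* the legitimate fix after it. The filters
therefore make one forward pass: a gap whose earlier fix is already marked
for removal is skipped, because that gap no longer exists between retained
points. No distances are recomputed within a pass. The result is that an
isolated displaced fix costs exactly one point, and false removals on clean
data are essentially zero. Running the full pipeline a second time can
remove at most as many points as the first pass (the SD shrinks once jumps
are gone); with the threshold frozen from the first pass it removes
nothing.

Distances are great-circle haversine distances on a sphere of radius
6,371,008.8 m (the IUGG mean Earth radius), computed by `geosphere`; the
test suite checks them against an independently coded spherical
law-of-cosines oracle.

## Quality metrics: two levels of aggregation

Participant-level summaries (`participant_quality_summary`,
`group_summary`) compute each metric within a participant and then take
statistics *of those participant-level statistics* per group. Point-level
outlier incidence (`outlier_incidence`) pools raw fixes within each
residence-by-activity-setting cell. The two levels answer different
questions — "what does a typical participant's stream look like" versus
"what fraction of all recorded fixes are problematic" — and produce very
different magnitudes for skewed gap distributions, because pooling weights
dense devices heavily. Both paths are exposed and tested; they are never
interchangeable.

Conventions worth stating:

- *Participation day*: a local calendar date inside the window with at
  least one fix.
- *Temporal coverage*: distinct whole minutes containing a fix, divided by
  the total whole minutes in the window (10,080 for seven days). Minute
  bins are epoch-aligned; the end minute of the window is exclusive.
- Statistics over fewer than two gaps are undefined and propagate as `NA`,
  never as zero.
- A gap inherits the setting label and timestamp of its *later* fix when
  attributed to a table cell; the first fix of a participant has no
  incoming gap and contributes only to accuracy and count columns.
- Outlier thresholds default to 1 hour (time gap), 1 km (distance gap) and
  1 km (accuracy), all strictly exceeded to count.

## Home geofencing and wake time

The home geofence family is the building footprint (buffer 0) plus its 20,
50 and 100 m outward buffers. Buffering happens in a local
azimuthal-equidistant frame centred on the footprint centroid (distance and
spherical bearing from the centre; exact for radial distances, with
negligible distortion at building scale), as the Minkowski sum of the
footprint's convex hull with a disc, discretized at 72 points per circle.
The discretization inscribes the circular arcs, an area deficit below 0.1%.
Non-convex footprints are buffered via their convex hull — a documented
approximation; the synthetic footprints are rectangles, for which the
buffer is exact. Point-in-polygon tests are even-odd ray casts with an
explicit on-edge check, so boundary points count as inside,
deterministically.

Wake-time-at-home labels each wake-window minute (08:00–20:30 local,
defaults taken from the study design the package emulates) as home, away
or no-data using the single fix nearest the minute midpoint; a
majority-vote alternative is available for sensitivity analysis. No-data
minutes are excluded from the denominator rather than imputed — the
conservative analogue of self-report time-use data, where unobserved
minutes simply do not enter. The proportion is undefined (`NA`) when no
labeled minute exists. Because the geofences nest, the proportion is
non-decreasing in buffer size for every participant, a property the tests
assert. Group intervals are normal-approximation 95% CIs,
`mean ± 1.96 · SD/√n`, clipped to [0, 1]; with fewer than two defined
proportions the interval is flagged undefined.

## EMA concordance

"Recorded at the same timestamp" is operationalized as the same whole
minute, with the fix nearest the EMA second used when several share the
minute and a configurable 60 s tolerance; survey and sensor clocks cannot
be expected to coincide to the second. EMA records without a same-minute
fix are counted as not matched, and matched-plus-unmatched reconciles with
the stratum's EMA total. Tables are 2×2 cross-tabulations of the EMA answer
against the geofence classification, with *column* percentages (within GPS
status); a zero column yields undefined percentages rather than zeros.
Strata (urban/non-urban, Android/iOS) are overlapping marginal views, not a
four-way cross. On a fixed matched set, widening the buffer can only move
fixes from GPS-not-home to GPS-at-home, so at-home diagonal agreement is
non-decreasing in buffer size; the suite asserts this on the shipped
reference counts and on synthetic cohorts.

The package ships a reference contingency-count table
(`inst/extdata/concordance_reference_counts.csv`) from the published
seven-day urban/non-urban validation study whose design the generator's
defaults emulate; `reference_concordance_tables()` rebuilds the full
percentage tables from those raw counts at run time.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the emulated study's conditions: 122 urban and
40 non-urban participants, iOS fractions 62.3%/67.5%, a seven-day window
starting at a local midnight, EMA three times per day. Device-conditional
distributions are log-normal for both inter-fix time gaps (medians 1.842 s
iOS, 5.859 s Android, with `sdlog` chosen so the mean/median ratios match
the observed participant-level means 2.783 s and 32.911 s) and accuracy
(medians 7.133 m iOS, 19.114 m Android, `sdlog` likewise matched to the
observed means). Log-normal families reproduce the right-skew — median ≪
mean — that the observed tables show. Positional noise is bivariate normal
with per-axis SD `accuracy/1.51`, making the drawn accuracy value the 68%
circular error radius; `noise_scale = 0` gives noiseless fixes.

Daily routines alternate home dwell with `trips_per_day` (default 2) radial
excursions: a destination drawn 0.2–10 km away, constant travel speed drawn
from 1–15 m/s, and dwell at the destination, placed in disjoint wake-window
blocks so that away time totals `1 - at_home_frac` (default 0.6 at home) of
the wake window. Trip destinations are at least 200 m out, beyond the
largest (100 m) geofence. EMA prompts fire only in minutes that are
stationary end to end — the answered-when-stationary assumption; a prompt
answered mid-transit 50 m from home would truthfully say "not home" while
any geofence wider than 50 m calls it home, which is a property of
geofencing, not an error the generator should manufacture. Per-day dropout
(default 0.015) silences whole days, mirroring observed participation-day
medians of 7 with means just under.

Artifacts: *jumps* (default rate 1% of fixes) displace a fix by 30–100 km —
the regime in which a single pooled 3·SD threshold separates artifact from
behaviour, as a global published cut-off implies; *teleports* (default
0.2%) insert a fix 1 s after an anchor, displaced 300–800 m, implying
300–800 m/s — above any plausible speed but far below the distance
threshold, so the two filters are exercised separately. Every injection is
labeled, enabling exact recall/false-removal accounting.

Not emulated: road networks (trips are straight-line), within-day sensor
outages (coverage under the defaults is governed by cadence and dropout
only), EMA misreporting (answers are truthful), multi-timezone travel, and
urban-canyon accuracy degradation. Passing tests therefore demonstrate the
pipeline's correctness on data satisfying these assumptions, not the
behavioural realism of any particular cohort.

## Problem sizes and numerical choices

The test suite and the acceptance script run scaled-down cohorts chosen to
exercise every code path while keeping the whole suite under a minute: a
50-participant × 7-day corrupted cohort at ~60 s median cadence (~360,000
fixes) for artifact recovery; 5-participant noiseless cohorts over 2–3 days
for parameter recovery; single-participant constructions for closed-form
checks. With the recovery cohort's 1% jump rate, the pooled gap SD is
~9.6 km, putting the 3·SD threshold near 29 km — below the 30 km minimum
jump — so recall is 100% by design margin, and the skip rule keeps false
removals at zero. Wake-time recovery is asserted to 0.03 absolute: minute
midpoints adjacent to schedule transitions can flip labels, bounding the
error by roughly twice the number of daily trips in minutes per day
(~1–2% of the 750-minute wake window).

Other numerical choices: the Earth radius is fixed at 6,371,008.8 m
everywhere; projection uses spherical bearings consistent with the
spherical distance formulas (mixing ellipsoidal azimuths with spherical
destinations produces metre-scale round-trip errors); the minute bin at a
window's exclusive end is dropped by subtracting 1 ms before binning
(POSIXct cannot resolve nanoseconds); percentages divide by column totals
with explicit `NA` on empty columns.

## Known limitations

- Buffering of genuinely non-convex footprints (L- or U-shaped buildings)
  via the convex hull overstates the geofence in the concavity.
- Point-in-polygon treats lon/lat as planar, appropriate at the
  building-to-county scales used here, not across poles or the antimeridian.
- The at-home minute labeling applies no dwell smoothing; an isolated noisy
  fix can flip a single minute.
- Group CIs are normal approximations on participant-level proportions;
  with very small groups they are flagged rather than replaced by exact
  intervals.
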