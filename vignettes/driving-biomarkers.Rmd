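---
title: "GPS driving biomarkers for preclinical Alzheimer disease: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GPS driving biomarkers for preclinical Alzheimer disease: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`drivemarkers` turns raw 30-second in-vehicle GPS samples into monthly
driving-behaviour indicators and classifies preclinical Alzheimer disease
(amyloid positivity with normal cognition) from them. This vignette explains
the underlying procedures, the parameters that matter, the synthetic-data
generator and its calibration, and the design decisions taken where the
problem was genuinely open.

## The measurement model

A logger plugged into a vehicle's OBD-II port records participant id, UTC
timestamp, latitude/longitude and speed every 30 s while the vehicle is
driven. The internal canonical unit for speed is m/s; file-level unit
declarations (`mph`, `kph`) are converted on ingest. Timestamps are stored
UTC and converted to a per-study IANA timezone (default
`America/Chicago`) only for local-time logic: night classification, month
assignment, and entropy time bins.

### Trips

The logger emits no ignition events, so trips are reconstructed from the
sampling pattern: consecutive points with inter-sample gaps of at most
`gap_s = 300` s form one trip; a longer silence is read as an ignition-off
interval, which is the natural proxy at 30-s sampling. Trips with fewer than
4 points or shorter than 0.1 km are discarded (logged). All three
thresholds are configurable. Trip distance is the sum of haversine
great-circle distances (Earth radius 6371.0088 km) over consecutive points.

### Kinematics and events

Acceleration is the first finite difference of sampled speed over the
actual inter-sample interval (m/s²); jerk is the difference of consecutive
accelerations divided by the midpoint time step (m/s³). At a 30-s cadence
these finite differences cannot literally observe an "8 mph in one second"
braking event, and commercial loggers detect such events internally and
emit them as flags. Event counting is therefore device-authoritative: when
a participant's log carries an `event_flag` column, hard brakes and sudden
accelerations are counted from flags; otherwise a kinematic fallback counts
sample-pair accelerations beyond ±3.57632 m/s² (8 mph/s), whatever the
native spacing happens to be.

One published inconsistency is worth stating plainly: group mean
|acceleration| ≈ 2.8 m/s² and |jerk| ≈ 1.4 m/s³ are implausibly large for
30-s finite differences (an honest 30-s cadence would need speed swings of
~85 m/s per interval). The device most likely differentiates at ~1 Hz
internally. The package computes finite differences at whatever sampling it
is given, and the simulator reproduces the published magnitudes by
injecting short 1-s "dither bursts" into its streams (see below) rather
than by pretending the 30-s cadence could produce them.

### Speeding

A trip's speed-compliance flags are defined only when posted limits
annotate at least half of its points; otherwise the trip is excluded from
the over-/under-speed denominators. Overspeed means any point more than
6 mph (2.68224 m/s) above its posted limit; underspeed means any *moving*
point (above a 0.5 m/s floor, so idling and queueing do not count) more
than 6 mph below it. The indicators OverV/UnderV are the fractions of
flag-defined trips containing at least one such episode — the only reading
of "average number of trips" compatible with published values of ~0.07.

### Driving space

Trip end-points are clustered into destinations greedily in chronological
order: an endpoint joins the first existing destination whose running
visit-weighted centroid lies within 150 m, else founds a new one. The
method is deterministic, order-stable and O(n·|L|); no clustering procedure
is prescribed by the field, and this one has the virtue of reproducibility.

The radius of gyration is
$$ r_g = \sqrt{\tfrac{1}{N}\sum_{i\in L} n_i\,(r_i - r_{cm})^2 }, $$
with $L$ the destination set, $n_i$ visit counts, $N = \sum n_i$ and
$r_{cm}$ the visit-weighted centre of mass. The formula is evaluated in a
local east-north tangent plane centred on the unweighted destination
midpoint, with Euclidean norms in km. Raw degree arithmetic would distort
with latitude; and evaluating the whole formula in one consistent planar
geometry (rather than mixing planar centroids with great-circle distances)
is what makes the implementation agree with a direct evaluation of the
formula to 1e-9, which the test suite checks against an independent
pairwise-identity oracle ($r_g^2 = \tfrac12\sum_{ij} p_i p_j d_{ij}^2$).
At metro-scale extents the difference from great-circle evaluation is
below one part in 10⁷.

Entropy is plug-in Shannon entropy (nats) over destination × time-of-day
states, with four equal six-hour bins (night 00–06, morning 06–12,
afternoon 12–18, evening 18–24 local); `time_bins = 1` degrades to purely
spatial entropy. The spatiotemporal reading (destinations "random in space
and time") also explains why published entropy (≈ 3.97) exceeds the log of
the mean destination count (ln 38.2 ≈ 3.64). No specific estimator is
prescribed in the literature we target; plug-in Shannon is the transparent
choice, and its finite-sample bias is handled explicitly in the simulator
calibration.

Night trips use apparent sunset/sunrise from the NOAA low-accuracy solar
position algorithm (Fourier expansions of solar declination and the
equation of time; zenith 90.833°), accurate to a few minutes at
mid-latitudes — ample, since start times cluster far from the terminator.
A trip is a night trip when its local start time falls after that date's
sunset *or before its sunrise*: pre-dawn driving is functionally night
driving. A strict after-sunset mode is available
(`night_mode = "after_sunset"`). Polar latitudes are rejected.

Trip-distance subgroups use half-open mile intervals [0,1), [1,5), [5,10),
[10,20), [20,∞), so bins always sum to the trip count and a trip of exactly
1 mile lands in [1,5).

### Aggregation and descriptives

The classifier's unit of analysis is the participant-month: all indicators
recomputed within each local calendar month of the trip's start time (no
split trips). Cohort descriptives and effect sizes, by contrast, are
computed over per-participant *study-period* indicators, because the
published group statistics (total distance ≈ 890 km, ≈ 114 trips) are
period totals over n = 75/64 participants and could not be means of monthly
values. Cohen's d uses the pooled-SD form with the convention
d = (without − with)/s_pooled; recomputing the published d column from its
own printed means and SDs reproduces 11 of 14 rows at two decimals, two
further rows in magnitude only (their printed signs contradict their
printed means), and one row (mean |acceleration|) not at all (0.13
recomputed vs 0.15 printed, presumably input rounding). The acceptance
tests assert exactly this pattern rather than papering over it.

## Classification

Labelled participant-months are split 70/30. The default `record` mode
reproduces the published protocol: months are treated as independent data
points, stratified by label, so one participant can contribute to both
sides. That protocol leaks participant identity — a forest can recognise a
participant's latent driving style rather than group differences — so a
`grouped` mode (split at participant level) is provided, and the package's
own evaluation shows the gap: record-mode AUC exceeds grouped-mode AUC on
average across seeds, which is itself a property the test suite asserts.

Four input-variable sets are fitted per run: age + APOE ε4; the 19 driving
features (14 indicators + 5 distance-bin counts); driving + age; driving +
age + APOE. Hyperparameters (trees {100, 300, 500}, max depth {∞, 5, 10},
min node size {1, 3, 5}) are selected by 3-fold cross-validated F1 on the
training set only; the best configuration is refit on the full training
set. The engine is `ranger` with impurity (Gini) importance, single-thread
and seeded for determinism; importances are normalised to sum to one and
sorted with an alphabetical tie-break. Missing feature values (e.g.
OverV/UnderV in months without posted limits) are imputed with training-set
medians. Metrics use the preclinical-AD class as positive: precision,
recall, F1 at threshold 0.5, and AUC as the normalised Mann-Whitney rank
statistic with half tie credit (checked against an all-pairs oracle).
Confidence intervals are 2.5/97.5 percentiles over 1000 bootstrap resamples
of test records; resamples missing a class are redrawn.

## The synthetic cohort generator

Real naturalistic-driving cohorts with CSF biomarkers are not publicly
redistributable, so the generator is a first-class module: it emulates a
two-group cohort (defaults: 75 without / 64 with preclinical AD; ages
75.7 ± 4.8 vs 79.1 ± 4.9 truncated at the 65-year inclusion bound; APOE ε4
carrier probabilities 0.30/0.33; CSF ratios drawn strictly on the correct
side of 0.0673) and realises, for each participant, twelve months of raw
30-s GPS points whose *extracted* indicators recover configurable group
means and SDs — by default the published group descriptives.

Per-participant latent targets θ (one per indicator) are drawn from a
Gaussian copula with moderate positive correlation (ρ = 0.5) among the
distance/trip-count indicators — the true correlation structure is
unreported; this is an explicit assumption. Marginals are moment-matched by
coefficient of variation: gamma above CV 0.8 (radius of gyration, event
rates — a lognormal's tail there makes cohort means erratic), lognormal
above 0.35, otherwise normal with physical clipping. The latent uniforms
are stratified (Latin-hypercube style, ranks preserving the copula), so a
finite cohort's empirical marginals match their nominal distributions and
cohort means are stable at realistic sample sizes.

Realisation then works backwards through the extraction pipeline:

* **Trips**: `round(θ_nTrips)` trips, distances lognormal in shape but
  rescaled to sum exactly to θ_TotalDist; scheduled within months with
  ≥ 600 s ignition-off gaps; night starts (probability
  θ_nNightTrip/θ_nTrips) drawn shortly after the computed local sunset.
* **Destinations**: a Zipf-weighted pool whose size K and exponent s are
  jointly solved so that the *expected number of distinct destinations
  visited* and the *expected plug-in spatiotemporal entropy* (computed
  exactly from binomial state counts, which absorbs the estimator's
  finite-sample bias) match θ_nUniqDest and θ_S. The two targets are not
  always jointly feasible — many distinct destinations force high plug-in
  entropy — so the solver minimises the combined squared relative error
  along the K(s) ridge; the residual discrepancy lands within a few percent
  at cohort level. Destinations are placed with uniform angles and Rayleigh
  radii, rescaled about the visit-weighted centre of mass so the expected
  radius of gyration equals θ_Rg, and nudged to ≥ 400 m pairwise separation
  so 150-m clustering never merges them.
* **Speed series**: each trip ends exactly at its destination; positions
  step along one geodesic proportionally to sampled speed. The cruise level
  solves the trip's mean sampled speed to θ_avgV. Kinematic targets are met
  with 1-s dither bursts: "single" bursts (one elevated sample) load
  |acceleration|, "double" bursts (up at +1 s, back at +2 s) load |jerk|.
  The response of the extracted means is affine in the burst amplitude, so
  a two-point evaluation per mix solves amplitude and single/double share
  exactly, averaged over the participant's realised trip-length
  distribution — the same series builder is used in calibration and
  realisation, so the two cannot diverge.
* **Events and speeding**: hard-brake/sudden-acceleration events are
  injected as device flags at Poisson counts matching the per-mile θ rates
  (device-authoritative extraction makes recovery exact in expectation,
  independent of sampling-rate limits). Synthetic posted limits track each
  sample's own speed, with one engineered episode per trip selected by
  Bernoulli(θ_OverV) / Bernoulli(θ_UnderV).

What the generator does **not** emulate: road networks and map-matched
routes (geography is a featureless plane around a home point), traffic,
weather, seasonality of behaviour, device dropouts, multi-driver vehicles,
and any true dependence of driving change on amyloid status beyond
group-shifted indicator distributions. Passing tests on simulated cohorts
therefore demonstrate that the *pipeline* measures what it claims with
calibrated sensitivity — not that real preclinical-AD drivers behave like
the simulator.

## Numerical and testing choices

Problem sizes were chosen so the whole suite exercises the full design
honestly at desk scale: cohort-level checks simulate ten independently
seeded default cohorts (139 participants × 12 months each, ≈ 800k GPS
points per cohort) and require extracted cohort means within 10% of the
group targets (25% for the small-magnitude event rates, whose relative
sampling error is intrinsically larger), exact trip-count recovery, and the
record-vs-grouped AUC ordering. Oracle checks (radius of gyration, AUC,
F1) run on hundreds of random small instances at 1e-9/1e-12 tolerances.
Degenerate inputs are contracts, not accidents: empty logs yield empty
collections, single-destination sets have zero gyration radius and entropy,
zero predicted positives report precision 0 with a flag, and months without
trips are absent rather than zero-filled.
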