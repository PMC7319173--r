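---
title: "Methods: from Argos fixes and tag sensors to activity budgets"
author: "sealdive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Argos fixes and tag sensors to activity budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealdive)
```

`sealdive` turns the raw data streams of an ice-seal satellite deployment —
Argos location fixes, per-dive records from a time-depth recorder, and hourly
wet/dry sensor summaries — into interpolated tracks, habitat annotations,
behavioural episodes, diel profiles, and monthly activity budgets.  This
vignette describes the models and rules each stage implements, the parameters
that matter, the synthetic-data generator used for validation, and the
numerical and design choices behind them.

## The movement model

Locations from the Argos system arrive irregularly (median interval around
half an hour) with class-dependent errors spanning two orders of magnitude
(hundreds of metres for class 3, kilometres to tens of kilometres for classes
0/A/B).  The track estimator is a continuous-time correlated random walk: per
planar axis, velocity $v$ follows an Ornstein–Uhlenbeck process and position
$x$ integrates it,

$$ dv = -\beta\, v\, dt + \sigma\, dW, \qquad dx = v\, dt, $$

with $\beta$ (1/hr) the inverse of the velocity autocorrelation time scale and
$\sigma$ (km/hr$^{1.5}$) the velocity noise scale; the stationary r.m.s.
velocity per axis is $\sigma/\sqrt{2\beta}$.  The two axes are independent and
share parameters, and observations add isotropic Gaussian error with the SD of
their location class.  Work happens in a Lambert azimuthal equal-area
projection centred on the study area (`laea_project()`), on the authalic
sphere, so planar kilometres are area-true and agree with great-circle
distances to a fraction of a percent over deployment scales.

The state-space model is exactly discretised over the irregular fix times and
fitted by maximising the Kalman-filter likelihood over $(\beta, \sigma)$
(`fit_ctcrw()`, Nelder–Mead on log parameters; the initial state is diffuse in
position and stationary in velocity, and the first observation is excluded
from the likelihood).  `predict_track()` then runs the Rauch–Tung–Striebel
smoother over the union of fix times and a regular 6-hour grid aligned to
00/06/12/18 UTC, reporting at each grid time the smoothed position and
`se_km` $= \sqrt{\mathrm{var}(x) + \mathrm{var}(y)}$.  Estimates with
`se_km` above 25 km (the scale of the coarsest environmental grid used
downstream) are dropped.

Before fitting, `prefilter_fixes()` removes fixes that are physically
implausible: class Z always; duplicate timestamps (the better class wins);
fixes on land; fixes implying speeds above 10 km/hr to both neighbours
(iteratively, worst first); and out-and-back spike geometries (turning angle
under 15° with both legs above 5 km/hr).  The speed and angle defaults are
standard plausibility thresholds for small phocids and are configurable.  With
error magnitudes like the published class-B values (SD 15 km) at a half-hour
cadence, apparent point-to-point speeds frequently exceed any plausible
threshold, so a large rejected share of class-B fixes is expected behaviour,
not a fault; the smoother absorbs the remainder through the class error model.

Validation is dual-route: smoother means are checked against a direct
generalised-least-squares solve on a three-fix toy problem, and parameter
recovery is measured on simulated tracks with $\beta = 1$, $\sigma = 2$ and
about 2,000 fixes.  The recovery experiment weights the location-class mix
toward classes 3–1: $\beta$ is the inverse of a one-hour time scale, and with
predominantly 8–15 km errors at a half-hour cadence the short-scale velocity
signal that identifies it is swamped, which is a property of the design, not
of the estimator.  Under the informative mix, both parameters come back within
a few percent (the acceptance suite requires 15% on the median of 20
replicates) and the 95% prediction ellipses cover about 95% of true positions.

## Habitat annotation

Daily positions are the 6-hr estimate nearest 12:00 UTC.  Each seal-day gets:

* **Ocean depth** — nearest-cell bathymetry; land cells return `NA`.
* **Distance to mainland** — great-circle distance to the nearest cell of the
  *largest* connected land component, so islands are excluded by construction.
* **Mean ice concentration** — unweighted mean over sea-cell centres within a
  50-km disc.
* **Distance to the ice edge** — signed distance to the periphery of
  *qualifying* ice: 8-connected components of cells at $\ge$ 15% concentration
  spanning $\ge$ 10 cells of the 25-km grid.  The periphery is a member cell
  with at least one open-sea neighbour below the threshold; the sign is
  negative when the position lies inside a qualifying component.  8-neighbour
  connectivity treats diagonally touching floes as contiguous; the whole
  computation is verified exactly against an independent brute-force scan
  (connected components via graph search, distance over every periphery cell).
* **Depth zone** — shelf below 300 m, basin beyond 1,000 m, and the 300–1,000 m
  shelf-break band in between, which dive-depth analyses exclude because
  location error against a steep slope makes depth ratios meaningless there.

Forays are maximal runs of consecutive basin-zone days.  A single shelf-break
day sandwiched between basin days bridges a run rather than splitting it (a
seal transiting the narrow break band is still off-shelf); two or more break
days, any shelf day, or a gap in the daily series ends the run.  The bridge
width is configurable because the underlying convention is genuinely open.

## Dive-bout segmentation

Hours that are at least 80% dry are haul-out hours; the threshold is safe
because hourly percent-dry values are strongly bimodal in these tags.
Haul-out bouts are maximal runs of consecutive flagged hours, and a missing
hour always breaks a bout.

The dive record is segmented by two rules applied in order:

1. A surface interval longer than 10 minutes is a **resting** boundary (and
   becomes a resting episode).
2. Within a gap-free run, a dive is *consistent* when its maximum depth is
   within ±15% of the depth of either of the two immediately preceding dives
   (relative to that preceding depth).  Maximal runs with at least five
   consistent dives are **repetitive** episodes.  A single interposed
   inconsistent dive is tolerated inside an episode; two consecutive
   inconsistent dives terminate it, with the first of the pair restarting a
   new candidate run.  Everything else is **mixed**.

Three operational details make the rule deterministic where prose alone is
ambiguous, and are fixed as follows: the ±15% tolerance is always computed
relative to the earlier dive of the comparison; the two-dive look-back never
crosses a resting boundary; and reference depths below 2 m are not accepted
as comparison denominators (the tag's detection floor makes sub-metre ratios
meaningless).  A deviant left dangling at the end of a run is pushed out of
the episode, since "interposed" requires a consistent dive on both sides.
The production state machine is tested for exact agreement with an
independently coded recursive reference on 1,000 random records.

A dive is a **bottom dive** when its maximum depth reaches at least 75% of
the mapped ocean depth on its day; ratios above 1 (location or bathymetry
error) still count, and water shallower than 10 m is left indeterminate.
Episode-level benthic behaviour uses the episode's median depth, the per-dive
calls remain available.

Diel structure is summarised as hour-of-day frequency profiles per month, in
local solar time fixed at UTC−10 for this study region, for four classes:
repetitive episodes deeper than 25 m (median), repetitive at or above 25 m,
mixed dives, and resting episodes.  Dive-class rows are normalised to sum to
one per month.  The haul-out profile is the across-seal mean (± SE) of each
seal's hourly haul-out proportion.  Depth histograms by four 6-hr local
periods use left-closed `[lo, hi)` bins above a 3.5-m floor.

The depth–duration relationship is fitted on binned medians: dives no longer
than 15 minutes are grouped into 10-m depth bins, bins with at least 10 dives
contribute their median duration (and median following-surface duration)
against the log of their median depth, and ordinary least squares gives
$\text{duration} = a + b \ln(\text{depth})$ with $S$ the bin-level residual
standard error in minutes.

## Monthly activity budgets

For each seal-month (clipped to the deployment span, so partial first and
last months are pro-rated):

1. The ratio of observed haul-out hours to observed wet/dry hours scales to
   the month's total **haul-out hours**.
2. The remaining hours are split between **diving** and **resting** by the
   ratio of time in diving episodes (repetitive plus mixed, including their
   internal surface intervals) to time in qualifying resting episodes.
   Resting episodes that overlap a haul-out hour are discarded — that time is
   already counted in step 1 — and apparent surface gaps longer than the
   2-hour coverage limit are treated as transmission gaps, not observed
   resting, mirroring the coverage definition below.
3. Diving hours are split into repetitive and mixed by the same episode-time
   ratio.

By construction the three components sum exactly to the month's hours.  A
seal-month is excluded when it has no wet/dry data, when the dive series
covers less than 10% of the month (coverage counts dive and surface time,
bridging gaps up to 2 hours), or when the mean distance to the mainland is
below 5 km — near shore, water depths drop under the tag's dive-detection
threshold and the dive record is structurally incomplete.  The wet/dry stream
provides the haul-out ratio and the dive stream gates inclusion; the two
coverages are deliberately kept separate.

## The synthetic-data generator

Every stage is validated against `simulate_study()`, which produces a
multi-seal deployment with planted ground truth:

* **Tracks** are exact simulations of the same integrated Ornstein–Uhlenbeck
  process the estimator assumes ($\beta = 1$/hr, $\sigma = 2$ km/hr$^{1.5}$
  by default, giving realistic travel speeds near 1.8 km/hr), on a 15-minute
  grid.  Fix times are a geometric thinning of that grid (median interval
  0.5 hr, rare long gaps), classes are drawn from a mix in which classes
  1–3 are about 7% of fixes, and errors use the published class magnitudes
  (0.25/0.5/1.5/4/8/15 km for 3/2/1/0/A/B) with class Z emitted as gross
  outliers.  With a domain raster the path reflects off the coast; the
  process deviates from a pure correlated walk only there.
* **Behaviour** is an interval schedule — not a Markov chain — so recovery
  tests have unambiguous truth: each day mixes a nightly-biased haul-out
  block (snapped to whole hours), repetitive bouts targeting 80% of local
  ocean depth (or the upper water column off-shelf), mixed bouts, and
  resting gaps.  Repetitive bouts jitter depths ±6% about the target, well
  inside the ±15% episode criterion; mixed bouts draw scattered depths and
  enforce the stated contract that consecutive depths differ by more than
  15%.  Durations follow $a + b\ln(\text{depth})$ plus noise; depths are
  quantised to 0.5 m, capped at 95% of the local bathymetry, and dives are
  stamped at whole seconds as tags do.
* **Wet/dry hours** draw from a two-mode mixture with mass only on
  \[80, 100\]% (hauled out) and \[0, 25\]% (wet), reproducing the strong
  bimodality that justifies the 80% rule.
* **Rasters** share one 60 × 60 grid of 25-km cells: a southern mainland
  band, a small island, a shelf rising to just under 300 m, a steep break
  ramp, a deep basin, and daily ice fields whose edge retreats over the
  basin in September and advances past the whole shelf in late winter.

What the generator does **not** emulate: Argos duty-cycling firmware,
autocorrelated or non-Gaussian location errors, tidal or haul-out-dependent
gaps in transmission, dive-shape profiles, ice drift, or real coastline
geometry.  Passing recovery tests therefore demonstrates the correctness of
the implementations under the stated error model, not robustness to every
pathology of field data.

## Numerical choices and problem sizes

Likelihood optimisation works on log parameters with a diffuse position
prior (variance $10^6$ km²); observation variances are floored at
$10^{-10}$ km² so noise-free fixtures remain well conditioned.  Covariance
recursions are symmetrised each step.  Degenerate inputs are defined, not
special-cased: empty dive records segment to empty episode lists, seals with
fewer than two fixes pass the prefilter with a warning, months without data
return typed exclusion records.

The test suite simulates deployments of one to two seals over one to three
months (thousands of dives, about two thousand fixes per track), which keeps
the full suite and the acceptance script within a few minutes on one core
while leaving every estimator in its asymptotic regime; the acceptance
experiments use 20 replicate seeds for parameter and budget recovery and
1,000/200 randomised cases for the segmentation and ice-edge oracles.

## Known limitations

* The movement model is single-state: no haul-out-informed observation
  model, no behavioural switching, and one fit per deployment.
* `se_km` combines the two axes isotropically; the full covariance ellipse
  is available internally but the 25-km cutoff uses the combined scalar.
* The velocity time scale is weakly identified when the fix stream is
  dominated by class A/B errors; budgets and habitat metrics are robust to
  this, but absolute $\beta$ estimates from such data should not be
  over-interpreted.
* Ice metrics use nearest-cell and cell-centre geometry on a 25-km grid;
  sub-cell coastline effects are out of scope.
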