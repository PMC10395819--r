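---
title: "Methods: from raw GPS fixes to mobility scaling laws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw GPS fixes to mobility scaling laws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobscale)
```

`mobscale` implements the processing chain that human-mobility research uses
to turn raw location streams into symbolic sequences and scaling-law
statistics, applied here to animal tracking data. This vignette documents
the model at each stage, the parameters that matter, the numerical and
design choices we made where the procedure is genuinely underdetermined, and
what the synthetic-data validation does and does not establish.

## Input model

A *fix* is one timestamped GPS observation of one individual (longitude and
latitude in WGS84 degrees). `read_fixes()` ingests Movebank-dialect CSV
exports, normalizes all timestamps to UTC, sorts within individual, drops
rows with unparseable fields (counted and reported), and collapses exact
duplicate timestamps to the first record. The calendar month — the analysis
unit throughout — is the UTC month. GPS loggers run on UTC and the study
extents involved (tens of kilometers) make a local-time month boundary a
cosmetic distinction; choosing UTC keeps the partition deterministic.

Distances are haversine great-circle distances on a sphere with the mean
Earth radius 6 371 008.8 m. At the ~100 km extents of coastal seabird
tracking the difference from an ellipsoidal or projected metric is far
below the thresholds it feeds (a few parts in 10⁴), and a spherical metric
needs no projection configuration.

## Stop detection

`detect_stops()` segments each trajectory with an anchor-based rule. The
candidate stop opens at the current fix (the anchor); subsequent fixes are
absorbed while their distance *to the anchor* is strictly less than δ.
The first fix at distance ≥ δ breaks the candidate; the dwell is the time
from the anchor to the last absorbed fix — the breaking fix contributes
neither to the dwell nor to the membership. If the dwell exceeds τ a
stop-point is emitted with the arithmetic-mean coordinate of its members
(adequate at ≤ δ extents) and the member time span; otherwise the candidate
is discarded. In both cases the scan restarts at the breaking fix, which
keeps the pass single-sweep and point-conserving.

Defaults are δ = 150 m and τ = 18 min, the values selected by sensitivity
analysis in the gull study this pipeline follows; `sensitivity_sweep()`
reproduces that analysis on any input.

Decisions worth making explicit, because the verbal description of this
family of algorithms leaves them open:

* distance is tested against the anchor, not a running centroid — the
  literal reading of the rule, and the variant that makes the scan
  single-pass;
* both comparisons are strict (`< δ`, `> τ`). Boundary equality is
  measure-zero for real coordinates, but fixing strictness makes the
  implementation testable against an independent transcription;
* a trailing candidate at the end of the trajectory is emitted if it passes
  the dwell test. Discarding it would systematically bias month-end
  behavior, since the month boundary truncates dwells;
* with fewer than two fixes no dwell is defined and no stop is possible.

The test of record for this module is oracle equivalence: on 1000 random
mixed dwell/transit trajectories the output is compared field-by-field with
an independently written point-by-point transcription of the rule.

## Stay-regions

`cluster_stops()` aggregates stop-points into stay-regions with DBSCAN on
the haversine metric, neighborhood radius ε (default 400 m for gull-scale
landscapes; 200 m is the published urban human setting) and self-inclusive
minimum neighborhood size 2. At that setting DBSCAN degenerates exactly to
the connected components of the graph joining stops closer than ε, which is
what the implementation computes (and what the test oracle recomputes with
`igraph`). Components smaller than `min_stops` (default 2 — "a region needs
at least two stops") are noise: dropped and counted by default, or promoted
to singleton regions with `keep_singletons = TRUE`, since dropping changes
the downstream visitation and growth curves and users should be able to
check that sensitivity.

A verbal description of this step could also be read as complete linkage
("every pair closer than ε"); that reading chains less aggressively than
DBSCAN. We implement DBSCAN as the named algorithm and expose the
complete-linkage reading as `method = "complete"` for sensitivity checks; a
property test verifies complete-linkage clusters only ever subdivide the
chained ones.

Regions are computed per individual and per month: each monthly trajectory
is a self-contained analysis unit, matching the monthly statistics, and
cross-month region identity is deliberately out of scope. Every surviving
stop becomes one *visit* carrying its stop's time interval; clustering
never alters timing.

## Temporal aggregation

Two encodings of the visit sequence are produced.

**Next Time-Bin (NTB).** One symbol per bin of width `bin_width` (default
3600 s, the conventional setting in the mobility literature), bins anchored
at the top of the UTC hour containing the first visit's start and covering
the span to the last visit's end (bin count = ⌈span / width⌉). Each bin
takes the region with the longest overlap; a duration tie goes to the
region with more visits *over the whole monthly sequence* — the to-date
visit count is the other defensible reading, but it makes the symbol chosen
for a bin depend on scan order; the whole-period count is deterministic and
order-independent. A residual tie falls to the smallest region id, which
guarantees full determinism. Bins with no stay-region time are retained as
gaps (`NA`): dropping them would silently compress the time axis that the
growth law is defined on, and forward-filling would fabricate dwell. Gaps
are excluded from visitation counts but advance time in `S(t)`.
Self-transitions (adjacent identical symbols) are retained by construction.

**Next Place (NP).** The region ids in visit order with consecutive
duplicates collapsed — transitions only. NP sequences are guaranteed gap-free
and repeat-free (the constructor enforces both), and on tie-free inputs
collapsing the non-gap runs of an NTB sequence reproduces the NP region
order, which is checked as a property test.

## Mobility metrics and exponent fitting

The radius of gyration is computed in the root-mean-square form
$r_g = \sqrt{\sum_i w_i\, d(r_i, \bar r)^2 / \sum_i w_i}$: a *signed* mean
of deviations about the centroid is identically zero, so the RMS form is
the only meaningful reading, and it is the definition used by the
human-mobility literature this package follows. From a symbol sequence, the
points are region centroids weighted by occupancy (gap bins excluded), so
NTB and NP sequences give different radii for the same month — both are
reported.

Rank curves (`visitation_frequency()`) count one visit per non-gap NTB bin
or per NP event; NTB therefore inflates top-rank frequencies through
self-transitions, which is a property of the encoding, not a bug. Growth
curves (`distinct_over_time()`) count first-seen regions along the
sequence's own axis (bin index or event index).

Exponents are fitted by ordinary least squares of log₁₀ y on log₁₀ x over
the full curve, with ζ reported as the negated slope of the rank curve and
μ as the slope of the growth curve. No rank or time cutoff is applied by
default: the originating analysis gives no evidence of one, and a silent
cutoff is a hidden parameter. Fits need at least three positive points;
degenerate inputs (constant y) yield exponent 0 with R² defined as 1.

The collective exponents are fitted on the population-averaged curves
(pointwise mean across individuals at each rank/time, averaging only the
individuals whose curve extends that far), per month and per scheme —
scaling laws of this kind describe collective behavior. Per-individual fits
are emitted alongside as diagnostics. Fitting pooled symbol counts or
averaging per-individual exponents are alternative conventions a user can
build from the exported pieces; the averaged-curve route is the package
default.

## Group comparisons

Per-individual-per-month values — the top-rank visitation share *f₁*, the
radius of gyration, and the distinct-region count — are the observation
units for the significance grids; they are the only granularity that gives
these non-parametric tests workable sample sizes in studies of ~10
individuals. Each metric × scheme cell is compared with a two-sample
Kolmogorov–Smirnov test and a two-group Kruskal–Wallis test, flagged at
α = 0.05 and α = 0.1. The breeding season defaults to April–June
(configurable); no multiple-testing correction is applied by default,
matching standard practice for this descriptive use, and the p-values are
reported raw so any correction can be applied downstream.

## The synthetic-data module

`simulate_epr()` implements the Exploration and Preferential Return
mechanism: with probability ρ·S^(−γ) the walker visits a new location,
otherwise it returns to a known one with probability proportional to its
past visit count, excluding the current location so adjacent repeats cannot
occur once a second location exists. While only one location exists, a
return step necessarily stays put — this preserves the degenerate ρ → 0
limit (S(t) ≡ 1, f = (1)) at the cost of possible self-transitions in the
opening phase; itinerary construction merges those into a single dwell.
The mechanism's asymptotic growth S(t) ~ t^{1/(1+γ)} gives a known target:
at γ = 1, ρ = 0.6 and 10⁵ steps the fitted μ must land within 0.05 of 0.5,
which is both a unit check on the simulator and an end-to-end check on
`distinct_over_time()` + `fit_exponent()`. The defaults ρ = 0.6, γ = 0.6
are the conventional parameterization of this model family; the source
study never parameterizes it.

`simulate_raw_gps()` renders an itinerary of stays and transits into fixes
at jittered ~2-minute intervals (the nominal sampling of the gull loggers),
with isotropic Gaussian noise (default σ = 20 m, typical GPS accuracy)
applied to dwell fixes in the local tangent plane; transit fixes are
interpolated along the leg. `make_planted_itinerary()` plants well-separated
stays for recall/precision scoring of stop detection;
`make_epr_itinerary()` lays EPR places on a golden-angle spiral (≥ 2 km
separation) so revisits exercise the clustering stage; and
`simulate_study_population()` composes these into a multi-individual,
multi-month study with per-individual exploration rates drawn from a range,
emulating the individual heterogeneity characteristic of gulls. All
generators take explicit seeds and leave the global RNG untouched.

What the generators do *not* emulate: tidal or diel activity rhythms,
dwell-time distributions with heavy tails, location-dependent fix loss,
spatially correlated GPS error, or movement between months that would make
cross-month region identity meaningful. Passing the synthetic suite
therefore demonstrates algorithmic correctness (each stage computes what it
claims on data with known structure), not that any particular biological
conclusion transfers to a real dataset.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale, chosen so
that the full suite completes in about a minute and a half: 1000 random
50-fix trajectories for the stop-detection oracle, 500 random 30-stop
instances for the clustering oracle, 10⁵ EPR steps for the convergence
check, and a five-individual, six-month, 60-stays-per-month synthetic
population for the pipeline quantities. These sizes are statements about
test design, not algorithmic limits; the pipeline is linear in fixes per
month apart from the pairwise clustering of (typically tens of) monthly
stops.

## Known limitations

* Exponents from short monthly sequences are fits over one to two decades
  at best; their absolute values are sensitive to the fitting convention
  (averaged curve vs pooled counts vs averaged exponents), which the
  originating literature leaves unstated.
* Stay-region identity does not persist across months, so month-to-month
  fidelity questions (does the bird return to *the same* roost?) need a
  different tool.
* The NTB gap policy (retain, exclude from counts, advance time) is one of
  three defensible conventions; the alternatives can be emulated by
  filtering the sequence but are not built in.
* `season_split()`'s default April–June window is the breeding season of
  the North Sea herring-gull system this pipeline was designed around;
  other systems need the window configured.
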