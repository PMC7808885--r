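---
title: "Methods: from badge event streams to communication networks"
author: "sociobadge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from badge event streams to communication networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociobadge)
```

## The measurement model

Wearable sociometric badges observe three things about a hospital ward.
Infrared transceivers on two facing badges detect each other repeatedly while
their wearers are in a face-to-face configuration, producing a dyadic
detection stream. An accelerometer summarizes each wearer's body motion as a
frequency (Hz); sustained gesturing during conversation raises this
frequency relative to quiet activity. Beacons mounted in functional areas
(bedsides, the central nurses' station, laboratories, lounges, ...) are
detected by badges nearby, localizing the wearer at area granularity —
corridors carry no beacons and are excluded by construction.

`sociobadge` is organized around the inferential chain these signals
support:

1. **Episodes.** For each unordered badge pair, maximal runs of infrared
   detections with inter-detection gaps of at most `gap_tolerance_s`
   (default 60 s) form one face-to-face episode; the episode ends one
   sampling tick (default 10 s) after its last detection. The gap tolerance
   bridges brief occlusions — a turned head, a passing colleague — without
   merging genuinely distinct meetings.
2. **Active interactions.** An episode counts as *active communication*
   when it lasts strictly more than `min_duration_min` (default 1 minute)
   and its motion statistic strictly exceeds `motion_threshold_hz` (default
   2 Hz). Both inequalities are strict. The motion statistic defaults to the
   larger of the two participants' episode-mean motion frequencies
   (`motion_rule = "either"`): active interaction is understood as
   gesture-aided conversation without presuming whose gestures carry it.
   `"both"` and `"mean"` are available for sensitivity analyses. The 2 Hz
   statistic is computed as the mean of per-minute motion samples falling in
   the episode window; this is a modelling choice, since an instantaneous or
   dominant-frequency reading of the gate is equally compatible with the
   measurement description.
3. **Localization.** An interaction is assigned to the zone receiving the
   majority of both participants' beacon pings during the episode, pooling
   the two badges because a conversing pair may straddle an area boundary.
   Ties go to the earliest-pinged zone; an interaction with no pings is kept
   in an explicit *unassigned* bucket rather than dropped, so occupancy
   totals always reconcile with interaction durations.
4. **Networks.** Cumulative active pair-minutes form a symmetric contact
   matrix. Sociograms link pairs whose cumulative minutes reach a threshold
   (`minutes >= t`, inclusive, so a threshold of 1 still means "at least one
   minute"); the node set is the full roster, so sweeping
   t = 1, 3, 4, 30, 150, 180 yields nested edge sets on fixed nodes.
   Centralities are computed on the *binary* thresholded graph — the
   layering over thresholds, not edge weighting, carries the intensity
   information.

## Centrality and core/periphery computations

*Degree* is reported raw and normalized by $n-1$. *Eigenvector centrality*
is the leading eigenvector of the adjacency matrix of the largest connected
component, found by power iteration from a uniform positive start. The
iteration runs on $A + I$ rather than $A$: both matrices share the Perron
eigenvector, but on bipartite components (paths, trees, stars) $A$'s extreme
eigenvalues come in a $\pm\lambda$ pair and plain power iteration
oscillates; the unit shift breaks the tie and guarantees convergence. Scores
are non-negative, unit Euclidean norm over the scored component, and zero
outside it, with a flag if the tolerance (max-norm $10^{-12}$ between
iterates) is not met within the iteration cap. *Betweenness* follows
Brandes' single-source accumulation on unweighted shortest paths, reported
raw and normalized by $(n-1)(n-2)/2$.

The *core/periphery fit* partitions nodes to maximize the Pearson
correlation between the observed binary adjacency and the ideal pattern in
which core–core dyads are 1 and periphery–periphery dyads are 0;
core–periphery dyads are excluded from the correlation, which makes the
score insensitive to how strongly the periphery attaches to the core and
focuses it on "dense core, sparse periphery". Both blocks need at least two
members for the correlation to exist, so degenerate optima (all-core,
all-periphery, graphs under four nodes, edgeless graphs) are returned
all-periphery with an `NA` score and a flag. Search is exhaustive up to 15
nodes and otherwise a greedy single-label hill climb with seeded random
restarts; on random 10-node graphs the greedy search recovers at least 95%
of the exhaustive optimum in the package's tests.

Two readings of a profession-pair heatmap cell are provided, because
"minutes × persons" is genuinely ambiguous: `pair_minutes` (default) counts
each unordered badge pair's minutes once, while `person_minutes` doubles
intra-profession cells, attributing the minutes to each participating
member. Intra-profession cells for professions with fewer than two members
are structurally empty and masked `NA`. The display scale is
$\log_{10}(x+1)$ so zero cells stay finite. Conservation holds over
*distinct* cells: the upper triangle (with diagonal) of the symmetric
profession matrix sums exactly to the upper triangle of the contact matrix.

## The synthetic study design

The generator emulates the study design the analysis stages assume, so the
pipeline can be exercised and validated end to end without sensor data.

* **Roster.** 76 staff: 15 attending physicians, 39 nurses, 4 senior
  residents, 1 resident, 4 nursing assistants, 8 medical technicians, 2
  receptionists, 1 pharmacist, 2 secretaries. Badge ids are deterministic
  (profession prefix + index).
* **Zone map.** 42 functional areas — 14 beds, a central nurses' station,
  conference, consultation and CT control rooms, 4 examination-and-procedure
  rooms, a family room, 3 laboratories, nurses' and physicians' lounges, 2
  physician stations, reception, a satellite pharmacy, a shower room, 4
  utility rooms, 5 storage rooms — holding 249 beacons in total, denser in
  the patient area.
* **Schedule.** Three 8-hour shifts per day with a 30-minute handover
  window after each shift start. Each badge works whole shifts drawn at
  random (seeded) from the slot grid until its hours match the target —
  160 h over the 4-week default, pro-rated for shorter windows. Random
  rotation rather than fixed teams is deliberate: fixed striding would
  partition the staff into artificial cohorts that never share a shift and
  fragment the contact network, which real ICU rosters do not do.
* **Encounters.** Per co-on-duty pair, a Poisson process at the mixing
  model's profession-pair rate (encounters per pair-hour at peak activity),
  modulated by a within-shift profile: a 3× burst in the handover window,
  then hourly weights $(1, 0.5, 0.22, 0.08, 0, 0, 0, 0)$. The profile
  concentrates sustained, gesture-aided conversation around the handover
  and the post-handover round and tapers to none in the late shift. The
  zero tail is a stylization: real wards have a low level of late-shift
  conversation, but at any realistic volume such a tail consists of a
  handful of episodes per hour, and Poisson noise on near-equal adjacent
  bins would create spurious strict local maxima in the daily intensity
  profile. With the zero tail, the three-peaks-per-day, 8-hour-spacing
  signature of shift handovers is a structural property of the default
  scenario rather than a coin flip, which is what the detection stage's
  diagnostics are designed to recover. Idle telemetry (motion samples and
  beacon pings) continues through the whole shift regardless.
* **Durations and motion.** Episode durations are log-normal (median 2 min,
  shape 0.8): conversational contacts are short with a heavy right tail.
  Per-minute motion samples are normal truncated at zero with means 2.5 Hz
  while conversing and 1.0 Hz while idle (sd 0.5), deliberately straddling
  the 2 Hz gate so classification is informative rather than trivial.
* **Mixing.** The default rate matrix is nurse-centred: nurse–nurse contact
  is highest (2.4 encounters per co-on-duty pair-hour at peak), nurses mix
  substantially with nursing assistants and doctors, nursing assistants
  avoid doctors, and clerical staff mix mostly among themselves. Zone
  propensities per profession concentrate nurses at bedsides and the
  central nurses' station, technicians in laboratories, receptionists at
  reception, and so on; an encounter's zone is drawn from the average of
  its two participants' propensities.
* **Seeding.** One master seed; every stochastic component (encounter
  counts, times, durations, zones, motion, beacon choice) reseeds from a
  labelled hash of it, so components are individually reproducible and
  identical inputs yield byte-identical streams.

What the generator does *not* emulate: physical infrared propagation and
occlusion, patient agents, within-zone coordinates, absenteeism, day/night
case-mix differences, and measurement artefacts such as badge dropout.
Passing tests on synthetic data therefore validate the *pipeline* — its
rules, conservation properties and algorithms — not the sensor physics, and
say nothing about how a particular real ward behaves.

## Numerical choices and degenerate inputs

* Timestamps are ISO 8601 with a fixed +00:00 offset; days break at local
  midnight, with a configurable day-start offset. Episodes spanning
  midnight count toward the day they start, except in intensity binning,
  where durations are apportioned to bins by exact overlap (conserving
  total minutes to 1e-9 relative tolerance).
* The intensity-series bin width must divide 24 h; the daily profile
  averages bins across days at the same time of day, and a peak is a bin
  strictly exceeding both circular neighbours.
* Hotspot ranking breaks ties lexicographically by zone id; "top 3" node
  flags break ties by interaction volume then badge id.
* Zero-member professions, empty rosters, header-only stream files,
  edgeless sociograms and single-node graphs all flow through with empty or
  flagged results rather than errors; malformed stream rows are dropped,
  counted and reported.

## Problem sizes

The package's own validation runs the full default scenario at two scales:
7 simulated days (about 300k infrared records, 180k motion samples — the
scale used in the test suite and the acceptance script, a few seconds per
stage) and the full 4-week design (about 1.2M infrared records and 730k
motion samples — 76 staff × 160 h × 60 min/h = 729,600 scheduled
person-minutes), which completes in well under a minute on a single CPU.
The oracle-equivalence suites check the three centralities against dense
eigendecomposition and exhaustive geodesic enumeration on hundreds of
random graphs of up to 10 nodes, and the core/periphery greedy search
against exhaustive partition enumeration.
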