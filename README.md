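# sociobadge

Contact-network analysis of hospital staff from wearable sociometric badges.

Wearable badge systems record three raw event streams for every staff member:
dyadic infrared detections (who is facing whom), accelerometer body-motion
frequency samples (gesturing associated with conversation), and pings from
location beacons installed throughout the ward. `sociobadge` turns such
streams into the quantities an interprofessional-communication study reports:

* **active face-to-face interactions** — dyadic episodes whose body-motion
  frequency *exceeds 2 Hz for more than 1 minute* (interpreted as
  gesture-aided conversation), segmented from the infrared stream with a
  configurable gap tolerance;
* **spatiotemporal occupancy** — interactions are localized to functional
  areas by majority vote of beacon pings, accumulated into daily zone
  occupancy maps and hotspot rankings;
* **profession-pair heatmaps** — cumulative interaction minutes between each
  pair of the nine staff professions, displayed on a `log10(x + 1)` scale;
* **threshold-layered sociograms** — undirected graphs linking staff whose
  cumulative interaction minutes reach a threshold (the layered sweep
  1, 3, 4, 30, 150, 180 min), exported as GraphML and edge-list TSV;
* **centrality and core/periphery structure** — degree (`k / (n-1)`),
  eigenvector (leading adjacency eigenvector by power iteration) and
  betweenness (Brandes' algorithm) centralities, plus a core/periphery
  partition maximizing the Pearson correlation between the observed
  adjacency and the ideal core/periphery block pattern.

Because badge studies rarely deposit raw sensor data, the package includes a
first-class, seeded synthetic generator that emulates the study design the
analysis assumes: 76 staff in 9 professions (15 attending physicians, 39
nurses, 4 senior residents, 1 resident, 4 nursing assistants, 8 medical
technicians, 2 receptionists, 1 pharmacist, 2 secretaries), 42 functional
areas holding 249 beacons, a 4-week three-shift rotation with handovers every
8 hours, and a nurse-centred profession mixing model. Every downstream stage
is therefore testable end to end without any external data.

## Worked example

One simulated week of the default study, from raw streams to network
structure:

```r
library(sociobadge)

roster   <- make_roster()                       # 76 staff, 9 professions
zone_map <- make_zone_map()                     # 42 zones, 249 beacons
schedule <- make_schedule(roster, n_days = 7, target_hours = 40, seed = 1)
streams  <- simulate_streams(roster, schedule, zone_map, mixing_model(),
                             seed = 1)
streams
#> <sb_streams> 293966 IR detections, 182400 motion samples, 182400 beacon pings

episodes <- attach_motion(segment_episodes(streams$ir), streams$accel)
active   <- classify_active(episodes)           # 2 Hz / >1 min rule
nrow(episodes); nrow(active)
#> [1] 7142
#> [1] 5798

series <- intensity_series(active, bin_width_min = 60)
count_daily_peaks(daily_profile(series))        # handovers every 8 h
#> [1] 3

cm <- contact_matrix(active, roster)
cm
#> <sb_contact_matrix> 76 badges, 1602 positive pairs, 21776.7 total minutes

round(profession_heatmap(cm, roster)$display[1:4, 1:4], 2)
#>                     attending_physician nurse senior_resident resident
#> attending_physician                2.48  3.44            2.30     1.35
#> nurse                              3.44  4.16            2.87     2.08
#> senior_resident                    2.30  2.87            1.17     0.00
#> resident                           1.35  2.08            0.00       NA

g30 <- threshold_graph(cm, 30, roster)          # the 30-minute sociogram
fit <- core_periphery_fit(g30, seed = 1)
fit
#> <sb_corefit> greedy: core 26 nodes, score 0.496
mean(setNames(roster$profession, roster$badge_id)[fit$core] == "nurse")
#> [1] 1

active <- assign_zones(active, streams$beacon, zone_map)
hotspots(daily_occupancy(active, zone_map, "2019-10-01"), 3)
#>                     zone_id               category  minutes
#> 1 central_nurses_station_01 central_nurses_station 946.1833
#> 2                    bed_13                    bed 212.3000
#> 3                    bed_10                    bed 189.7500
```

Reading the output: the interaction intensity peaks three times per day at
the 8-hour shift handovers; the nurse–nurse heatmap cell is the largest
(`4.16` on the log scale, about 14,500 pair-minutes); at the 30-minute
threshold the fitted core consists entirely of nurses while physicians and
other professions sit in the periphery; and the interaction hotspots are the
central nurses' station and the patient bedsides.

`run_pipeline()` (or the CLI wrapper in `inst/cli/sociobadge.R`) executes
simulate → detect → map → network in one call, writing all CSV/TSV/GraphML
outputs plus a JSON run manifest with input digests and per-stage record
counts.

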