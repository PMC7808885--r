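# The desk-scale study scenario used by the heavier end-to-end checks:
# the default 76-member roster and zone map over 7 simulated days at the
# pro-rated 40-hour target, with the default mixing model. Results are cached
# per seed so several tests can share one simulation.

.scenario_cache <- new.env(parent = emptyenv())

scenario_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  roster <- make_roster()
  zone_map <- make_zone_map()
  schedule <- make_schedule(roster, n_days = 7, target_hours = 40,
                            seed = seed)
  streams <- simulate_streams(roster, schedule, zone_map, mixing_model(),
                              seed = seed)
  episodes <- attach_motion(segment_episodes(streams$ir), streams$accel)
  active <- classify_active(episodes)
  res <- list(roster = roster, zone_map = zone_map, schedule = schedule,
              streams = streams, episodes = episodes, active = active)
  .scenario_cache[[key]] <- res
  res
}
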