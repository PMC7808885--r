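pipe_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full badge-analysis pipeline
#'
#' Executes simulate (optional), detect, map and network stages from one
#' validated configuration, writing every output file plus a run manifest
#' (`manifest.json`) into `out_dir`. Any stage failure aborts with the stage
#' name, removing the files written by this run.
#'
#' @param config An [validate_config()] configuration (a list, path or YAML
#'   string is validated first).
#' @return The run manifest, invisibly: configuration snapshot, input file
#'   MD5 digests, tool version, per-stage record counts, and collected
#'   warnings (class `sb_manifest`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "sb_config")) config else validate_config(config)
  quiet <- isTRUE(cfg$quiet)
  written <- character(0)
  warnings <- character(0)
  note <- function(w) warnings <<- c(warnings, conditionMessage(w))
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "setup"
  result <- tryCatch(withCallingHandlers({
    # --- simulate ---------------------------------------------------------
    if (isTRUE(cfg$simulate)) {
      stage <- "simulate"
      roster <- make_roster(unlist(cfg$roster_counts))
      zone_map <- make_zone_map()
      schedule <- make_schedule(roster, start_date = cfg$start_date,
                                n_days = cfg$n_days,
                                target_hours = cfg$target_hours,
                                handover_min = cfg$handover_min,
                                seed = cfg$seed)
      streams <- simulate_streams(roster, schedule, zone_map, mixing_model(),
                                  seed = cfg$seed)
      written <- c(written,
                   write_streams(out_dir, streams, roster, zone_map, schedule))
      ds <- list(roster = roster, zone_map = zone_map, schedule = schedule,
                 ir = streams$ir, accel = streams$accel,
                 beacon = streams$beacon)
      pipe_log(quiet, stage, "%d staff, %d days, %d IR records",
               nrow(roster), cfg$n_days, nrow(streams$ir))
      in_dir <- out_dir
    } else {
      stage <- "read"
      in_dir <- cfg$in_dir
      ds <- read_streams(in_dir)
      pipe_log(quiet, stage, "read %d IR records from %s", nrow(ds$ir), in_dir)
    }
    input_files <- file.path(in_dir, c("roster.csv", "zones.csv",
                                       "schedule.csv", "ir.csv", "accel.csv",
                                       "beacon.csv"))
    digests <- tools::md5sum(input_files[file.exists(input_files)])

    # --- detect -----------------------------------------------------------
    stage <- "detect"
    dcfg <- do.call(detection_config, cfg$detection)
    episodes <- segment_episodes(ds$ir, dcfg)
    episodes <- attach_motion(episodes, ds$accel)
    all_eps <- classify_active(episodes, dcfg, keep_all = TRUE)
    pipe_log(quiet, stage, "%d episodes, %d active", nrow(all_eps),
             sum(all_eps$active))

    # --- map --------------------------------------------------------------
    stage <- "map"
    all_eps <- assign_zones(all_eps, ds$beacon, ds$zone_map)
    written <- c(written,
                 write_interactions(all_eps,
                                    file.path(out_dir, "interactions.csv")))
    active <- all_eps[all_eps$active, , drop = FALSE]
    class(active) <- c("sb_interactions", "data.frame")
    if (nrow(ds$schedule)) {
      days <- seq(day_label(min(ds$schedule$start), cfg$day_start_offset_min),
                  day_label(max(ds$schedule$end - 1), cfg$day_start_offset_min),
                  by = "day")
    } else {
      days <- as.Date(character(0))
    }
    for (d in as.list(days)) {
      occ <- daily_occupancy(active, ds$zone_map, d, cfg$day_start_offset_min)
      written <- c(written,
                   write_occupancy(occ, file.path(
                     out_dir, sprintf("occupancy_%s.csv", format(d)))))
    }
    pipe_log(quiet, stage, "%d active interactions over %d day(s), %d unassigned",
             nrow(active), length(days), sum(is.na(active$zone_id)))

    # --- network ----------------------------------------------------------
    stage <- "network"
    cm <- contact_matrix(active, ds$roster)
    written <- c(written,
                 write_contact_matrix(cm, file.path(out_dir,
                                                    "contact_matrix.csv")))
    pm <- profession_heatmap(cm, ds$roster, unit = cfg$heatmap_unit)
    written <- c(written, write_heatmap(pm, file.path(out_dir, "heatmap.csv")))
    edge_counts <- integer(0)
    for (thr in cfg$thresholds) {
      g <- threshold_graph(cm, thr, ds$roster)
      rep_t <- centrality_report(g, ds$roster)
      fit_t <- core_periphery_fit(g, seed = cfg$seed)
      written <- c(written, write_sociogram(
        g, rep_t, fit_t,
        file.path(out_dir, sprintf("sociogram_t%g.graphml", thr)),
        file.path(out_dir, sprintf("edges_t%g.tsv", thr))))
      edge_counts[sprintf("t%g", thr)] <- igraph::ecount(g)
      if (thr == cfg$core_threshold_min) {
        data.table::fwrite(as.data.frame(rep_t),
                           file.path(out_dir, "centrality.csv"))
        written <- c(written, file.path(out_dir, "centrality.csv"))
      }
    }
    pipe_log(quiet, stage, "edges per threshold: %s",
             paste(sprintf("%s=%d", names(edge_counts), edge_counts),
                   collapse = " "))

    manifest <- structure(list(
      tool = "sociobadge",
      version = as.character(utils::packageVersion("sociobadge")),
      created = format_iso(Sys.time()),
      config = unclass(cfg),
      input_digests = as.list(digests),
      counts = c(list(
        staff = nrow(ds$roster), zones = nrow(ds$zone_map$zones),
        ir_records = nrow(ds$ir), accel_records = nrow(ds$accel),
        beacon_records = nrow(ds$beacon), episodes = nrow(all_eps),
        active_interactions = nrow(active),
        unassigned_interactions = sum(is.na(active$zone_id)),
        days = length(days)),
        as.list(setNames(as.integer(edge_counts),
                         paste0("edges_", names(edge_counts))))),
      warnings = warnings), class = "sb_manifest")
    jsonlite::write_json(unclass(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }, warning = note),
  error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' @export
print.sb_manifest <- function(x, ...) {
  cat(sprintf("<sb_manifest> sociobadge %s, %s\n", x$version, x$created))
  cat("counts:\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  if (length(x$warnings)) {
    cat(sprintf("%d warning(s)\n", length(x$warnings)))
  }
  invisible(x)
}
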