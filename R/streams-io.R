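#' Write a simulated study to CSV
#'
#' Writes the six delimited files a badge deployment produces: `roster.csv`
#' (badge_id, profession), `zones.csv` (beacon_id, zone_id, category),
#' `schedule.csv` (badge_id, start_iso, end_iso), `ir.csv` (timestamp_iso,
#' observer_badge, observed_badge), `accel.csv` (timestamp_iso, badge_id,
#' motion_hz) and `beacon.csv` (timestamp_iso, badge_id, beacon_id).
#' All comma-separated, header row, UTF-8; timestamps ISO 8601 with a fixed
#' +00:00 offset.
#'
#' @param dir Output directory (created if absent).
#' @param streams An [simulate_streams()] `sb_streams` object.
#' @param roster,zone_map,schedule The matching study structures.
#' @return Invisibly, the paths written.
#' @export
write_streams <- function(dir, streams, roster, zone_map, schedule) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("roster.csv", "zones.csv", "schedule.csv",
                            "ir.csv", "accel.csv", "beacon.csv"))
  data.table::fwrite(roster[, c("badge_id", "profession")], paths[1])
  data.table::fwrite(zone_map$beacons[, c("beacon_id", "zone_id", "category")],
                     paths[2])
  data.table::fwrite(data.frame(badge_id = schedule$badge_id,
                                start_iso = format_iso(schedule$start),
                                end_iso = format_iso(schedule$end)), paths[3])
  data.table::fwrite(data.frame(timestamp_iso = format_iso(streams$ir$timestamp),
                                observer_badge = streams$ir$observer_badge,
                                observed_badge = streams$ir$observed_badge),
                     paths[4])
  data.table::fwrite(data.frame(timestamp_iso = format_iso(streams$accel$timestamp),
                                badge_id = streams$accel$badge_id,
                                motion_hz = streams$accel$motion_hz), paths[5])
  data.table::fwrite(data.frame(timestamp_iso = format_iso(streams$beacon$timestamp),
                                badge_id = streams$beacon$badge_id,
                                beacon_id = streams$beacon$beacon_id), paths[6])
  invisible(paths)
}

read_csv_checked <- function(path, expected) {
  if (!file.exists(path)) stop("missing input file: ", path)
  dt <- data.table::fread(path, colClasses = "character",
                          encoding = "UTF-8", sep = ",")
  if (!identical(names(dt), expected)) {
    stop(sprintf("unexpected header in %s: got [%s], expected [%s]",
                 basename(path), paste(names(dt), collapse = ", "),
                 paste(expected, collapse = ", ")))
  }
  dt
}

#' Read a study directory back into memory
#'
#' Parses the six CSV files written by [write_streams()]. Each stream is
#' timestamp-sorted; rows with unparseable timestamps or non-numeric motion
#' frequencies are dropped, counted, and reported in one warning per file.
#'
#' @param dir Directory holding `roster.csv`, `zones.csv`, `schedule.csv`,
#'   `ir.csv`, `accel.csv`, `beacon.csv`.
#' @return A list of class `sb_dataset` with elements `roster`
#'   (`sb_roster`), `zone_map` (`sb_zone_map`), `schedule` (data.frame with
#'   `badge_id`, `start`, `end`), `ir`, `accel`, `beacon` (as in
#'   [simulate_streams()]), and attribute `malformed` (named count of dropped
#'   rows per file).
#' @export
read_streams <- function(dir) {
  malformed <- c(ir = 0L, accel = 0L, beacon = 0L, schedule = 0L)

  ro <- read_csv_checked(file.path(dir, "roster.csv"),
                         c("badge_id", "profession"))
  roster <- as_plain_df(ro)
  class(roster) <- c("sb_roster", "data.frame")

  zo <- read_csv_checked(file.path(dir, "zones.csv"),
                         c("beacon_id", "zone_id", "category"))
  zones <- unique(as_plain_df(zo[, c("zone_id", "category")]))
  zones <- zones[order(match(zones$zone_id, zo$zone_id)), ]
  rownames(zones) <- NULL
  zone_map <- structure(list(zones = zones, beacons = as_plain_df(zo)),
                        class = "sb_zone_map")

  sc <- read_csv_checked(file.path(dir, "schedule.csv"),
                         c("badge_id", "start_iso", "end_iso"))
  s1 <- parse_iso(sc$start_iso)
  s2 <- parse_iso(sc$end_iso)
  ok <- !is.na(s1) & !is.na(s2)
  malformed["schedule"] <- sum(!ok)
  schedule <- data.frame(badge_id = sc$badge_id[ok], start = s1[ok],
                         end = s2[ok], stringsAsFactors = FALSE)

  ir <- read_csv_checked(file.path(dir, "ir.csv"),
                         c("timestamp_iso", "observer_badge", "observed_badge"))
  tt <- parse_iso(ir$timestamp_iso)
  ok <- !is.na(tt)
  malformed["ir"] <- sum(!ok)
  ir_df <- data.frame(timestamp = tt[ok], observer_badge = ir$observer_badge[ok],
                      observed_badge = ir$observed_badge[ok],
                      stringsAsFactors = FALSE)
  ir_df <- ir_df[order(ir_df$timestamp, ir_df$observer_badge,
                       ir_df$observed_badge), ]

  ac <- read_csv_checked(file.path(dir, "accel.csv"),
                         c("timestamp_iso", "badge_id", "motion_hz"))
  tt <- parse_iso(ac$timestamp_iso)
  hz <- suppressWarnings(as.numeric(ac$motion_hz))
  ok <- !is.na(tt) & !is.na(hz)
  malformed["accel"] <- sum(!ok)
  accel_df <- data.frame(timestamp = tt[ok], badge_id = ac$badge_id[ok],
                         motion_hz = hz[ok], stringsAsFactors = FALSE)
  accel_df <- accel_df[order(accel_df$timestamp, accel_df$badge_id), ]

  be <- read_csv_checked(file.path(dir, "beacon.csv"),
                         c("timestamp_iso", "badge_id", "beacon_id"))
  tt <- parse_iso(be$timestamp_iso)
  ok <- !is.na(tt)
  malformed["beacon"] <- sum(!ok)
  beacon_df <- data.frame(timestamp = tt[ok], badge_id = be$badge_id[ok],
                          beacon_id = be$beacon_id[ok], stringsAsFactors = FALSE)
  beacon_df <- beacon_df[order(beacon_df$timestamp, beacon_df$badge_id), ]

  total_bad <- sum(malformed)
  if (total_bad > 0) {
    warning(sprintf("dropped %d malformed row(s): %s", total_bad,
                    paste(sprintf("%s=%d", names(malformed), malformed),
                          collapse = ", ")))
  }
  rownames(ir_df) <- rownames(accel_df) <- rownames(beacon_df) <- NULL
  structure(list(roster = roster, zone_map = zone_map, schedule = schedule,
                 ir = ir_df, accel = accel_df, beacon = beacon_df),
            class = "sb_dataset", malformed = malformed)
}

#' @export
print.sb_dataset <- function(x, ...) {
  cat(sprintf(
    "<sb_dataset> %d staff, %d zones; %d IR / %d motion / %d beacon records\n",
    nrow(x$roster), nrow(x$zone_map$zones), nrow(x$ir), nrow(x$accel),
    nrow(x$beacon)))
  invisible(x)
}
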