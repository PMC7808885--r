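#' Assign interactions to zones via beacon pings
#'
#' For each interaction, pools both participants' beacon pings with
#' timestamps in `[start, end)`, maps pings to zones, and assigns the zone
#' with the most pings; ties go to the zone pinged earliest, and an
#' interaction with no pings stays unassigned (`NA`) rather than being
#' dropped, so occupancy totals remain auditable. Pings referencing beacons
#' absent from the zone map are ignored with a warning.
#'
#' @param interactions An [classify_active()] result.
#' @param beacon Data.frame with `timestamp`, `badge_id`, `beacon_id`
#'   (timestamp-sorted).
#' @param zone_map A [make_zone_map()] zone map.
#' @return `interactions` with `zone_id` filled where determinable.
#' @export
assign_zones <- function(interactions, beacon, zone_map) {
  n <- nrow(interactions)
  if (n == 0 || nrow(beacon) == 0) {
    interactions$zone_id <- rep(NA_character_, n)
    return(interactions)
  }
  zone_of <- setNames(zone_map$beacons$zone_id, zone_map$beacons$beacon_id)
  unknown <- !(beacon$beacon_id %in% names(zone_of))
  if (any(unknown)) {
    warning(sprintf("ignored %d ping(s) referencing unknown beacons",
                    sum(unknown)))
    beacon <- beacon[!unknown, , drop = FALSE]
  }
  if (nrow(beacon) == 0) {
    interactions$zone_id <- rep(NA_character_, n)
    return(interactions)
  }
  ep <- data.table::data.table(
    id = rep(seq_len(n), 2L),
    badge_id = c(interactions$badge_a, interactions$badge_b),
    s = rep(as.numeric(interactions$start), 2L),
    e = rep(as.numeric(interactions$end), 2L))
  bc <- data.table::data.table(badge_id = beacon$badge_id,
                               t = as.numeric(beacon$timestamp),
                               zone_id = zone_of[beacon$beacon_id])
  hits <- bc[ep, on = c("badge_id", "t>=s", "t<e"),
             list(id = id, zone_id = x.zone_id, t = x.t), allow.cartesian = TRUE,
             nomatch = NULL]
  if (nrow(hits) == 0) {
    interactions$zone_id <- rep(NA_character_, n)
    return(interactions)
  }
  tally <- hits[, list(n_pings = .N, t_min = min(t)),
                by = list(id, zone_id)]
  data.table::setorder(tally, id, -n_pings, t_min, zone_id)
  best <- tally[!duplicated(tally$id), ]
  zone <- rep(NA_character_, n)
  zone[best$id] <- best$zone_id
  interactions$zone_id <- zone
  interactions
}

#' Daily zone occupancy of active interactions
#'
#' Accumulates active interaction pair-minutes per zone for interactions
#' starting on the given day (episodes spanning midnight count toward the day
#' they start). Interactions without a zone go to an explicit `unassigned`
#' bucket, so the per-zone totals plus the unassigned bucket always equal the
#' day's total active minutes.
#'
#' @param interactions Zone-assigned interactions ([assign_zones()]).
#' @param zone_map A [make_zone_map()] zone map.
#' @param day A `Date` (or string) naming the study day.
#' @param day_start_offset_min Minutes after midnight at which a day starts.
#' @return Data.frame (`zone_id`, `category`, `minutes`) covering every zone
#'   plus the `unassigned` row, class `sb_occupancy` with attribute `day`.
#' @export
daily_occupancy <- function(interactions, zone_map, day,
                            day_start_offset_min = 0) {
  day <- as.Date(day)
  sel <- interactions[
    day_label(interactions$start, day_start_offset_min) == day, , drop = FALSE]
  zones <- zone_map$zones
  minutes <- setNames(numeric(nrow(zones) + 1),
                      c(zones$zone_id, "unassigned"))
  if (nrow(sel)) {
    key <- ifelse(is.na(sel$zone_id), "unassigned", sel$zone_id)
    bad <- setdiff(unique(key), names(minutes))
    if (length(bad)) {
      stop("interaction assigned to zone absent from map: ",
           paste(bad, collapse = ", "))
    }
    agg <- tapply(sel$duration_min, key, sum)
    minutes[names(agg)] <- agg
  }
  out <- data.frame(
    zone_id = names(minutes),
    category = c(zones$category, "unassigned"),
    minutes = as.numeric(minutes), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("sb_occupancy", "data.frame"), day = day)
}

#' Rank interaction hotspots
#'
#' Top-`k` zones by accumulated minutes, descending; ties broken by
#' lexicographic zone id. The `unassigned` bucket is not a physical zone and
#' is excluded from the ranking.
#'
#' @param occupancy A [daily_occupancy()] result (or any data.frame with
#'   `zone_id` and `minutes`).
#' @param k Number of zones to return (at least 1); `k` beyond the number of
#'   zones returns all of them.
#' @return Data.frame (`zone_id`, `category` if present, `minutes`),
#'   non-increasing in minutes.
#' @export
hotspots <- function(occupancy, k) {
  stopifnot(k >= 1)
  occ <- occupancy[occupancy$zone_id != "unassigned", , drop = FALSE]
  occ <- occ[order(-occ$minutes, occ$zone_id), , drop = FALSE]
  out <- head(occ, k)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
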