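#' Default functional-area specification
#'
#' The itemized list of the 42 functional areas covered by location beacons:
#' 14 beds, a central nurses' station, a conference room, a consultation room,
#' a CT control room, 4 examination-and-procedure rooms, a family room,
#' 3 laboratories, a nurses' lounge, a physicians' lounge, 2 physician
#' stations, a reception, a satellite pharmacy, a shower room, 4 utility rooms
#' and 5 storage rooms. Corridors carry no beacons and are excluded by
#' construction. Beacons per area are chosen so the default map totals 249
#' beacons, denser in the patient area where detection coverage matters most.
#'
#' @return A data.frame with columns `category`, `count`, `beacons_per_area`.
#' @export
default_area_spec <- function() {
  data.frame(
    category = c("bed", "central_nurses_station", "conference_room",
                 "consultation_room", "ct_control_room",
                 "examination_procedure_room", "family_room", "laboratory",
                 "nurses_lounge", "physicians_lounge", "physician_station",
                 "reception", "satellite_pharmacy", "shower_room",
                 "utility_room", "storage_room"),
    count = c(14L, 1L, 1L, 1L, 1L, 4L, 1L, 3L, 1L, 1L, 2L, 1L, 1L, 1L, 4L, 5L),
    beacons_per_area = c(8L, 12L, 6L, 4L, 4L, 6L, 4L, 5L, 5L, 5L, 6L,
                         4L, 4L, 2L, 4L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Build a zone map
#'
#' Expands an area specification into zones (functional areas) and the
#' beacons installed in them. Zone ids are `category_index`; beacon ids are
#' globally unique `zoneid_bNN` tokens, each belonging to exactly one zone.
#'
#' @param area_spec A data.frame with columns `category`, `count`,
#'   `beacons_per_area` (positive integers). Defaults to [default_area_spec()],
#'   which yields 42 zones and 249 beacons.
#' @return An object of class `sb_zone_map`: a list with data.frames
#'   `zones` (`zone_id`, `category`) and `beacons`
#'   (`beacon_id`, `zone_id`, `category`).
#' @export
#' @examples
#' zm <- make_zone_map()
#' nrow(zm$zones)    # 42
#' nrow(zm$beacons)  # 249
make_zone_map <- function(area_spec = default_area_spec()) {
  need <- c("category", "count", "beacons_per_area")
  if (!all(need %in% names(area_spec))) {
    stop("area_spec needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(area_spec) == 0) {
    zones <- data.frame(zone_id = character(0), category = character(0))
    beacons <- data.frame(beacon_id = character(0), zone_id = character(0),
                          category = character(0))
    return(structure(list(zones = zones, beacons = beacons),
                     class = "sb_zone_map"))
  }
  if (any(area_spec$count < 1) || any(area_spec$beacons_per_area < 1)) {
    stop("count and beacons_per_area must be positive integers")
  }
  zones <- do.call(rbind, lapply(seq_len(nrow(area_spec)), function(i) {
    data.frame(
      zone_id = sprintf("%s_%02d", area_spec$category[i],
                        seq_len(area_spec$count[i])),
      category = area_spec$category[i],
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(zones$zone_id)) {
    stop("duplicate zone ids from category/index collision: ",
         paste(unique(zones$zone_id[duplicated(zones$zone_id)]),
               collapse = ", "))
  }
  bpa <- rep(area_spec$beacons_per_area, times = area_spec$count)
  beacons <- data.frame(
    beacon_id = sprintf("%s_b%02d", rep(zones$zone_id, times = bpa),
                        unlist(lapply(bpa, seq_len), use.names = FALSE)),
    zone_id = rep(zones$zone_id, times = bpa),
    category = rep(zones$category, times = bpa),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(beacons$beacon_id))
  structure(list(zones = zones, beacons = beacons), class = "sb_zone_map")
}

#' @export
print.sb_zone_map <- function(x, ...) {
  cat(sprintf("<sb_zone_map> %d zones, %d beacons, %d categories\n",
              nrow(x$zones), nrow(x$beacons), length(unique(x$zones$category))))
  invisible(x)
}
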