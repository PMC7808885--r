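#' Simulate raw badge event streams
#'
#' Generates the three raw sensor streams a badge system records: paired
#' dyadic infrared detections at a fixed tick while two badges are in an
#' encounter, per-minute body-motion frequency samples for every on-duty
#' badge ("conversing" while in an encounter, "idle" otherwise), and
#' per-minute location beacon pings (from the encounter's zone while
#' conversing, otherwise from a zone drawn by the badge's profession
#' propensities).
#'
#' Encounters arise per co-on-duty badge pair as a Poisson process whose
#' piecewise-constant intensity is the pair's mixing rate modulated by the
#' within-shift hourly weights and the handover multiplier (see
#' [mixing_model()]). Encounter durations are log-normal, truncated at the
#' end of the shared shift. All randomness is driven by labelled child seeds
#' of `seed` ([derive_seed()]), so identical inputs and seed reproduce the
#' streams exactly.
#'
#' @param roster A [make_roster()] roster.
#' @param schedule A [make_schedule()] schedule; every scheduled badge must
#'   appear in the roster.
#' @param zone_map A [make_zone_map()] zone map.
#' @param mixing A [mixing_model()].
#' @param seed Integer master seed (required).
#' @param tick_s Infrared detection tick in seconds (default 10: a 1-minute
#'   episode spans at least 6 ticks).
#' @param sample_period_s Motion/beacon sampling period in seconds
#'   (default 60).
#' @return An object of class `sb_streams`: a list with data.frames
#'   `ir` (`timestamp`, `observer_badge`, `observed_badge`),
#'   `accel` (`timestamp`, `badge_id`, `motion_hz`) and
#'   `beacon` (`timestamp`, `badge_id`, `beacon_id`), each sorted by time.
#' @export
#' @examples
#' r <- make_roster(c(nurse = 4, attending_physician = 2))
#' sch <- make_schedule(r, n_days = 1, target_hours = 8)
#' st <- simulate_streams(r, sch, make_zone_map(), mixing_model(), seed = 1)
#' nrow(st$ir) > 0
simulate_streams <- function(roster, schedule, zone_map,
                             mixing = mixing_model(), seed,
                             tick_s = 10, sample_period_s = 60) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("an explicit integer `seed` is required")
  }
  seed <- as.integer(seed)
  extra <- setdiff(unique(schedule$badge_id), roster$badge_id)
  if (length(extra)) {
    stop("badges scheduled but absent from roster: ",
         paste(extra, collapse = ", "))
  }
  prof <- profession_of(roster)
  handover_min <- attr(schedule, "handover_min") %||% 30
  shift_hr <- attr(schedule, "shift_length_hr") %||% 8

  empty <- sb_streams(
    ir = data.frame(timestamp = as_utc(character(0)),
                    observer_badge = character(0),
                    observed_badge = character(0)),
    accel = data.frame(timestamp = as_utc(character(0)),
                       badge_id = character(0), motion_hz = numeric(0)),
    beacon = data.frame(timestamp = as_utc(character(0)),
                        badge_id = character(0), beacon_id = character(0)))
  if (nrow(schedule) == 0) return(empty)

  # --- within-shift intensity segments -----------------------------------
  w <- mixing$shift_hour_weights
  if (length(w) != shift_hr) {
    stop("shift_hour_weights must have one weight per shift hour")
  }
  hm <- min(max(handover_min, 0), 60)
  seg_off <- c(0, hm * 60, seq_len(shift_hr - 1) * 3600)
  seg_wid <- diff(c(seg_off, shift_hr * 3600))
  seg_wt <- c(w[1] * mixing$handover_mult, w[1], w[-1])
  keep <- seg_wid > 0
  seg_off <- seg_off[keep]; seg_wid <- seg_wid[keep]; seg_wt <- seg_wt[keep]
  exposure_hr <- sum(seg_wid / 3600 * seg_wt)

  # --- co-on-duty pairs per shift slot -----------------------------------
  sl <- data.table::as.data.table(schedule)[, list(badge_id, start, end)]
  pairs <- merge(sl, sl, by = c("start", "end"), allow.cartesian = TRUE,
                 suffixes = c("_a", "_b"))
  pairs <- pairs[pairs$badge_id_a < pairs$badge_id_b, ]
  data.table::setorder(pairs, start, badge_id_a, badge_id_b)

  enc <- NULL
  if (nrow(pairs)) {
    pa <- prof[pairs$badge_id_a]; pb <- prof[pairs$badge_id_b]
    lambda <- mixing$rate_hr[cbind(pa, pb)] * exposure_hr
    set.seed(derive_seed(seed, "encounters"))
    n_enc <- rpois(length(lambda), lambda)
    if (sum(n_enc) > 0) {
      idx <- rep(seq_along(n_enc), n_enc)
      seg <- sample.int(length(seg_wt), sum(n_enc), replace = TRUE,
                        prob = seg_wid * seg_wt)
      off <- seg_off[seg] + floor(runif(sum(n_enc)) * seg_wid[seg])
      med <- mixing$dur_median_min
      med_enc <- if (is.matrix(med)) med[cbind(pa[idx], pb[idx])] else med
      set.seed(derive_seed(seed, "durations"))
      dur_s <- pmax(tick_s, round(60 * rlnorm(sum(n_enc), log(med_enc),
                                              mixing$dur_sdlog)))
      slot_start <- as.numeric(pairs$start)[idx]
      slot_end <- as.numeric(pairs$end)[idx]
      t_start <- pmin(slot_start + off, slot_end - tick_s)
      t_end <- pmin(t_start + dur_s, slot_end)
      enc <- data.table::data.table(
        badge_a = pairs$badge_id_a[idx], badge_b = pairs$badge_id_b[idx],
        prof_a = pa[idx], prof_b = pb[idx],
        t_start = t_start, t_end = t_end)
      enc$zone_id <- draw_encounter_zones(enc, mixing, zone_map, seed)
    }
  }

  # --- infrared stream ----------------------------------------------------
  if (!is.null(enc) && nrow(enc)) {
    n_ticks <- floor((enc$t_end - enc$t_start) / tick_s) + 1L
    ts <- rep(enc$t_start, n_ticks) + (sequence(n_ticks) - 1) * tick_s
    a <- rep(enc$badge_a, n_ticks); b <- rep(enc$badge_b, n_ticks)
    ir <- data.table::data.table(
      timestamp = c(ts, ts), observer_badge = c(a, b),
      observed_badge = c(b, a))
    data.table::setorder(ir, timestamp, observer_badge, observed_badge)
    ir$timestamp <- as.POSIXct(ir$timestamp, tz = "UTC",
                               origin = "1970-01-01")
  } else {
    ir <- data.table::as.data.table(empty$ir)
  }

  # --- per-minute on-duty sample grid ------------------------------------
  n_samp <- floor(as.numeric(sl$end - sl$start, units = "secs") /
                    sample_period_s)
  grid <- data.table::data.table(
    badge_id = rep(sl$badge_id, n_samp),
    t = rep(as.numeric(sl$start), n_samp) +
      (sequence(n_samp) - 1) * sample_period_s)
  data.table::setorder(grid, badge_id, t)

  # which samples fall inside an encounter of their badge (and which zone)
  grid$enc_zone <- NA_character_
  if (!is.null(enc) && nrow(enc)) {
    enc_long <- data.table::data.table(
      badge_id = c(enc$badge_a, enc$badge_b),
      s = c(enc$t_start, enc$t_start), e = c(enc$t_end, enc$t_end),
      zone_id = c(enc$zone_id, enc$zone_id))
    data.table::setorder(enc_long, badge_id, s, e)
    hit <- enc_long[grid, on = c("badge_id", "s<=t", "e>t"),
                    mult = "first", which = TRUE]
    grid$enc_zone <- enc_long$zone_id[hit]
  }
  conversing <- !is.na(grid$enc_zone)

  # --- accelerometer stream ----------------------------------------------
  set.seed(derive_seed(seed, "motion"))
  mu <- ifelse(conversing, mixing$motion_conversing_hz, mixing$motion_idle_hz)
  accel <- data.table::data.table(
    timestamp = grid$t, badge_id = grid$badge_id,
    motion_hz = round(rtnorm0(nrow(grid), mu, mixing$motion_sd_hz), 3))
  data.table::setorder(accel, timestamp, badge_id)
  accel$timestamp <- as.POSIXct(accel$timestamp, tz = "UTC",
                                origin = "1970-01-01")

  # --- beacon stream ------------------------------------------------------
  if (nrow(zone_map$zones)) {
    zone <- grid$enc_zone
    if (any(!conversing)) {
      zone[!conversing] <- draw_idle_zones(
        prof[grid$badge_id[!conversing]], mixing, zone_map, seed)
    }
    set.seed(derive_seed(seed, "beacon-pick"))
    beacon <- data.table::data.table(
      timestamp = grid$t, badge_id = grid$badge_id,
      beacon_id = draw_beacons(zone, zone_map))
    data.table::setorder(beacon, timestamp, badge_id)
    beacon$timestamp <- as.POSIXct(beacon$timestamp, tz = "UTC",
                                   origin = "1970-01-01")
  } else {
    beacon <- data.table::as.data.table(empty$beacon)
  }

  sb_streams(ir = as_plain_df(ir), accel = as_plain_df(accel),
             beacon = as_plain_df(beacon))
}

sb_streams <- function(ir, accel, beacon) {
  structure(list(ir = ir, accel = accel, beacon = beacon),
            class = "sb_streams")
}

#' @export
print.sb_streams <- function(x, ...) {
  cat(sprintf(
    "<sb_streams> %d IR detections, %d motion samples, %d beacon pings\n",
    nrow(x$ir), nrow(x$accel), nrow(x$beacon)))
  invisible(x)
}

as_plain_df <- function(dt) {
  out <- as.data.frame(dt)
  rownames(out) <- NULL
  out
}

# Draw one zone per encounter from the averaged profession propensities of
# the two participants, category first, then uniformly within the category.
draw_encounter_zones <- function(enc, mixing, zone_map, seed) {
  if (nrow(zone_map$zones) == 0) return(rep(NA_character_, nrow(enc)))
  set.seed(derive_seed(seed, "zone-category"))
  zp <- mixing$zone_propensity
  cats <- colnames(zp)
  key <- paste(enc$prof_a, enc$prof_b, sep = "|")
  cat_draw <- character(nrow(enc))
  for (k in sort(unique(key))) {
    sel <- which(key == k)
    pq <- strsplit(k, "|", fixed = TRUE)[[1]]
    pr <- (zp[pq[1], ] + zp[pq[2], ]) / 2
    cat_draw[sel] <- cats[sample.int(length(cats), length(sel),
                                     replace = TRUE, prob = pr)]
  }
  set.seed(derive_seed(seed, "zone-within"))
  draw_zone_in_category(cat_draw, zone_map)
}

draw_idle_zones <- function(professions, mixing, zone_map, seed) {
  set.seed(derive_seed(seed, "idle-category"))
  zp <- mixing$zone_propensity
  cats <- colnames(zp)
  cat_draw <- character(length(professions))
  for (p in sort(unique(professions))) {
    sel <- which(professions == p)
    cat_draw[sel] <- cats[sample.int(length(cats), length(sel),
                                     replace = TRUE, prob = zp[p, ])]
  }
  set.seed(derive_seed(seed, "idle-zone"))
  draw_zone_in_category(cat_draw, zone_map)
}

draw_zone_in_category <- function(cat_draw, zone_map) {
  zones_by_cat <- split(zone_map$zones$zone_id, zone_map$zones$category)
  out <- character(length(cat_draw))
  for (cc in sort(unique(cat_draw))) {
    sel <- which(cat_draw == cc)
    zz <- zones_by_cat[[cc]]
    if (is.null(zz)) stop("no zones of category ", cc, " in zone map")
    out[sel] <- zz[sample.int(length(zz), length(sel), replace = TRUE)]
  }
  out
}

draw_beacons <- function(zone_ids, zone_map) {
  by_zone <- split(zone_map$beacons$beacon_id, zone_map$beacons$zone_id)
  out <- character(length(zone_ids))
  for (z in sort(unique(zone_ids))) {
    sel <- which(zone_ids == z)
    bb <- by_zone[[z]]
    out[sel] <- bb[sample.int(length(bb), length(sel), replace = TRUE)]
  }
  out
}
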