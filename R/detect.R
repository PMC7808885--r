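#' Detection configuration
#'
#' Parameters of the active-interaction rule: a dyadic face-to-face episode
#' counts as active communication when it lasts more than `min_duration_min`
#' minutes and body-motion frequency exceeds `motion_threshold_hz`
#' (both comparisons strict). The motion gate is evaluated under
#' `motion_rule`: `"either"` (default; the larger of the two participants'
#' episode means must exceed the threshold), `"both"` (the smaller must), or
#' `"mean"` (the pairwise mean must).
#'
#' @param motion_threshold_hz Motion gate in Hz (default 2).
#' @param min_duration_min Duration gate in minutes (default 1).
#' @param gap_tolerance_s Maximum gap between successive infrared detections
#'   of the same pair merged into one episode (default 60 s: bridges brief
#'   occlusions without joining distinct meetings).
#' @param motion_rule One of `"either"`, `"both"`, `"mean"`.
#' @param ir_tick_s Infrared sampling tick in seconds; an episode extends one
#'   tick beyond its last detection (default 10).
#' @return A list of class `sb_detection_config`.
#' @export
detection_config <- function(motion_threshold_hz = 2.0, min_duration_min = 1.0,
                             gap_tolerance_s = 60, motion_rule = "either",
                             ir_tick_s = 10) {
  stopifnot(motion_threshold_hz > 0, min_duration_min > 0,
            gap_tolerance_s >= 0, ir_tick_s > 0)
  motion_rule <- match.arg(motion_rule, c("either", "both", "mean"))
  structure(list(motion_threshold_hz = motion_threshold_hz,
                 min_duration_min = min_duration_min,
                 gap_tolerance_s = gap_tolerance_s,
                 motion_rule = motion_rule, ir_tick_s = ir_tick_s),
            class = "sb_detection_config")
}

empty_episodes <- function() {
  out <- data.frame(badge_a = character(0), badge_b = character(0),
                    start = as_utc(character(0)), end = as_utc(character(0)),
                    duration_min = numeric(0), n_detections = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("sb_episodes", "data.frame")
  out
}

#' Segment infrared detections into face-to-face episodes
#'
#' Symmetrizes observer/observed, de-duplicates paired detections, and merges
#' each unordered badge pair's maximal runs of detections with inter-record
#' gaps of at most `gap_tolerance_s` into one episode. An episode ends one
#' infrared tick after its last detection. Records where a badge observes
#' itself are skipped with a warning.
#'
#' @param ir Data.frame with `timestamp`, `observer_badge`, `observed_badge`
#'   (timestamp-sorted, as from [read_streams()]).
#' @param config A [detection_config()].
#' @return Episodes: data.frame (`badge_a` < `badge_b`, `start`, `end`,
#'   `duration_min`, `n_detections`), class `sb_episodes`, ordered by
#'   start time.
#' @export
segment_episodes <- function(ir, config = detection_config()) {
  if (nrow(ir) == 0) return(empty_episodes())
  self <- ir$observer_badge == ir$observed_badge
  if (any(self)) {
    warning(sprintf("skipped %d self-observation record(s)", sum(self)))
    ir <- ir[!self, , drop = FALSE]
  }
  if (nrow(ir) == 0) return(empty_episodes())
  dt <- data.table::data.table(
    badge_a = pmin(ir$observer_badge, ir$observed_badge),
    badge_b = pmax(ir$observer_badge, ir$observed_badge),
    t = as.numeric(ir$timestamp))
  dt <- unique(dt)
  data.table::setorder(dt, badge_a, badge_b, t)
  gap <- c(Inf, diff(dt$t))
  new_pair <- c(TRUE, dt$badge_a[-1] != dt$badge_a[-nrow(dt)] |
                  dt$badge_b[-1] != dt$badge_b[-nrow(dt)])
  ep <- cumsum(new_pair | gap > config$gap_tolerance_s)
  out <- dt[, list(badge_a = badge_a[1], badge_b = badge_b[1],
                   t_start = min(t), t_last = max(t), n_detections = .N),
            by = list(episode_id = ep)]
  res <- data.frame(
    badge_a = out$badge_a, badge_b = out$badge_b,
    start = as.POSIXct(out$t_start, tz = "UTC", origin = "1970-01-01"),
    end = as.POSIXct(out$t_last + config$ir_tick_s, tz = "UTC",
                     origin = "1970-01-01"),
    n_detections = out$n_detections, stringsAsFactors = FALSE)
  res$duration_min <- as.numeric(res$end - res$start, units = "mins")
  res <- res[order(res$start, res$badge_a, res$badge_b),
             c("badge_a", "badge_b", "start", "end", "duration_min",
               "n_detections")]
  rownames(res) <- NULL
  class(res) <- c("sb_episodes", "data.frame")
  res
}

#' Attach per-participant mean motion frequency to episodes
#'
#' For each episode and participant, averages the participant's motion
#' samples with timestamps in `[start, end)`. A participant without samples
#' in the window gets mean 0 and is flagged in `motion_missing_a`/`_b`.
#'
#' @param episodes An [segment_episodes()] result.
#' @param accel Data.frame with `timestamp`, `badge_id`, `motion_hz`
#'   (timestamp-sorted).
#' @return `episodes` with columns `motion_a_hz`, `motion_b_hz`,
#'   `motion_missing_a`, `motion_missing_b` added.
#' @export
attach_motion <- function(episodes, accel) {
  n <- nrow(episodes)
  if (n == 0) {
    episodes$motion_a_hz <- numeric(0)
    episodes$motion_b_hz <- numeric(0)
    episodes$motion_missing_a <- logical(0)
    episodes$motion_missing_b <- logical(0)
    return(episodes)
  }
  mean_for <- function(badges) {
    if (nrow(accel) == 0) return(rep(NA_real_, n))
    ep <- data.table::data.table(
      id = seq_len(n), badge_id = badges,
      s = as.numeric(episodes$start), e = as.numeric(episodes$end))
    ac <- data.table::data.table(badge_id = accel$badge_id,
                                 t = as.numeric(accel$timestamp),
                                 motion_hz = accel$motion_hz)
    hit <- ac[ep, on = c("badge_id", "t>=s", "t<e"),
              list(m = mean(motion_hz)), by = .EACHI]
    res <- rep(NA_real_, n)
    res[ep$id] <- hit$m
    res
  }
  ma <- mean_for(episodes$badge_a)
  mb <- mean_for(episodes$badge_b)
  episodes$motion_a_hz <- ifelse(is.na(ma), 0, ma)
  episodes$motion_b_hz <- ifelse(is.na(mb), 0, mb)
  episodes$motion_missing_a <- is.na(ma)
  episodes$motion_missing_b <- is.na(mb)
  episodes
}

motion_statistic <- function(episodes, rule) {
  switch(rule,
         either = pmax(episodes$motion_a_hz, episodes$motion_b_hz),
         both = pmin(episodes$motion_a_hz, episodes$motion_b_hz),
         mean = (episodes$motion_a_hz + episodes$motion_b_hz) / 2,
         stop("unknown motion rule: ", rule))
}

#' Classify episodes as active face-to-face interactions
#'
#' Applies the active-communication rule: duration strictly greater than the
#' duration gate and episode motion strictly above the motion gate under the
#' configured rule. With the defaults this is the "exceeded 2 Hz for more
#' than 1 minute" criterion.
#'
#' @param episodes Episodes carrying motion means ([attach_motion()]).
#' @param config A [detection_config()].
#' @param keep_all If `TRUE`, return all episodes with a logical `active`
#'   column instead of only the active subset.
#' @return Active interactions: the episode columns plus `active` (all `TRUE`
#'   unless `keep_all`) and `zone_id` (`NA` until [assign_zones()]), class
#'   `sb_interactions`.
#' @export
classify_active <- function(episodes, config = detection_config(),
                            keep_all = FALSE) {
  need <- c("motion_a_hz", "motion_b_hz")
  if (!all(need %in% names(episodes))) {
    stop("episodes lack motion means; run attach_motion() first")
  }
  stat <- motion_statistic(episodes, config$motion_rule)
  act <- episodes$duration_min > config$min_duration_min &
    stat > config$motion_threshold_hz
  out <- episodes
  out$active <- act
  if (!keep_all) out <- out[act, , drop = FALSE]
  if (is.null(out$zone_id)) out$zone_id <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("sb_interactions", "data.frame")
  out
}

#' Interaction-intensity time series
#'
#' Bins active interactions into fixed-width bins, apportioning each
#' interaction's duration to bins by exact overlap, so the series conserves
#' total active pair-minutes within the window.
#'
#' @param interactions Active interactions ([classify_active()]).
#' @param bin_width_min Bin width in minutes; must divide 1440.
#' @param window Optional POSIXct length-2 window; defaults to the smallest
#'   whole-day span covering the interactions.
#' @return Data.frame (`bin_start`, `pair_minutes`), class
#'   `sb_intensity`, with `bin_width_min` as an attribute.
#' @export
intensity_series <- function(interactions, bin_width_min = 60, window = NULL) {
  if (1440 %% bin_width_min != 0) {
    stop("bin_width_min must divide 1440 (24 h)")
  }
  bw <- bin_width_min * 60
  if (is.null(window)) {
    if (nrow(interactions) == 0) {
      stop("no interactions and no explicit window")
    }
    d0 <- as.POSIXct(format(min(interactions$start), "%Y-%m-%d"), tz = "UTC")
    d1 <- max(interactions$end)
    nday <- ceiling(as.numeric(d1 - d0, units = "days"))
    window <- c(d0, d0 + max(nday, 1) * 86400)
  }
  w0 <- as.numeric(window[1]); w1 <- as.numeric(window[2])
  stopifnot(w1 > w0)
  bins <- seq(w0, w1 - 1, by = bw)
  minutes <- numeric(length(bins))
  if (nrow(interactions)) {
    s <- pmax(as.numeric(interactions$start), w0)
    e <- pmin(as.numeric(interactions$end), w1)
    ok <- which(e > s)
    if (length(ok)) {
      first <- floor((s[ok] - w0) / bw)
      last <- ceiling((e[ok] - w0) / bw) - 1
      nb <- last - first + 1L
      idx <- rep(first, nb) + (sequence(nb) - 1L)       # 0-based bin index
      lo <- pmax(rep(s[ok], nb), w0 + idx * bw)
      hi <- pmin(rep(e[ok], nb), w0 + (idx + 1) * bw)
      contrib <- (hi - lo) / 60
      agg <- rowsum(contrib, idx)
      minutes[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
  }
  out <- data.frame(
    bin_start = as.POSIXct(bins, tz = "UTC", origin = "1970-01-01"),
    pair_minutes = minutes)
  structure(out, class = c("sb_intensity", "data.frame"),
            bin_width_min = bin_width_min, window = window)
}

#' Average a series over days into a time-of-day profile
#'
#' @param series An [intensity_series()] result covering whole days.
#' @param day_start_offset_min Minutes after midnight at which the analysis
#'   day starts (default 0).
#' @return Named numeric vector of mean pair-minutes per time-of-day bin.
#' @export
daily_profile <- function(series, day_start_offset_min = 0) {
  bw <- attr(series, "bin_width_min")
  per_day <- 1440 %/% bw
  tod <- (floor((as.numeric(series$bin_start) / 60 - day_start_offset_min))
          %% 1440) %/% bw
  prof <- tapply(series$pair_minutes, tod, mean)
  full <- setNames(numeric(per_day), as.character(0:(per_day - 1)))
  full[names(prof)] <- prof
  names(full) <- sprintf("%02d:%02d", (as.integer(names(full)) * bw) %/% 60,
                         (as.integer(names(full)) * bw) %% 60)
  full
}

#' Count strict local maxima in a circular daily profile
#'
#' A bin is a peak when its value strictly exceeds both circular neighbours.
#'
#' @param profile Numeric vector (one day of bins, wrapping around midnight).
#' @return Integer peak count.
#' @export
count_daily_peaks <- function(profile) {
  n <- length(profile)
  if (n < 3) return(0L)
  left <- profile[c(n, seq_len(n - 1))]
  right <- profile[c(seq_len(n - 1) + 1, 1)]
  sum(profile > left & profile > right)
}
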