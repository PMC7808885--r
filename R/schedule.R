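#' Build a three-shift work schedule
#'
#' Assigns each badge a seeded random rotation over the study's shift slots.
#' The day is divided into three shifts whose starts are spaced 8 hours apart
#' (day, evening, night); every shift change is a handover window. Each badge
#' works `round(target_hours / shift_length_hr)` whole shifts drawn without
#' replacement from the slot grid, so scheduled hours hit the target exactly
#' when it is a multiple of the shift length and within 2% otherwise
#' (larger discrepancies are rejected as infeasible).
#'
#' @param roster An [make_roster()] roster.
#' @param start_date First study day (Date or `"YYYY-MM-DD"`).
#' @param n_days Number of study days (default 28, a 4-week window).
#' @param shift_starts_hr Template of daily shift start hours; must be three
#'   starts exactly 8 h apart (default `c(0, 8, 16)`).
#' @param shift_length_hr Shift length in hours (default 8).
#' @param target_hours Target mean on-duty hours per badge over the window
#'   (default 160, i.e. 20 shifts in 4 weeks).
#' @param handover_min Handover window length in minutes after each shift
#'   start (default 30).
#' @param seed Integer seed for the slot assignment.
#' @return A data.frame (`badge_id`, `start`, `end`) of on-duty intervals,
#'   sorted and non-overlapping per badge, class `sb_schedule`, with the
#'   template stored in attributes `shift_starts_hr`, `shift_length_hr`,
#'   `handover_min`, `start_date`, `n_days`.
#' @export
#' @examples
#' sch <- make_schedule(make_roster(), n_days = 7, target_hours = 40)
#' mean(as.numeric(sch$end - sch$start, units = "hours")) # 8
make_schedule <- function(roster, start_date = "2019-10-01", n_days = 28,
                          shift_starts_hr = c(0, 8, 16), shift_length_hr = 8,
                          target_hours = 160, handover_min = 30, seed = 1L) {
  stopifnot(n_days >= 1)
  if (length(shift_starts_hr) != 3 ||
      any(diff(shift_starts_hr) != shift_length_hr) ||
      shift_length_hr * 3 != 24) {
    stop("template must have 3 daily shift starts exactly 8 h apart")
  }
  t0 <- as_utc(paste0(as.character(as.Date(start_date)), " 00:00:00")) +
    shift_starts_hr[1] * 3600
  n_slots <- 3L * as.integer(n_days)
  k <- as.integer(round(target_hours / shift_length_hr))
  if (k < 1L || k > n_slots) {
    stop(sprintf("target of %g h is infeasible over %d days", target_hours,
                 n_days))
  }
  if (abs(k * shift_length_hr - target_hours) / target_hours > 0.02) {
    stop(sprintf(
      "target of %g h is not attainable within 2%% using whole %g-h shifts",
      target_hours, shift_length_hr))
  }
  n <- nrow(roster)
  slot_starts <- t0 + (seq_len(n_slots) - 1L) * shift_length_hr * 3600
  if (n == 0) {
    out <- data.frame(badge_id = character(0),
                      start = slot_starts[0], end = slot_starts[0])
  } else {
    set.seed(derive_seed(seed, "schedule"))
    picks <- lapply(seq_len(n), function(i) sort(sample.int(n_slots, k)))
    out <- data.frame(
      badge_id = rep(roster$badge_id, each = k),
      start = slot_starts[unlist(picks, use.names = FALSE)],
      stringsAsFactors = FALSE
    )
    out$end <- out$start + shift_length_hr * 3600
  }
  structure(out,
            class = c("sb_schedule", "data.frame"),
            shift_starts_hr = shift_starts_hr,
            shift_length_hr = shift_length_hr,
            handover_min = handover_min,
            start_date = as.Date(start_date),
            n_days = as.integer(n_days))
}

#' @export
print.sb_schedule <- function(x, ...) {
  hrs <- if (nrow(x)) sum(as.numeric(x$end - x$start, units = "hours")) else 0
  cat(sprintf(
    "<sb_schedule> %d shifts, %d badges, %d days, %.1f mean h/badge\n",
    nrow(x), length(unique(x$badge_id)), attr(x, "n_days"),
    if (length(unique(x$badge_id))) hrs / length(unique(x$badge_id)) else 0))
  invisible(x)
}

#' Scheduled hours per badge
#'
#' @param schedule An [make_schedule()] schedule.
#' @return Named numeric vector of on-duty hours per badge.
#' @export
scheduled_hours <- function(schedule) {
  if (!nrow(schedule)) return(setNames(numeric(0), character(0)))
  h <- tapply(as.numeric(schedule$end - schedule$start, units = "hours"),
              schedule$badge_id, sum)
  setNames(as.numeric(h), names(h))
}
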