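default_rate_matrix <- function() {
  p <- profession_levels()
  m <- matrix(0.05, 9, 9, dimnames = list(p, p))
  set_rate <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  # Nurse-centred mixing: nurses interact most with each other, substantially
  # with nursing assistants and doctors; assistants avoid doctors; clerical
  # staff mix mainly among themselves.
  set_rate("nurse", "nurse", 2.40)
  set_rate("nurse", "nursing_assistant", 1.00)
  set_rate("nurse", "attending_physician", 0.50)
  set_rate("nurse", "senior_resident", 0.50)
  set_rate("nurse", "resident", 0.40)
  set_rate("nurse", "medical_technician", 0.35)
  set_rate("nurse", "pharmacist", 0.40)
  set_rate("nurse", "receptionist", 0.15)
  set_rate("nurse", "secretary", 0.10)
  set_rate("attending_physician", "attending_physician", 0.30)
  set_rate("attending_physician", "senior_resident", 0.35)
  set_rate("attending_physician", "resident", 0.30)
  set_rate("attending_physician", "nursing_assistant", 0.08)
  set_rate("attending_physician", "medical_technician", 0.15)
  set_rate("attending_physician", "pharmacist", 0.25)
  set_rate("attending_physician", "secretary", 0.15)
  set_rate("senior_resident", "senior_resident", 0.25)
  set_rate("senior_resident", "resident", 0.30)
  set_rate("senior_resident", "nursing_assistant", 0.08)
  set_rate("senior_resident", "medical_technician", 0.15)
  set_rate("senior_resident", "pharmacist", 0.20)
  set_rate("resident", "resident", 0.20)
  set_rate("resident", "nursing_assistant", 0.08)
  set_rate("resident", "medical_technician", 0.12)
  set_rate("resident", "pharmacist", 0.15)
  set_rate("nursing_assistant", "nursing_assistant", 1.20)
  set_rate("nursing_assistant", "medical_technician", 0.10)
  set_rate("medical_technician", "medical_technician", 0.40)
  set_rate("receptionist", "receptionist", 0.40)
  set_rate("receptionist", "secretary", 0.30)
  set_rate("secretary", "secretary", 0.30)
  m
}

default_zone_propensity <- function() {
  cats <- default_area_spec()$category
  p <- profession_levels()
  z <- matrix(0, length(p), length(cats), dimnames = list(p, cats))
  put <- function(prof, ...) {
    v <- c(...)
    z[prof, names(v)] <<- v
  }
  put("nurse", bed = .52, central_nurses_station = .30,
      examination_procedure_room = .05, utility_room = .04,
      nurses_lounge = .02, storage_room = .02, laboratory = .01,
      conference_room = .02, consultation_room = .01, physician_station = .01)
  put("attending_physician", bed = .34, physician_station = .22,
      conference_room = .10, examination_procedure_room = .08,
      physicians_lounge = .08, central_nurses_station = .06,
      ct_control_room = .05, consultation_room = .04, laboratory = .03)
  put("senior_resident", bed = .36, physician_station = .20,
      conference_room = .10, examination_procedure_room = .10,
      physicians_lounge = .06, central_nurses_station = .08,
      ct_control_room = .04, consultation_room = .03, laboratory = .03)
  z["resident", ] <- z["senior_resident", ]
  put("nursing_assistant", bed = .45, central_nurses_station = .20,
      utility_room = .15, storage_room = .10, nurses_lounge = .03,
      examination_procedure_room = .05, shower_room = .02)
  put("medical_technician", laboratory = .40, bed = .25,
      examination_procedure_room = .15, ct_control_room = .08,
      central_nurses_station = .07, utility_room = .05)
  put("receptionist", reception = .70, conference_room = .05,
      central_nurses_station = .15, family_room = .10)
  put("pharmacist", satellite_pharmacy = .55, bed = .15,
      central_nurses_station = .15, physician_station = .05,
      storage_room = .05, laboratory = .05)
  put("secretary", reception = .35, conference_room = .20,
      physician_station = .15, central_nurses_station = .15,
      family_room = .05, physicians_lounge = .10)
  stopifnot(all(abs(rowSums(z) - 1) < 1e-9))
  z
}

#' Profession-level mixing model for the stream generator
#'
#' Parameters of the synthetic encounter process. Encounters arise per
#' co-on-duty badge pair as an inhomogeneous Poisson process:
#' `rate_hr[p, q]` encounters per pair-hour at peak activity, modulated by a
#' within-shift hourly weight profile and a handover burst multiplier on the
#' first `handover_min` minutes of every shift. Episode durations are
#' log-normal; per-minute body-motion samples are truncated normal with a
#' "conversing" and an "idle" mode straddling the 2 Hz detection gate; the
#' zone of an encounter is drawn from the average of the two participants'
#' profession-level zone-category propensities.
#'
#' The default within-shift weights `(1, 0.5, 0.22, 0.08, 0, 0, 0, 0)`
#' concentrate sustained conversation around the handover and the
#' post-handover round, tapering to none late in the shift; combined with the
#' 3x handover multiplier this yields the three-peaks-per-day intensity
#' pattern at 8-hour spacing that the analysis stages expect.
#'
#' @param rate_hr Symmetric non-negative 9x9 encounter-rate matrix
#'   (encounters per co-on-duty pair-hour at weight 1), dimnames
#'   [profession_levels()].
#' @param dur_median_min,dur_sdlog Log-normal episode duration parameters:
#'   median in minutes and shape (sdlog). Defaults 2 and 0.8.
#' @param motion_conversing_hz,motion_idle_hz,motion_sd_hz Means and common sd
#'   of the truncated-normal (at 0) per-minute motion-frequency samples, in Hz.
#'   Defaults 2.5, 1.0, 0.5.
#' @param handover_mult Encounter-rate multiplier inside handover windows
#'   (default 3).
#' @param shift_hour_weights Non-negative relative encounter intensity for
#'   each hour of an 8-hour shift.
#' @param zone_propensity Row-stochastic 9 x n-category matrix of zone-category
#'   propensities per profession.
#' @return A list of the above, class `sb_mixing_model`.
#' @export
mixing_model <- function(rate_hr = default_rate_matrix(),
                         dur_median_min = 2, dur_sdlog = 0.8,
                         motion_conversing_hz = 2.5, motion_idle_hz = 1.0,
                         motion_sd_hz = 0.5, handover_mult = 3,
                         shift_hour_weights = c(1, 0.5, 0.22, 0.08, 0, 0, 0, 0),
                         zone_propensity = default_zone_propensity()) {
  stopifnot(is.matrix(rate_hr), nrow(rate_hr) == 9, ncol(rate_hr) == 9)
  if (!isTRUE(all.equal(rate_hr, t(rate_hr)))) {
    stop("rate_hr must be symmetric")
  }
  if (any(rate_hr < 0)) stop("rate_hr must be non-negative")
  stopifnot(dur_median_min > 0, dur_sdlog > 0, motion_conversing_hz > 0,
            motion_idle_hz > 0, motion_sd_hz > 0, handover_mult >= 0,
            all(shift_hour_weights >= 0), any(shift_hour_weights > 0))
  stopifnot(is.matrix(zone_propensity), nrow(zone_propensity) == 9,
            all(zone_propensity >= 0),
            all(abs(rowSums(zone_propensity) - 1) < 1e-8))
  structure(
    list(rate_hr = rate_hr, dur_median_min = dur_median_min,
         dur_sdlog = dur_sdlog, motion_conversing_hz = motion_conversing_hz,
         motion_idle_hz = motion_idle_hz, motion_sd_hz = motion_sd_hz,
         handover_mult = handover_mult,
         shift_hour_weights = shift_hour_weights,
         zone_propensity = zone_propensity),
    class = "sb_mixing_model")
}

#' @export
print.sb_mixing_model <- function(x, ...) {
  cat(sprintf(
    "<sb_mixing_model> peak rates %.2g-%.2g /pair-h, durations lognormal(median %g min, sdlog %g),\n  handover x%g, motion conversing/idle %g/%g Hz (sd %g)\n",
    min(x$rate_hr), max(x$rate_hr), x$dur_median_min, x$dur_sdlog,
    x$handover_mult, x$motion_conversing_hz, x$motion_idle_hz, x$motion_sd_hz))
  invisible(x)
}
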