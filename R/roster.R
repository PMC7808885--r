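#' The nine staff professions
#'
#' The closed set of profession labels used throughout the package, in the
#' fixed order used for profession-by-profession matrices.
#'
#' @return Character vector of length 9.
#' @export
profession_levels <- function() {
  c("attending_physician", "nurse", "senior_resident", "resident",
    "nursing_assistant", "medical_technician", "receptionist",
    "pharmacist", "secretary")
}

#' Professions counted as doctors in report summaries
#'
#' @return Character vector (attending physicians and residents).
#' @export
doctor_professions <- function() {
  c("attending_physician", "senior_resident", "resident")
}

#' Default staff composition
#'
#' Per-profession head counts of the emulated 76-member ICU staff:
#' 15 attending physicians, 39 nurses, 4 senior residents, 1 resident,
#' 4 nursing assistants, 8 medical technicians, 2 receptionists,
#' 1 pharmacist and 2 secretaries.
#'
#' @return Named integer vector over [profession_levels()].
#' @export
default_profession_counts <- function() {
  setNames(
    c(15L, 39L, 4L, 1L, 4L, 8L, 2L, 1L, 2L),
    profession_levels()
  )
}

badge_prefixes <- c(
  attending_physician = "doc", nurse = "nur", senior_resident = "snr",
  resident = "res", nursing_assistant = "nas", medical_technician = "tec",
  receptionist = "rcp", pharmacist = "phm", secretary = "sec"
)

#' Build a staff roster
#'
#' Creates the node universe of every downstream network: one badge per staff
#' member, with a deterministic badge id (profession prefix plus index).
#'
#' @param counts Named vector of non-negative head counts keyed by profession
#'   (see [profession_levels()]); missing professions mean zero. Defaults to
#'   the 76-member composition of [default_profession_counts()].
#' @return A data.frame with columns `badge_id`, `profession`
#'   (class `sb_roster`).
#' @export
#' @examples
#' r <- make_roster()
#' nrow(r)                       # 76
#' sum(r$profession == "nurse")  # 39
make_roster <- function(counts = default_profession_counts()) {
  levels <- profession_levels()
  if (is.null(names(counts)) && length(counts) > 0) {
    stop("`counts` must be named by profession")
  }
  unknown <- setdiff(names(counts), levels)
  if (length(unknown)) {
    stop("unknown professions: ", paste(unknown, collapse = ", "))
  }
  full <- setNames(integer(length(levels)), levels)
  full[names(counts)] <- as.integer(counts)
  neg <- names(full)[full < 0]
  if (length(neg)) {
    stop("negative count for profession: ", paste(neg, collapse = ", "))
  }
  profession <- rep(levels, times = full)
  badge_id <- unlist(lapply(levels[full > 0], function(p) {
    sprintf("%s_%02d", badge_prefixes[[p]], seq_len(full[[p]]))
  }), use.names = FALSE)
  if (is.null(badge_id)) badge_id <- character(0)
  out <- data.frame(badge_id = badge_id, profession = profession,
                    stringsAsFactors = FALSE)
  class(out) <- c("sb_roster", "data.frame")
  out
}

#' @export
print.sb_roster <- function(x, ...) {
  cat(sprintf("<sb_roster> %d staff across %d professions\n",
              nrow(x), length(unique(x$profession))))
  if (nrow(x)) print(table(factor(x$profession, profession_levels())))
  invisible(x)
}

# profession lookup as a named vector badge_id -> profession
profession_of <- function(roster) {
  setNames(roster$profession, roster$badge_id)
}
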