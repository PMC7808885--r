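#' Derive a child seed from a master seed and a label
#'
#' Sub-streams of the generator (encounters, durations, motion, beacons, ...)
#' each reseed the RNG with a seed derived deterministically from the master
#' seed and a stage label, so individual components are reproducible in
#' isolation.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "encounters")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(abs(as.integer(seed))) %% m
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% m # 31*m + 255 < 2^53: exact in double arithmetic
  }
  as.integer(h %% (m - 1L) + 1)
}

# Fixed UTC offset for all on-disk timestamps.
ISO_SUFFIX <- "+00:00"

format_iso <- function(t) {
  if (length(t) == 0) return(character(0))
  paste0(format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"), ISO_SUFFIX)
}

parse_iso <- function(x) {
  as.POSIXct(sub("\\+00:00$", "", x), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  as.POSIXct(x, tz = "UTC")
}

# Day label (UTC calendar date) with an optional day-start offset in minutes:
# timestamps earlier than the offset count toward the previous day.
day_label <- function(t, day_start_offset_min = 0) {
  as.Date(t - day_start_offset_min * 60, tz = "UTC")
}

# Truncated-normal sampler, lower bound 0, via inverse-CDF (vectorised means).
rtnorm0 <- function(n, mean, sd) {
  lo <- pnorm(0, mean = mean, sd = sd)
  qnorm(runif(n, min = lo, max = 1), mean = mean, sd = sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
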