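default_config <- function() {
  list(
    seed = 1L,
    simulate = TRUE,
    in_dir = NULL,
    out_dir = "sociobadge_out",
    roster_counts = as.list(default_profession_counts()),
    n_days = 28L,
    start_date = "2019-10-01",
    target_hours = 160,
    handover_min = 30,
    detection = list(
      motion_threshold_hz = 2.0,
      min_duration_min = 1.0,
      gap_tolerance_s = 60,
      motion_rule = "either",
      ir_tick_s = 10
    ),
    thresholds = c(1, 3, 4, 30, 150, 180),
    heatmap_unit = "pair_minutes",
    bin_width_min = 60,
    day_start_offset_min = 0,
    core_threshold_min = 30,
    quiet = FALSE
  )
}

#' Validate a pipeline configuration
#'
#' Parses a structured (YAML) configuration, fills defaults, and rejects
#' unknown keys and out-of-range values by name. An empty configuration
#' yields the full default analysis settings: a 2 Hz motion gate over more
#' than 1 minute, sociogram thresholds of 1, 3, 4, 30, 150 and 180 minutes,
#' and the default 76-member roster over a 4-week three-shift schedule.
#'
#' @param x A path to a YAML file, a YAML string, a list, or `NULL` for the
#'   defaults.
#' @return A validated configuration list of class `sb_config`.
#' @export
#' @examples
#' cfg <- validate_config(NULL)
#' cfg$detection$motion_threshold_hz   # 2
validate_config <- function(x = NULL) {
  raw <- if (is.null(x)) {
    list()
  } else if (is.list(x)) {
    x
  } else if (is.character(x) && length(x) == 1) {
    if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  } else {
    stop("config must be a path, YAML text, or a list")
  }
  if (is.null(raw)) raw <- list()
  def <- default_config()

  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$detection)) {
    unknown_d <- setdiff(names(raw$detection), names(def$detection))
    if (length(unknown_d)) {
      stop("unknown config key(s): ",
           paste(paste0("detection.", unknown_d), collapse = ", "))
    }
    raw$detection <- modifyList(def$detection, raw$detection)
  }
  if (!is.null(raw$roster_counts)) {
    unknown_r <- setdiff(names(raw$roster_counts), profession_levels())
    if (length(unknown_r)) {
      stop("unknown config key(s): ",
           paste(paste0("roster_counts.", unknown_r), collapse = ", "))
    }
    full <- as.list(setNames(integer(9), profession_levels()))
    raw$roster_counts <- modifyList(full, raw$roster_counts)
  }
  cfg <- modifyList(def, raw, keep.null = TRUE)

  d <- cfg$detection
  if (d$motion_threshold_hz <= 0) stop("detection.motion_threshold_hz must be > 0")
  if (d$min_duration_min <= 0) stop("detection.min_duration_min must be > 0")
  if (d$gap_tolerance_s < 0) stop("detection.gap_tolerance_s must be >= 0")
  if (!d$motion_rule %in% c("either", "both", "mean")) {
    stop("detection.motion_rule must be one of either/both/mean")
  }
  if (any(unlist(cfg$roster_counts) < 0)) {
    stop("roster_counts must be non-negative")
  }
  if (cfg$n_days < 1) stop("n_days must be >= 1")
  if (any(cfg$thresholds < 0)) stop("thresholds must be >= 0")
  if (1440 %% cfg$bin_width_min != 0) stop("bin_width_min must divide 1440")
  if (!cfg$heatmap_unit %in% c("pair_minutes", "person_minutes")) {
    stop("heatmap_unit must be pair_minutes or person_minutes")
  }
  if (!isTRUE(cfg$simulate) && is.null(cfg$in_dir)) {
    stop("in_dir is required when simulate is false")
  }
  structure(cfg, class = c("sb_config", "list"))
}
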