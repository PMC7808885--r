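#' Cumulative contact matrix
#'
#' Symmetric person-by-person matrix of cumulative active interaction
#' minutes: entry (i, j) is the summed duration of all active interactions
#' between badges i and j whose start falls in the analysis window. The
#' diagonal is zero and the badge order is the roster order, so isolates are
#' retained.
#'
#' @param interactions Active interactions ([classify_active()]); rows with
#'   an `active` column set to `FALSE` are ignored.
#' @param roster A [make_roster()] roster; interactions referencing badges
#'   outside it are rejected.
#' @param window Optional POSIXct length-2 window filtering by start time.
#' @return Numeric matrix with badge-id dimnames, class `sb_contact_matrix`,
#'   attribute `window`.
#' @export
contact_matrix <- function(interactions, roster, window = NULL) {
  if (!is.null(interactions$active)) {
    interactions <- interactions[interactions$active, , drop = FALSE]
  }
  if (!is.null(window)) {
    s <- as.numeric(interactions$start)
    interactions <- interactions[
      s >= as.numeric(window[1]) & s < as.numeric(window[2]), , drop = FALSE]
  }
  ids <- roster$badge_id
  bad <- setdiff(unique(c(interactions$badge_a, interactions$badge_b)), ids)
  if (length(bad)) {
    stop("interactions reference badges absent from roster: ",
         paste(bad, collapse = ", "))
  }
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(interactions)) {
    ia <- match(interactions$badge_a, ids)
    ib <- match(interactions$badge_b, ids)
    if (any(ia == ib)) stop("self-interaction in input")
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    agg <- rowsum(interactions$duration_min, key)
    ij <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
    m[ij] <- agg[, 1]
    m[ij[, c(2, 1), drop = FALSE]] <- agg[, 1]
  }
  structure(m, class = c("sb_contact_matrix", "matrix", "array"),
            window = window)
}

#' @export
print.sb_contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<sb_contact_matrix> %d badges, %d positive pairs, %.1f total minutes\n",
    nrow(x), sum(x[upper.tri(x)] > 0), sum(x[upper.tri(x)])))
  invisible(x)
}

#' Profession-pair interaction heatmap
#'
#' Aggregates a contact matrix to the 9x9 profession level. Under the default
#' `"pair_minutes"` unit a cell holds the summed minutes over unordered badge
#' pairs (each pair counted once); under `"person_minutes"` intra-profession
#' cells are doubled, attributing the minutes to each participating member.
#' Intra-profession cells of professions with fewer than two members are not
#' applicable and masked `NA`. The display matrix is `log10(minutes + 1)`.
#'
#' @param cm An [contact_matrix()] result.
#' @param roster The matching roster.
#' @param unit `"pair_minutes"` (default) or `"person_minutes"`.
#' @return A list of class `sb_profession_matrix` with `minutes` (9x9, `NA`
#'   masked), `display` (log10 scale), and `unit`.
#' @export
profession_heatmap <- function(cm, roster, unit = "pair_minutes") {
  unit <- match.arg(unit, c("pair_minutes", "person_minutes"))
  levels <- profession_levels()
  g <- factor(roster$profession, levels)[match(rownames(cm), roster$badge_id)]
  G <- outer(g, levels, "==") * 1
  P <- t(G) %*% unclass(cm) %*% G
  dimnames(P) <- list(levels, levels)
  diag(P) <- diag(P) / 2                    # each intra pair counted once
  if (unit == "person_minutes") diag(P) <- diag(P) * 2
  counts <- table(factor(roster$profession, levels))
  mask <- as.numeric(counts) < 2
  diag(P)[mask] <- NA
  structure(list(minutes = P, display = log10(P + 1), unit = unit),
            class = "sb_profession_matrix")
}

#' @export
print.sb_profession_matrix <- function(x, ...) {
  cat(sprintf("<sb_profession_matrix> unit=%s, total %.1f minutes\n",
              x$unit, sum(x$minutes, na.rm = TRUE)))
  print(round(x$display, 2))
  invisible(x)
}

#' Threshold sociogram
#'
#' Undirected graph on the full roster in which two badges are linked when
#' their cumulative active interaction minutes reach the threshold
#' (`minutes >= threshold_min`, and strictly positive). Isolates are
#' retained, so sociograms at increasing thresholds are nested edge
#' subgraphs on a fixed node set.
#'
#' @param cm An [contact_matrix()] result.
#' @param threshold_min Threshold in minutes (>= 0).
#' @param roster Optional roster used to attach a `profession` vertex
#'   attribute.
#' @return An [igraph::graph][igraph] with edge attributes `weight` and
#'   `weight_minutes` and graph attribute `threshold_min`.
#' @export
threshold_graph <- function(cm, threshold_min, roster = NULL) {
  stopifnot(threshold_min >= 0)
  m <- unclass(cm)
  m[m < threshold_min | m <= 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$weight_minutes <- igraph::E(g)$weight
  g <- igraph::set_graph_attr(g, "threshold_min", threshold_min)
  if (!is.null(roster)) {
    igraph::V(g)$profession <-
      roster$profession[match(igraph::V(g)$name, roster$badge_id)]
  }
  g
}

#' Per-profession daily totals of active communication
#'
#' For each study day and profession, sums the active interaction minutes of
#' that profession's members, counting an interaction once per participating
#' member (so a nurse-doctor interaction contributes its full duration to
#' both professions).
#'
#' @param interactions Active interactions.
#' @param roster The roster.
#' @param day_start_offset_min Minutes after midnight at which a day starts.
#' @return Data.frame (`day`, `profession`, `minutes`) over the full
#'   day-by-profession grid.
#' @export
daily_profession_totals <- function(interactions, roster,
                                    day_start_offset_min = 0) {
  prof <- profession_of(roster)
  levels <- profession_levels()
  if (nrow(interactions) == 0) {
    return(data.frame(day = as.Date(character(0)), profession = character(0),
                      minutes = numeric(0)))
  }
  d <- day_label(interactions$start, day_start_offset_min)
  long <- data.frame(
    day = rep(d, 2L),
    profession = c(prof[interactions$badge_a], prof[interactions$badge_b]),
    minutes = rep(interactions$duration_min, 2L))
  days <- sort(unique(long$day))
  agg <- tapply(long$minutes,
                list(factor(as.character(long$day), as.character(days)),
                     factor(long$profession, levels)), sum)
  agg[is.na(agg)] <- 0
  out <- data.frame(
    day = rep(days, each = length(levels)),
    profession = rep(levels, times = length(days)),
    minutes = as.numeric(t(agg)))
  out
}
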