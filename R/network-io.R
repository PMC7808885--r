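#' Write and read the interactions table
#'
#' `interactions.csv` columns: `pair_a`, `pair_b`, `start_iso`, `end_iso`,
#' `duration_min`, `motion_a_hz`, `motion_b_hz`, `active` (0/1), `zone_id`
#' (empty when unassigned).
#'
#' @param interactions Episodes with motion means and an `active` flag
#'   ([classify_active()] with `keep_all = TRUE`, or the active subset).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_interactions <- function(interactions, path) {
  out <- data.frame(
    pair_a = interactions$badge_a, pair_b = interactions$badge_b,
    start_iso = format_iso(interactions$start),
    end_iso = format_iso(interactions$end),
    duration_min = interactions$duration_min,
    motion_a_hz = interactions$motion_a_hz,
    motion_b_hz = interactions$motion_b_hz,
    active = as.integer(interactions$active %||% rep(TRUE, nrow(interactions))),
    zone_id = ifelse(is.na(interactions$zone_id %||%
                             rep(NA_character_, nrow(interactions))),
                     "", interactions$zone_id))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  dt <- read_csv_checked(path, c("pair_a", "pair_b", "start_iso", "end_iso",
                                 "duration_min", "motion_a_hz", "motion_b_hz",
                                 "active", "zone_id"))
  out <- data.frame(
    badge_a = dt$pair_a, badge_b = dt$pair_b,
    start = parse_iso(dt$start_iso), end = parse_iso(dt$end_iso),
    duration_min = as.numeric(dt$duration_min),
    motion_a_hz = as.numeric(dt$motion_a_hz),
    motion_b_hz = as.numeric(dt$motion_b_hz),
    active = as.integer(dt$active) == 1L,
    zone_id = ifelse(dt$zone_id == "", NA_character_, dt$zone_id),
    stringsAsFactors = FALSE)
  class(out) <- c("sb_interactions", "data.frame")
  out
}

#' Write a contact matrix as square CSV
#'
#' @param cm An [contact_matrix()] result.
#' @param path Output path; badge ids form the header and first column.
#' @return Invisibly, `path`.
#' @export
write_contact_matrix <- function(cm, path) {
  if (nrow(cm) == 0) {
    df <- data.frame(badge_id = character(0))
  } else {
    df <- data.frame(badge_id = rownames(cm), unclass(cm),
                     check.names = FALSE)
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' Write the profession heatmap as CSV
#'
#' Writes the pre-log minutes; not-applicable cells are empty.
#'
#' @param pm An [profession_heatmap()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_heatmap <- function(pm, path) {
  m <- pm$minutes
  df <- data.frame(profession = rownames(m), m, check.names = FALSE)
  data.table::fwrite(df, path, na = "")
  invisible(path)
}

#' Export a sociogram
#'
#' Writes GraphML (node attributes `profession`, `degree`, `eigenvector`,
#' `betweenness`, `core`; edge attribute `weight_minutes`) and a companion
#' edge list TSV (`source`, `target`, `minutes`).
#'
#' @param g A [threshold_graph()] sociogram.
#' @param report A [centrality_report()] for `g`.
#' @param corefit A [core_periphery_fit()] for `g`.
#' @param graphml_path,edges_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_sociogram <- function(g, report, corefit, graphml_path, edges_path) {
  idx <- match(igraph::V(g)$name, report$badge_id)
  igraph::V(g)$degree <- report$degree[idx]
  igraph::V(g)$eigenvector <- report$eigenvector[idx]
  igraph::V(g)$betweenness <- report$betweenness[idx]
  igraph::V(g)$core <- as.integer(corefit$membership[igraph::V(g)$name])
  igraph::write_graph(g, graphml_path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  if (is.null(el$weight_minutes)) el$weight_minutes <- numeric(nrow(el))
  edges <- data.frame(source = el$from, target = el$to,
                      minutes = el$weight_minutes)
  data.table::fwrite(edges, edges_path, sep = "\t")
  invisible(c(graphml_path, edges_path))
}

#' Write a daily occupancy table
#'
#' @param occupancy A [daily_occupancy()] result.
#' @param path Output path (`zone_id`, `category`, `minutes`).
#' @return Invisibly, `path`.
#' @export
write_occupancy <- function(occupancy, path) {
  data.table::fwrite(as.data.frame(occupancy), path)
  invisible(path)
}
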