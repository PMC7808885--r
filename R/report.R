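#' Bundled centrality report
#'
#' Combines degree, eigenvector and betweenness centrality (raw and
#' normalized), connected-component membership, weighted interaction volume
#' (strength, in minutes), and flags for the three most interactive doctors
#' and nurses (by strength, ties broken by badge id). Per-profession median
#' ranks (rank 1 = most central, average ranks on ties) for the three
#' measures are attached as attribute `profession_summary`.
#'
#' @param g An undirected sociogram carrying edge weights in minutes.
#' @param roster The matching roster.
#' @return Data.frame with one row per node, class `sb_centrality_report`.
#' @export
centrality_report <- function(g, roster) {
  deg <- degree_centrality(g)
  btw <- betweenness_centrality(g)
  has_edges <- igraph::ecount(g) > 0
  if (has_edges) {
    eig <- eigenvector_centrality(g)
  } else {
    eig <- data.frame(badge_id = deg$badge_id,
                      eigenvector = rep(0, nrow(deg)))
  }
  comp <- igraph::components(g)
  strength <- if (has_edges) igraph::strength(g) else rep(0, nrow(deg))
  out <- data.frame(
    badge_id = deg$badge_id,
    profession = roster$profession[match(deg$badge_id, roster$badge_id)],
    component = as.integer(comp$membership),
    degree = deg$degree, degree_norm = deg$degree_norm,
    eigenvector = eig$eigenvector[match(deg$badge_id, eig$badge_id)],
    betweenness = btw$betweenness[match(deg$badge_id, btw$badge_id)],
    betweenness_norm = btw$betweenness_norm[match(deg$badge_id, btw$badge_id)],
    strength_min = as.numeric(strength),
    stringsAsFactors = FALSE)

  top3 <- function(rows) {
    o <- rows[order(-out$strength_min[rows], out$badge_id[rows])]
    head(o, 3)
  }
  out$top3_doctor <- rep(FALSE, nrow(out))
  out$top3_nurse <- rep(FALSE, nrow(out))
  out$top3_doctor[top3(which(out$profession %in% doctor_professions()))] <- TRUE
  out$top3_nurse[top3(which(out$profession == "nurse"))] <- TRUE

  ranks <- data.frame(
    degree = rank(-out$degree),
    eigenvector = rank(-out$eigenvector),
    betweenness = rank(-out$betweenness))
  summ <- do.call(rbind, lapply(split(ranks, out$profession), function(df) {
    vapply(df, median, numeric(1))
  }))
  attr(out, "profession_summary") <- if (is.null(summ)) {
    data.frame(profession = character(0), median_rank_degree = numeric(0),
               median_rank_eigenvector = numeric(0),
               median_rank_betweenness = numeric(0))
  } else {
    data.frame(profession = rownames(summ),
               median_rank_degree = summ[, "degree"],
               median_rank_eigenvector = summ[, "eigenvector"],
               median_rank_betweenness = summ[, "betweenness"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  class(out) <- c("sb_centrality_report", "data.frame")
  out
}

#' Per-profession median centrality ranks
#'
#' @param report A [centrality_report()] result.
#' @return The `profession_summary` attribute: a data.frame of median ranks.
#' @export
profession_rank_summary <- function(report) {
  attr(report, "profession_summary")
}
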