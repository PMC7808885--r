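graph_adjacency <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  if (is.null(rownames(a))) {
    nm <- igraph::V(g)$name
    if (is.null(nm)) nm <- as.character(seq_len(nrow(a)))
    dimnames(a) <- list(nm, nm)
  }
  a[a != 0] <- 1
  a
}

adj_names <- function(a) {
  if (is.null(rownames(a))) character(nrow(a)) else rownames(a)
}

#' Degree centrality
#'
#' Raw degree (number of incident links) and degree normalized by `n - 1`.
#'
#' @param g An undirected [threshold_graph()] sociogram.
#' @return Data.frame (`badge_id`, `degree`, `degree_norm`); the normalized
#'   column is `NA` (with attribute `flag`) when the graph has fewer than two
#'   nodes.
#' @export
degree_centrality <- function(g) {
  a <- graph_adjacency(g)
  n <- nrow(a)
  deg <- rowSums(a)
  out <- data.frame(badge_id = adj_names(a), degree = as.numeric(deg),
                    degree_norm = if (n >= 2) as.numeric(deg) / (n - 1)
                                  else rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n < 2) attr(out, "flag") <- "normalized degree undefined for n < 2"
  out
}

#' Eigenvector centrality by power iteration
#'
#' Scores nodes by the leading eigenvector of the binary adjacency matrix of
#' the largest connected component, computed by power iteration from a
#' uniform positive start on `A + I` (the shift leaves the leading
#' eigenvector unchanged but guarantees convergence on bipartite components,
#' where `A` itself has a symmetric extreme spectrum). Scores are
#' non-negative with unit Euclidean norm over the scored component; nodes
#' outside the largest component score 0.
#'
#' @param g An undirected sociogram with at least one edge.
#' @param tol Convergence tolerance: max-norm change between successive
#'   normalized iterates (default 1e-12).
#' @param max_iter Iteration cap; reaching it flags non-convergence.
#' @return Data.frame (`badge_id`, `eigenvector`), attribute `converged`.
#' @export
eigenvector_centrality <- function(g, tol = 1e-12, max_iter = 10000) {
  a <- graph_adjacency(g)
  if (sum(a) == 0) {
    stop("eigenvector centrality is undefined on an edgeless graph")
  }
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  in_main <- comp$membership == main
  am <- a[in_main, in_main, drop = FALSE]
  nc <- nrow(am)
  x <- rep(1 / sqrt(nc), nc)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    y <- as.numeric(am %*% x) + x        # (A + I) x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      x <- y
      converged <- TRUE
      break
    }
    x <- y
  }
  scores <- numeric(nrow(a))
  scores[in_main] <- x
  out <- data.frame(badge_id = adj_names(a), eigenvector = scores,
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- converged
  if (!converged) {
    warning(sprintf("power iteration did not reach tol=%g in %d iterations",
                    tol, max_iter))
  }
  out
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' Unweighted shortest-path betweenness via Brandes' single-source
#' accumulation: for every source, a breadth-first search builds geodesic
#' counts and predecessor lists, and dependencies are accumulated in reverse
#' BFS order. Node pairs in different components contribute nothing. Raw
#' scores and scores normalized by `(n - 1)(n - 2) / 2` are returned.
#'
#' @param g An undirected sociogram.
#' @return Data.frame (`badge_id`, `betweenness`, `betweenness_norm`).
#' @export
betweenness_centrality <- function(g) {
  a <- graph_adjacency(g)
  n <- nrow(a)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2                              # undirected: each pair seen twice
  norm_den <- if (n > 2) (n - 1) * (n - 2) / 2 else NA_real_
  data.frame(badge_id = adj_names(a), betweenness = bc,
             betweenness_norm = bc / norm_den, stringsAsFactors = FALSE)
}
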