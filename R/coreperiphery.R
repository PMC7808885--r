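cp_score <- function(e1, e0, n1, n0) {
  # Pearson correlation between the observed binary adjacency and the ideal
  # core/periphery pattern over evaluated dyads: core-core dyads (ideal 1)
  # and periphery-periphery dyads (ideal 0); core-periphery dyads excluded.
  N <- n1 + n0
  E <- e1 + e0
  num <- e1 - E * n1 / N
  den2 <- (E - E^2 / N) * (n1 - n1^2 / N)
  out <- ifelse(N > 0 & den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  out
}

cp_result <- function(membership, score, degenerate, method, n_restarts) {
  structure(list(core = names(membership)[membership],
                 membership = membership, score = score,
                 degenerate = degenerate, method = method,
                 n_restarts = n_restarts),
            class = "sb_corefit")
}

#' Core/periphery structure fit
#'
#' Partitions the nodes into a core and a periphery maximizing the Pearson
#' correlation between the observed binary adjacency and the ideal
#' core/periphery pattern, evaluated over core-core dyads (ideal 1) and
#' periphery-periphery dyads (ideal 0); core-periphery dyads are excluded
#' from the correlation. Both blocks must hold at least two nodes for the
#' correlation to be defined, so graphs too small or too degenerate to admit
#' such a split are returned all-periphery with an `NA` score and the
#' `degenerate` flag set (an edgeless graph likewise).
#'
#' The search is exhaustive for graphs of up to 15 nodes and otherwise a
#' greedy single-label-swap hill climb from `n_restarts` seeded random
#' starts; both are deterministic given `seed`.
#'
#' @param g An undirected sociogram (at least 3 nodes and 1 edge for a
#'   meaningful fit).
#' @param n_restarts Random restarts of the greedy search (default 20).
#' @param seed Integer seed for the restarts.
#' @param method `"auto"` (exhaustive up to 15 nodes, greedy beyond),
#'   `"exhaustive"` or `"greedy"`.
#' @return A list of class `sb_corefit`: `core` (badge ids), `membership`
#'   (named logical), `score`, `degenerate`, `method`, `n_restarts`.
#' @export
core_periphery_fit <- function(g, n_restarts = 20, seed = 1L,
                               method = c("auto", "exhaustive", "greedy")) {
  method <- match.arg(method)
  a <- graph_adjacency(g)
  n <- nrow(a)
  none <- setNames(rep(FALSE, n), rownames(a))
  if (n < 4 || sum(a) == 0) {
    return(cp_result(none, NA_real_, TRUE, "degenerate", n_restarts))
  }
  el <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  use_exhaustive <- method == "exhaustive" ||
    (method == "auto" && n <= 15)
  if (use_exhaustive && n > 20) {
    stop("exhaustive core/periphery search is limited to 20 nodes")
  }

  if (use_exhaustive) {
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n),
                                   KEEP.OUT.ATTRS = FALSE))
    k <- rowSums(masks)
    valid <- k >= 2 & k <= n - 2
    masks <- masks[valid, , drop = FALSE]
    k <- k[valid]
    e1 <- numeric(nrow(masks))
    e0 <- numeric(nrow(masks))
    for (r in seq_len(nrow(el))) {
      i <- el[r, 1]; j <- el[r, 2]
      cc <- masks[, i] & masks[, j]
      e1 <- e1 + cc
      e0 <- e0 + (!masks[, i] & !masks[, j])
    }
    score <- cp_score(e1, e0, k * (k - 1) / 2, (n - k) * (n - k - 1) / 2)
    if (all(is.na(score))) {
      return(cp_result(none, NA_real_, TRUE, "exhaustive", n_restarts))
    }
    best <- which.max(score)
    membership <- setNames(as.logical(masks[best, ]), rownames(a))
    return(cp_result(membership, score[best], FALSE, "exhaustive",
                     n_restarts))
  }

  deg <- rowSums(a)
  best_score <- -Inf
  best_membership <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, paste0("core-periphery-", r)))
    core <- runif(n) < 0.5
    while (sum(core) < 2) core[sample(which(!core), 1)] <- TRUE
    while (sum(!core) < 2) core[sample(which(core), 1)] <- FALSE
    k <- sum(core)
    e1 <- sum(a[core, core, drop = FALSE]) / 2
    e0 <- sum(a[!core, !core, drop = FALSE]) / 2
    cur <- cp_score(e1, e0, k * (k - 1) / 2, (n - k) * (n - k - 1) / 2)
    if (is.na(cur)) cur <- -Inf
    repeat {
      dc <- as.numeric(a %*% core)           # neighbours in the core
      # score after flipping each node, from O(1) count updates
      k2 <- ifelse(core, k - 1, k + 1)
      e1f <- ifelse(core, e1 - dc, e1 + dc)
      e0f <- ifelse(core, e0 + deg - dc, e0 - (deg - dc))
      gains <- cp_score(e1f, e0f, k2 * (k2 - 1) / 2,
                        (n - k2) * (n - k2 - 1) / 2)
      gains[k2 < 2 | (n - k2) < 2 | is.na(gains)] <- -Inf
      v_best <- which.max(gains)
      if (gains[v_best] > cur + 1e-12) {
        e1 <- e1f[v_best]; e0 <- e0f[v_best]; k <- k2[v_best]
        core[v_best] <- !core[v_best]
        cur <- gains[v_best]
      } else {
        break
      }
    }
    if (cur > best_score) {
      best_score <- cur
      best_membership <- core
    }
  }
  if (!is.finite(best_score)) {
    return(cp_result(none, NA_real_, TRUE, "greedy", n_restarts))
  }
  cp_result(setNames(best_membership, rownames(a)), best_score, FALSE,
            "greedy", n_restarts)
}

#' @export
print.sb_corefit <- function(x, ...) {
  cat(sprintf("<sb_corefit> %s: core %d nodes, score %s%s\n", x$method,
              length(x$core),
              ifelse(is.na(x$score), "NA", sprintf("%.3f", x$score)),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
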