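# Independent brute-force oracles used to check the package's algorithms.
# These deliberately share no code with the implementation paths they test.

# Erdos-Renyi adjacency with named nodes.
rand_adjacency <- function(n, p) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
  a
}

graph_from_adj <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# Betweenness by exhaustive enumeration of all geodesics between all pairs.
bf_betweenness <- function(a) {
  n <- nrow(a)
  bc <- numeric(n)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  for (s in seq_len(n - 1)) {
    d <- rep(Inf, n); d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in nbrs[[v]]) {
        if (is.infinite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
      }
    }
    for (t in (s + 1):n) {
      if (is.infinite(d[t])) next
      paths <- list()
      enum <- function(v, suffix) {
        if (v == s) { paths[[length(paths) + 1]] <<- c(v, suffix); return() }
        for (u in nbrs[[v]]) if (d[u] == d[v] - 1) enum(u, c(v, suffix))
      }
      enum(t, integer(0))
      np <- length(paths)
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior)) {
        tab <- table(interior)
        ix <- as.integer(names(tab))
        bc[ix] <- bc[ix] + as.numeric(tab) / np
      }
    }
  }
  bc
}

# Eigenvector centrality by dense symmetric eigendecomposition of the
# largest component's adjacency.
oracle_eigenvector <- function(a) {
  g <- graph_from_adj(a)
  comp <- igraph::components(g)
  in_main <- comp$membership == which.max(comp$csize)
  e <- eigen(a[in_main, in_main, drop = FALSE], symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  scores <- numeric(nrow(a))
  scores[in_main] <- v
  scores
}

# Core/periphery: exhaustive search over all core subsets, scoring each
# partition by direct cor() over the evaluated dyad vectors.
bf_corefit <- function(a) {
  n <- nrow(a)
  ut <- which(upper.tri(a), arr.ind = TRUE)
  x <- a[upper.tri(a)]
  best <- -Inf; best_core <- NULL
  for (k in 2:(n - 2)) {
    for (set in utils::combn(n, k, simplify = FALSE)) {
      core <- seq_len(n) %in% set
      cc <- core[ut[, 1]] & core[ut[, 2]]
      pp <- !core[ut[, 1]] & !core[ut[, 2]]
      keep <- cc | pp
      sc <- suppressWarnings(stats::cor(x[keep], as.numeric(cc[keep])))
      if (!is.na(sc) && sc > best) { best <- sc; best_core <- set }
    }
  }
  list(score = best, core = best_core)
}

# Episode segmentation by per-pair sorting and splitting at gaps.
bf_segment <- function(ir, gap_s, tick_s) {
  keep <- ir$observer_badge != ir$observed_badge
  df <- unique(data.frame(
    a = pmin(ir$observer_badge[keep], ir$observed_badge[keep]),
    b = pmax(ir$observer_badge[keep], ir$observed_badge[keep]),
    t = as.numeric(ir$timestamp)[keep], stringsAsFactors = FALSE))
  res <- NULL
  for (key in sort(unique(paste(df$a, df$b)))) {
    sub <- df[paste(df$a, df$b) == key, ]
    ts <- sort(sub$t)
    brk <- c(0, which(diff(ts) > gap_s), length(ts))
    for (i in seq_len(length(brk) - 1)) {
      seg <- ts[(brk[i] + 1):brk[i + 1]]
      res <- rbind(res, data.frame(
        badge_a = sub$a[1], badge_b = sub$b[1], start = min(seg),
        end = max(seg) + tick_s, n = length(seg),
        stringsAsFactors = FALSE))
    }
  }
  res[order(res$start, res$badge_a, res$badge_b), ]
}

# Small fixture: ir records at given epoch seconds for one or more pairs.
mk_ir <- function(t, a, b, origin = "2019-10-01 00:00:00") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  data.frame(timestamp = t0 + t, observer_badge = a, observed_badge = b,
             stringsAsFactors = FALSE)
}

mk_accel <- function(t, badge, hz, origin = "2019-10-01 00:00:00") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  data.frame(timestamp = t0 + t, badge_id = badge, motion_hz = hz,
             stringsAsFactors = FALSE)
}

mk_beacon <- function(t, badge, beacon, origin = "2019-10-01 00:00:00") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  data.frame(timestamp = t0 + t, badge_id = badge, beacon_id = beacon,
             stringsAsFactors = FALSE)
}

# Hand-built interactions table.
mk_interactions <- function(a, b, start_s, dur_min,
                            zone = NA_character_,
                            origin = "2019-10-01 00:00:00") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  n <- length(a)
  out <- data.frame(
    badge_a = pmin(a, b), badge_b = pmax(a, b),
    start = t0 + start_s, end = t0 + start_s + dur_min * 60,
    duration_min = rep_len(dur_min, n),
    motion_a_hz = rep_len(3, n), motion_b_hz = rep_len(3, n),
    active = rep_len(TRUE, n), zone_id = rep_len(zone, n),
    stringsAsFactors = FALSE)
  class(out) <- c("sb_interactions", "data.frame")
  out
}

# A small study used by several simulator tests.
small_study <- function(n_days = 2, seed = 7,
                        counts = c(nurse = 5, attending_physician = 3,
                                   medical_technician = 2)) {
  roster <- make_roster(counts)
  schedule <- make_schedule(roster, n_days = n_days,
                            target_hours = 8 * n_days, seed = seed)
  zone_map <- make_zone_map()
  list(roster = roster, schedule = schedule, zone_map = zone_map)
}
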