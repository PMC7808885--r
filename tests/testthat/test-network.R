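r6 <- make_roster(c(nurse = 3, attending_physician = 2, resident = 1))

test_that("contact matrix accumulates symmetric pair minutes", {
  one <- mk_interactions("nur_01", "nur_02", 0, 10)
  m <- contact_matrix(one, r6)
  expect_equal(m["nur_01", "nur_02"], 10)
  expect_equal(m["nur_02", "nur_01"], 10)
  expect_equal(sum(unclass(m)), 20)
  expect_equal(dim(m), c(6, 6))

  none <- contact_matrix(one[0, ], r6)
  expect_true(all(unclass(none) == 0))

  set.seed(3)
  n <- 150
  a <- sample(r6$badge_id, n, TRUE)
  b <- sample(r6$badge_id, n, TRUE)
  keep <- a != b
  rand <- mk_interactions(a[keep], b[keep], runif(sum(keep), 0, 86400),
                          runif(sum(keep), 0.5, 20))
  m2 <- contact_matrix(rand, r6)
  expect_equal(unclass(m2), t(unclass(m2)))
  expect_true(all(diag(unclass(m2)) == 0))
  for (i in 1:5) for (j in 1:6) {
    if (i >= j) next
    sel <- rand$badge_a == r6$badge_id[i] & rand$badge_b == r6$badge_id[j] |
      rand$badge_a == r6$badge_id[j] & rand$badge_b == r6$badge_id[i]
    expect_equal(m2[i, j], sum(rand$duration_min[sel]))
  }
  expect_error(contact_matrix(mk_interactions("nur_01", "zz_99", 0, 5), r6),
               "zz_99")
})

test_that("contact matrix respects the analysis window and active flag", {
  t0 <- as.POSIXct("2019-10-01", tz = "UTC")
  ints <- mk_interactions(c("nur_01", "nur_01"), c("nur_02", "nur_02"),
                          c(0, 90000), c(5, 7))
  m <- contact_matrix(ints, r6, window = c(t0, t0 + 86400))
  expect_equal(m["nur_01", "nur_02"], 5)
  ints$active <- c(FALSE, TRUE)
  m2 <- contact_matrix(ints, r6)
  expect_equal(m2["nur_01", "nur_02"], 7)
})

test_that("profession heatmap groups pairs with N/A masking and log display", {
  one <- mk_interactions("nur_01", "nur_02", 0, 10)
  pm <- profession_heatmap(contact_matrix(one, r6), r6)
  expect_equal(pm$minutes["nurse", "nurse"], 10)
  expect_equal(pm$display["nurse", "nurse"], log10(11))
  expect_true(is.na(pm$minutes["resident", "resident"]))      # 1 member
  expect_true(is.na(pm$minutes["pharmacist", "pharmacist"]))  # 0 members
  expect_false(is.na(pm$minutes["nurse", "resident"]))

  pm2 <- profession_heatmap(contact_matrix(one, r6), r6,
                            unit = "person_minutes")
  expect_equal(pm2$minutes["nurse", "nurse"], 20)

  set.seed(11)
  n <- 100
  a <- sample(r6$badge_id, n, TRUE); b <- sample(r6$badge_id, n, TRUE)
  keep <- a != b
  rand <- mk_interactions(a[keep], b[keep], runif(sum(keep), 0, 86400),
                          runif(sum(keep), 0.5, 20))
  cm <- contact_matrix(rand, r6)
  pm3 <- profession_heatmap(cm, r6)
  prof <- setNames(r6$profession, r6$badge_id)
  for (p in c("nurse", "attending_physician")) {
    for (q in c("nurse", "attending_physician", "resident")) {
      ids_p <- names(prof)[prof == p]; ids_q <- names(prof)[prof == q]
      want <- 0
      for (i in r6$badge_id) for (j in r6$badge_id) {
        if (i < j && ((i %in% ids_p && j %in% ids_q) ||
                      (i %in% ids_q && j %in% ids_p))) {
          want <- want + cm[i, j]
        }
      }
      expect_equal(pm3$minutes[p, q], want)
    }
  }
  # conservation: the distinct profession-pair cells (the symmetric matrix's
  # upper triangle with diagonal) sum to the contact-matrix upper triangle
  expect_equal(sum(pm3$minutes[upper.tri(pm3$minutes, diag = TRUE)],
                   na.rm = TRUE),
               sum(unclass(cm)[upper.tri(cm)]), tolerance = 1e-9)
})

test_that("threshold graphs keep isolates and nest with rising thresholds", {
  set.seed(19)
  n <- 60
  a <- sample(r6$badge_id, n, TRUE); b <- sample(r6$badge_id, n, TRUE)
  keep <- a != b
  rand <- mk_interactions(a[keep], b[keep], runif(sum(keep), 0, 86400),
                          runif(sum(keep), 0.5, 50))
  cm <- contact_matrix(rand, r6)

  g_hi <- threshold_graph(cm, max(cm) + 1)
  expect_equal(igraph::ecount(g_hi), 0)
  expect_equal(igraph::vcount(g_hi), 6)

  g0 <- threshold_graph(cm, 0)
  expect_equal(igraph::ecount(g0), sum(unclass(cm)[upper.tri(cm)] > 0))

  edges_at <- function(thr) {
    g <- threshold_graph(cm, thr)
    apply(igraph::as_edgelist(g), 1, function(x) paste(sort(x), collapse = "|"))
  }
  thresholds <- c(1, 3, 4, 30, 150, 180)
  sets <- lapply(thresholds, edges_at)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("degree centrality matches structure and row sums", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  d <- degree_centrality(star)
  expect_equal(d$degree[d$badge_id == "hub"], 4)
  expect_equal(d$degree[d$badge_id != "hub"], rep(1, 4))
  expect_equal(d$degree_norm[d$badge_id == "hub"], 1)

  full <- igraph::make_full_graph(4)
  igraph::V(full)$name <- paste0("n", 1:4)
  expect_equal(degree_centrality(full)$degree_norm, rep(1, 4))

  set.seed(8)
  a <- rand_adjacency(10, 0.4)
  expect_equal(degree_centrality(graph_from_adj(a))$degree,
               unname(rowSums(a)))
})

test_that("eigenvector centrality matches closed forms and the dense oracle", {
  p3 <- igraph::make_graph(~ a - b - c)
  e <- eigenvector_centrality(p3)
  expect_equal(round(e$eigenvector, 4), c(0.5, 0.7071, 0.5))

  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- paste0("n", 1:5)
  expect_equal(eigenvector_centrality(full)$eigenvector, rep(1 / sqrt(5), 5))

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("a", "b", "c")
  expect_error(eigenvector_centrality(edgeless), "edgeless")

  set.seed(29)
  for (rep in 1:10) {
    a <- rand_adjacency(8, 0.35)
    if (sum(a) == 0) next
    got <- eigenvector_centrality(graph_from_adj(a))
    expect_lt(max(abs(got$eigenvector - oracle_eigenvector(a))), 1e-6)
    expect_true(all(got$eigenvector >= -1e-12))
    expect_equal(sum(got$eigenvector^2), 1, tolerance = 1e-9)
  }
})

test_that("betweenness matches unique-geodesic cases and path enumeration", {
  p3 <- igraph::make_graph(~ a - b - c)
  b3 <- betweenness_centrality(p3)
  expect_equal(b3$betweenness, c(0, 1, 0))

  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  bs <- betweenness_centrality(star)
  expect_equal(bs$betweenness[bs$badge_id == "hub"], 10)  # C(5, 2)
  expect_equal(bs$betweenness_norm[bs$badge_id == "hub"], 1) # 10 / C(5, 2)

  set.seed(37)
  for (rep in 1:10) {
    a <- rand_adjacency(8, 0.35)
    got <- betweenness_centrality(graph_from_adj(a))
    expect_equal(got$betweenness, bf_betweenness(a), tolerance = 1e-9)
  }
})

test_that("core/periphery fit recovers a perfect core and the exhaustive optimum", {
  # clique of 4, each of 4 pendants attached to one clique node
  el <- rbind(t(utils::combn(1:4, 2)), cbind(1:4, 5:8))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%d", 1:8)
  fit <- core_periphery_fit(g)
  expect_equal(fit$score, 1.0)
  expect_setequal(fit$core, sprintf("n%d", 1:4))
  expect_false(fit$degenerate)

  # perfect matching on 6 nodes: weak structure, still must equal the oracle
  m6 <- igraph::graph_from_edgelist(cbind(1:3, 4:6), directed = FALSE)
  igraph::V(m6)$name <- sprintf("m%d", 1:6)
  fit_m <- core_periphery_fit(m6)
  a_m <- igraph::as_adjacency_matrix(m6, sparse = FALSE)
  expect_equal(fit_m$score, bf_corefit(a_m)$score, tolerance = 1e-12)

  # edgeless graphs are degenerate, all periphery
  e4 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(e4)$name <- sprintf("e%d", 1:4)
  fit_e <- core_periphery_fit(e4)
  expect_true(fit_e$degenerate)
  expect_equal(length(fit_e$core), 0)
  expect_true(is.na(fit_e$score))
})

test_that("exhaustive and greedy fits agree with the partition oracle", {
  set.seed(41)
  for (rep in 1:5) {
    a <- rand_adjacency(10, 0.35)
    if (sum(a) == 0) next
    g <- graph_from_adj(a)
    want <- bf_corefit(a)
    exh <- core_periphery_fit(g, method = "exhaustive")
    expect_equal(exh$score, want$score, tolerance = 1e-12)
    greedy <- core_periphery_fit(g, n_restarts = 20, seed = 1,
                                 method = "greedy")
    expect_gte(greedy$score, 0.95 * want$score)
    # determinism of the seeded greedy search
    greedy2 <- core_periphery_fit(g, n_restarts = 20, seed = 1,
                                  method = "greedy")
    expect_identical(greedy$membership, greedy2$membership)
  }
})

test_that("centrality report reproduces hand-computed values on a path", {
  # path n1 - n2 - n3 - n4 - n5 with degrees 1,2,2,2,1
  g <- igraph::make_graph(~ n1 - n2 - n3 - n4 - n5)
  igraph::E(g)$weight <- c(10, 20, 30, 40)
  igraph::E(g)$weight_minutes <- igraph::E(g)$weight
  roster <- data.frame(badge_id = paste0("n", 1:5),
                       profession = c("nurse", "nurse", "nurse",
                                      "attending_physician",
                                      "attending_physician"))
  rep5 <- centrality_report(g, roster)
  expect_equal(rep5$degree, c(1, 2, 2, 2, 1))
  expect_equal(rep5$betweenness, c(0, 3, 4, 3, 0))
  expect_equal(rep5$eigenvector,
               c(0.2887, 0.5, 0.5774, 0.5, 0.2887), tolerance = 1e-4)
  expect_equal(rep5$strength_min, c(10, 30, 50, 70, 40))
  # top 3 nurses by strength: n3 (50), n2 (30), n1 (10)
  expect_equal(rep5$badge_id[rep5$top3_nurse], c("n1", "n2", "n3"))
  expect_equal(sum(rep5$top3_doctor), 2)   # only two doctors exist
  summ <- profession_rank_summary(rep5)
  expect_equal(sort(summ$profession),
               sort(c("nurse", "attending_physician")))
})

test_that("daily profession totals count each interaction per member", {
  r2 <- make_roster(c(nurse = 2, attending_physician = 1))
  one <- mk_interactions("nur_01", "doc_01", 3600, 10)
  tot <- daily_profession_totals(one, r2)
  d1 <- tot[tot$day == as.Date("2019-10-01"), ]
  expect_equal(d1$minutes[d1$profession == "nurse"], 10)
  expect_equal(d1$minutes[d1$profession == "attending_physician"], 10)
  expect_equal(d1$minutes[d1$profession == "secretary"], 0)

  empty <- daily_profession_totals(one[0, ], r2)
  expect_equal(nrow(empty), 0)

  set.seed(43)
  n <- 80
  a <- sample(r2$badge_id, n, TRUE); b <- sample(r2$badge_id, n, TRUE)
  keep <- a != b
  rand <- mk_interactions(a[keep], b[keep], runif(sum(keep), 0, 2 * 86400),
                          runif(sum(keep), 1, 15))
  tot2 <- daily_profession_totals(rand, r2)
  prof <- setNames(r2$profession, r2$badge_id)
  for (d in unique(tot2$day)) {
    for (p in c("nurse", "attending_physician")) {
      sel <- as.Date(rand$start, tz = "UTC") == d
      want <- sum(rand$duration_min[sel & prof[rand$badge_a] == p]) +
        sum(rand$duration_min[sel & prof[rand$badge_b] == p])
      expect_equal(tot2$minutes[tot2$day == d & tot2$profession == p], want)
    }
  }
})
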