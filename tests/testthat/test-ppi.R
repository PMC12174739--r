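test_that("edge-list ingestion thresholds, deduplicates and drops self-loops", {
  edges <- data.frame(
    node1 = c("a", "a", "b", "c", "d", "d", "e"),
    node2 = c("b", "b", "c", "a", "d", "e", "f"),
    combined_score = c(900, 700, 500, 450, 800, 350, "bad"),
    stringsAsFactors = FALSE)
  expect_warning(expect_warning(
    g <- suppressMessages(interaction_graph(edges, threshold = 400)),
    "malformed"), "self-loop")
  expect_equal(igraph::ecount(g), 3)          # a-b (dedup), b-c, c-a
  expect_equal(sort(igraph::V(g)$name), c("a", "b", "c"))
  ab <- igraph::E(g)[igraph::V(g)["a"] %--% igraph::V(g)["b"]]
  expect_equal(ab$score, 900)                 # duplicate keeps the higher score
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(edges[1:4, ], path, sep = "\t", row.names = FALSE, quote = FALSE)
  g2 <- suppressMessages(read_edge_list(path, threshold = 400))
  expect_equal(igraph::ecount(g2), 3)
})

test_that("MCODE vertex weights equal core density times core order", {
  tri <- suppressMessages(interaction_graph(clique_edges(c("a", "b", "c"))))
  w <- mcode_vertex_weights(tri)
  expect_equal(unname(w), rep(2, 3))  # closed neighbourhood is a 3-clique: 2-core, density 1
  pathg <- suppressMessages(interaction_graph(data.frame(
    node1 = c("a", "b"), node2 = c("b", "c"), combined_score = 900)))
  wp <- mcode_vertex_weights(pathg)
  expect_equal(unname(wp[c("a", "c")]), c(0, 0))   # degree 1 < cutoff
  expect_equal(unname(wp["b"]), 2 / 3)             # 1-core of the path, density 2/3
})

test_that("MCODE separates two bridged 5-cliques and applies the k-core filter", {
  # 11-node fixture: 5-cliques {c1..c5} and {d1..d5} joined through node x
  c1 <- paste0("c", 1:5)
  d1 <- paste0("d", 1:5)
  edges <- rbind(clique_edges(c1), clique_edges(d1),
                 data.frame(node1 = c("c1", "x"), node2 = c("x", "d1"),
                            combined_score = 900))
  g <- suppressMessages(interaction_graph(edges))
  cl <- mcode_clusters(g)  # defaults carry k-core = 4
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$members, c1)
  expect_setequal(cl[[2]]$members, d1)
  expect_equal(cl[[1]]$score, 5)  # density 1 x size 5
  # determinism: repeated runs give identical output
  expect_identical(mcode_clusters(g), cl)
  # a graph whose largest clique is a triangle has no 4-core: nothing survives
  expect_length(mcode_clusters(tri <- suppressMessages(
    interaction_graph(clique_edges(c("a", "b", "c"))))), 0)
  # empty graph
  expect_length(mcode_clusters(igraph::make_empty_graph(0, directed = FALSE)), 0)
})

test_that("clusters always contain the required k-core and haircut leaves no degree-1 members", {
  cfg <- synthesis_config(seed = 9, ppi_complex_sizes = c(10, 8, 6),
                          ppi_background_p = 0.08)
  ppi <- simulate_ppi(cfg, sprintf("n%03d", 1:80))
  g <- suppressMessages(interaction_graph(ppi$edges))
  cl <- mcode_clusters(g)
  expect_gt(length(cl), 0)
  for (c in cl) {
    sub <- igraph::induced_subgraph(g, c$members)
    expect_gte(max(igraph::coreness(sub)), 4)
    expect_true(all(igraph::degree(sub) >= 2))
  }
})

test_that("MCODE recovers planted complexes with high Jaccard overlap at generator defaults", {
  # fluff is on: planted complexes are dense but not complete, so their
  # low-weight fringe re-enters through the boundary-density stage
  for (seed in 1:3) {
    cfg <- synthesis_config(seed = seed)  # intra 0.9, background 0.05
    ppi <- simulate_ppi(cfg, sprintf("m%03d", 1:150))
    g <- suppressMessages(interaction_graph(ppi$edges))
    cl <- mcode_clusters(g, mcode_params(fluff = TRUE))
    jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
    for (cx in ppi$complexes) {
      best <- max(vapply(cl, function(c) jaccard(cx, c$members), numeric(1)))
      expect_gte(best, 0.8)
    }
  }
})

test_that("normalized betweenness matches the brute-force all-pairs oracle", {
  star <- suppressMessages(interaction_graph(data.frame(
    node1 = "hub", node2 = paste0("leaf", 1:5), combined_score = 900)))
  bs <- betweenness_centrality(star)
  expect_equal(unname(bs["hub"]), 1)
  expect_true(all(bs[paste0("leaf", 1:5)] == 0))
  pathg <- suppressMessages(interaction_graph(data.frame(
    node1 = c("a", "b"), node2 = c("b", "c"), combined_score = 900)))
  expect_equal(unname(betweenness_centrality(pathg)["b"]), 1)
  # two triangles sharing one vertex: the shared vertex carries 4 of the 6
  # normalized pair dependencies
  tt <- suppressMessages(interaction_graph(rbind(
    clique_edges(c("s", "a1", "a2")), clique_edges(c("s", "b1", "b2")))))
  expect_equal(unname(betweenness_centrality(tt)["s"]), 4 / 6)
  # random graphs up to 12 nodes against the brute-force oracle
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(5:12, 1)
    adj <- matrix(0L, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.35) adj[i, j] <- adj[j, i] <- 1L
    nm <- sprintf("v%02d", 1:n)
    dimnames(adj) <- list(nm, nm)
    keep <- rowSums(adj) > 0
    if (sum(keep) < 3) next
    adj <- adj[keep, keep, drop = FALSE]
    gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    raw_oracle <- brute_betweenness(adj)
    comp <- igraph::components(gg)
    csize <- comp$csize[comp$membership]
    norm_oracle <- ifelse(csize > 2, raw_oracle / ((csize - 1) * (csize - 2) / 2), 0)
    expect_equal(unname(betweenness_centrality(gg)), unname(norm_oracle),
                 tolerance = 1e-12)
  }
})

test_that("hub calling selects candidates above threshold and per-cluster main hubs", {
  c1 <- paste0("c", 1:5)
  d1 <- paste0("d", 1:5)
  edges <- rbind(clique_edges(c1), clique_edges(d1),
                 data.frame(node1 = c("c1", "x"), node2 = c("x", "d1"),
                            combined_score = 900))
  g <- suppressMessages(interaction_graph(edges))
  cl <- mcode_clusters(g)
  hubs <- betweenness_hubs(g, cl)
  # the bridge node and its two clique anchors route the cross-clique
  # shortest paths: raw scores 25 (x) and 24 (c1, d1) over 45 pairs
  expect_equal(hubs$candidates, c("c1", "d1", "x"))
  expect_equal(unname(hubs$main_hubs), c("c1", "d1"))
  expect_true(all(hubs$betweenness >= 0 & hubs$betweenness <= 1))
  percl <- betweenness_hubs(g, cl, hub_config(scope = "per_cluster"))
  expect_length(percl$candidates, 0)  # cliques have no internal bottleneck
  expect_error(hub_config(candidate_threshold = 1.2), "candidate_threshold")
})
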