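test_that("node metrics on canonical graphs match hand-computed values", {
  star <- canonicalGraph("star", 5)
  tab <- nodeTable(nodeMetrics(star))
  center <- tab[tab$node == "v1", ]
  expect_equal(center$closeness, 0.25)
  expect_equal(center$betweenness, 6)   # C(4,2) leaf pairs
  expect_equal(center$clustering, 0)

  path <- canonicalGraph("path", 3)
  tb <- nodeTable(nodeMetrics(path))
  b <- tb[tb$node == "v2", ]
  expect_equal(b$closeness, 0.5)
  expect_equal(b$betweenness, 1)
  expect_equal(b$degree, 2)

  tri <- canonicalGraph("cycle", 3)
  tt <- nodeTable(nodeMetrics(tri))
  expect_equal(tt$clustering, rep(1, 3))
  expect_equal(tt$betweenness, rep(0, 3))
})

test_that("network aggregates match closed forms and published density", {
  k5 <- canonicalGraph("complete", 5)
  st <- networkStats(networkAggregates(k5, nodeMetrics(k5)))
  expect_equal(st$avgPathLength, 1)
  expect_equal(st$efficiency, 1)
  expect_equal(st$density, 1)

  p3 <- canonicalGraph("path", 3)
  st3 <- networkStats(networkAggregates(p3, nodeMetrics(p3)))
  expect_equal(st3$avgPathLength, 8 / 6)
  expect_equal(st3$efficiency, 5 / 6)
  expect_equal(st3$barycenter, "v2")
  expect_equal(st3$diameter, 2)

  # published Homo sapiens density from N = 216, M = 2643
  g <- emulateOrganism("Homo sapiens", seed = 2)
  sth <- networkStats(networkAggregates(g, nodeMetrics(g), communities = FALSE))
  expect_equal(round(sth$density, 3), 0.114)
})

test_that("disconnected networks fall back to the largest component with a warning", {
  g <- igraph::disjoint_union(canonicalGraph("path", 3), canonicalGraph("path", 2))
  igraph::V(g)$name <- paste0("u", 1:5)
  tab <- nodeMetrics(g)
  expect_warning(st <- networkStats(networkAggregates(g, tab, communities = FALSE)),
                 "largest connected component")
  expect_equal(st$avgPathLength, 8 / 6)
  expect_equal(st$diameter, 2)
})

test_that("normalization follows the size-removal conventions", {
  star <- canonicalGraph("star", 5)
  tab <- normalizeMetrics(networkAggregates(star, nodeMetrics(star), communities = FALSE))
  nt <- nodeTable(tab)
  c1 <- nt[nt$node == "v1", ]
  expect_equal(c1$normCloseness, 1.0)   # 4 * 0.25
  expect_equal(c1$normDegree, 1.0)      # 4/4

  p3 <- canonicalGraph("path", 3)
  nb <- nodeTable(normalizeMetrics(nodeMetrics(p3)))$normBetweenness
  expect_equal(nb, c(0, 1, 0))

  # degenerate min-max: all-equal betweenness maps to all zeros
  tri <- canonicalGraph("cycle", 3)
  expect_equal(nodeTable(normalizeMetrics(nodeMetrics(tri)))$normBetweenness,
               rep(0, 3))
  expect_error(normalizeMetrics(nodeMetrics(canonicalGraph("empty", 1))), "N >= 2")
})

test_that("degree sum equals twice the edge count across a seeded corpus", {
  for (g in random_graph_corpus(20, seed = 7)) {
    if (igraph::is_directed(g)) next
    tab <- nodeTable(nodeMetrics(g))
    expect_equal(sum(tab$degree), 2 * igraph::ecount(g))
  }
})

test_that("node metrics agree with brute-force BFS/path-enumeration oracles", {
  corpus <- Filter(Negate(igraph::is_directed), random_graph_corpus(40, seed = 13))
  expect_gte(length(corpus), 15)
  for (g in corpus) {
    tab <- nodeTable(nodeMetrics(g))
    d <- oracle_distances(g)
    reach <- apply(d, 1, function(r) sum(r[is.finite(r) & r > 0]))
    expect_equal(tab$closeness, ifelse(reach > 0, 1 / reach, 0))
    expect_equal(tab$betweenness, oracle_betweenness(g), tolerance = 1e-10)
    expect_equal(tab$clustering, oracle_clustering(g))
    ecc <- apply(d, 1, function(r) max(c(r[is.finite(r)], 0)))
    expect_equal(tab$eccentricity, unname(ecc))
  }
})

test_that("community detection handles degenerate and block-structured inputs", {
  clique <- canonicalGraph("complete", 6)
  cm <- detectCommunities(clique, seed = 3)
  expect_equal(cm$nCommunities, 1)
  expect_equal(cm$modularity, 0)

  edgeless <- canonicalGraph("empty", 4)
  cm0 <- detectCommunities(edgeless, seed = 3)
  expect_equal(cm0$nCommunities, 4)
  expect_equal(cm0$modularity, 0)

  tcb <- canonicalGraph("two_clique_bridge", 10)
  cmb <- detectCommunities(tcb, seed = 1)
  expect_equal(cmb$nCommunities, 2)
  blocks <- rep(1:2, each = 5)
  expect_equal(oracle_adjusted_rand(cmb$membership, blocks), 1)
  # modularity of the returned partition matches an independent computation
  expect_equal(cmb$modularity, oracle_modularity(tcb, cmb$membership))
  expect_true(cmb$modularity >= 0 && cmb$modularity <= 1)
})

test_that("the metric report mirrors the summary-table layout", {
  g <- canonicalGraph("two_clique_bridge", 10)
  tabs <- list(bridge = networkAggregates(g, nodeMetrics(g), seed = 1))
  rep1 <- metricReport(tabs)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$nRecords, 42L)
  expect_named(rep1, c("network", "barycenter", "nNodes", "nRecords", "density",
                       "diameter", "avgDegree", "avgCloseness", "avgBetweenness",
                       "avgClustering", "modularity", "nCommunities"))
})
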