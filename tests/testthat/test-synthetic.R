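test_that("canonical graphs have their defining structure", {
  expect_equal(igraph::ecount(canonicalGraph("complete", 5)), 10)
  star <- canonicalGraph("star", 5)
  expect_equal(unname(igraph::degree(star)[c("v1", "v2")]), c(4, 1))
  tcb <- canonicalGraph("two_clique_bridge", 10)
  expect_equal(igraph::ecount(tcb), 21)
  expect_equal(igraph::ecount(canonicalGraph("cycle", 6)), 6)
  expect_equal(igraph::ecount(canonicalGraph("empty", 4)), 0)
  expect_error(canonicalGraph("cycle", 2), "n >= 3")
  expect_error(canonicalGraph("two_clique_bridge", 7), "even")
})

test_that("explicit degree sequences are realized exactly; (3,1,1,1) is the star", {
  g <- sampleGraphicalNetwork(syntheticProfile(degreeSequence = c(3, 1, 1, 1), seed = 5))
  expect_equal(sort(as.numeric(igraph::degree(g))), c(1, 1, 1, 3))
  # unique simple realization on 4 nodes: the star
  expect_equal(igraph::ecount(g), 3)
  hub <- which.max(igraph::degree(g))
  expect_true(all(igraph::as_edgelist(g, names = FALSE) == hub |
                  igraph::as_edgelist(g, names = FALSE) %in% setdiff(1:4, hub)))

  for (seed in 1:5) {
    degs <- c(4, 3, 3, 2, 2, 1, 1)
    h <- sampleGraphicalNetwork(syntheticProfile(degreeSequence = degs, seed = seed))
    expect_equal(sort(as.numeric(igraph::degree(h))), sort(degs))
    expect_true(igraph::is_simple(h))
  }
})

test_that("non-graphical sequences are rejected with the violated condition named", {
  expect_error(sampleGraphicalNetwork(syntheticProfile(degreeSequence = c(3, 1))),
               "exceeds n-1")
  expect_error(sampleGraphicalNetwork(syntheticProfile(degreeSequence = c(1, 1, 1))),
               "odd degree sum")
  expect_error(sampleGraphicalNetwork(syntheticProfile(degreeSequence = c(3, 3, 1, 1))),
               "Erdos-Gallai")
})

test_that("generation is deterministic under a fixed seed", {
  prof <- syntheticProfile(blockSizes = c(15, 15), pIn = 0.9, pOut = 0.05, seed = 11)
  g1 <- sampleGraphicalNetwork(prof)
  g2 <- sampleGraphicalNetwork(prof)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))

  e1 <- emulateOrganism("Saccharomyces cerevisiae", seed = 4)
  e2 <- emulateOrganism("Saccharomyces cerevisiae", seed = 4)
  expect_identical(igraph::as_edgelist(e1), igraph::as_edgelist(e2))
})

test_that("planted two-block networks are recovered by community detection", {
  prof <- syntheticProfile(blockSizes = c(15, 15), pIn = 0.9, pOut = 0.05, seed = 21)
  g <- sampleGraphicalNetwork(prof)
  cm <- detectCommunities(g, seed = 1)
  expect_equal(oracle_adjusted_rand(cm$membership, igraph::V(g)$block), 1)
})

test_that("emulated organisms match the published node/edge counts and density", {
  cases <- list(c("Drosophila melanogaster", 57, 380),
                c("Arabidopsis thaliana", 62, 594),
                c("Homo sapiens", 216, 2643))
  tab <- organismTable()
  for (cs in cases) {
    g <- emulateOrganism(cs[1], seed = 9)
    expect_equal(igraph::vcount(g), as.integer(cs[2]))
    expect_equal(igraph::ecount(g), as.integer(cs[3]))
    expect_true(igraph::is_simple(g))
    row <- tab[tab$organism == cs[1], ]
    expect_equal(round(2 * igraph::ecount(g) / (igraph::vcount(g) * (igraph::vcount(g) - 1)), 3),
                 row$density)
    # dominant hub carries the barycenter protein label
    expect_equal(igraph::V(g)$name[which.max(igraph::degree(g))], row$barycenter)
  }
  expect_error(emulateOrganism("Canis lupus"), "unknown organism")
})
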