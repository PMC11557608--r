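test_that("configuration replicates preserve the degree sequence exactly", {
  graphs <- list(canonicalGraph("star", 6),
                 canonicalGraph("two_clique_bridge", 10),
                 sampleGraphicalNetwork(syntheticProfile(degreeSequence = c(4, 3, 3, 2, 2, 1, 1),
                                                         seed = 2)))
  for (g in graphs) {
    for (s in 1:10) {
      h <- configurationModel(g, seed = s)
      expect_identical(igraph::degree(h), igraph::degree(g))
      expect_true(igraph::is_simple(h))
    }
  }
  # (3,1,1,1) has a unique simple realization: every replicate is the star
  star <- canonicalGraph("star", 4)
  h <- configurationModel(star, seed = 8)
  expect_equal(sort(igraph::degree(h)), sort(igraph::degree(star)))
  expect_equal(unname(igraph::degree(h)["v1"]), 3)
})

test_that("the 6-cycle degree class yields multiple distinct realizations", {
  c6 <- canonicalGraph("cycle", 6)
  keys <- vapply(1:10, function(s) {
    el <- igraph::as_edgelist(configurationModel(c6, seed = s))
    paste(sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))), collapse = ";")
  }, character(1))
  expect_gt(length(unique(keys)), 1)
})

test_that("ensemble z-scores follow (x - mu)/sigma with sample sd and flag degeneracy", {
  # arithmetic check on a hand-built ensemble path: native 10 vs {2,4,6}
  x <- 10; reps <- c(2, 4, 6)
  expect_equal((x - mean(reps)) / sd(reps), 3)

  g <- canonicalGraph("two_clique_bridge", 10)
  ens <- nullEnsemble(g, R = 5, seed = 3)
  expect_s4_class(ens, "NullEnsemble")
  zs <- ensembleZScores(ens)
  agg <- ensembleAggregates(ens)
  nat <- nodeTable(nodeMetrics(g))
  manual <- (mean(nat$closeness) - mean(agg$avgCloseness)) / sd(agg$avgCloseness)
  i <- zs$metric == "avgCloseness"
  if (zs$defined[i]) {
    expect_equal(zs$z[i], manual)
  } else {
    expect_true(is.na(zs$z[i]))
  }

  # degenerate ensemble: star replicates are all identical, sigma = 0
  star <- canonicalGraph("star", 4)
  zs2 <- ensembleZScores(star, R = 4, seed = 1)
  expect_true(all(!zs2$defined))
  expect_true(all(is.na(zs2$z)))
})

test_that("paired signed-rank matches exact enumeration for small n", {
  expect_equal(pairedSignedRank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1)), 2 / 32)
  expect_warning(p <- pairedSignedRank(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_equal(p, 1)
  expect_equal(pairedSignedRank(c(1, -1), c(0, 0)), 1)  # antisymmetric differences

  set.seed(99)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    d <- round(runif(n, 0.5, 10), 3) * sample(c(-1, 1), n, replace = TRUE)
    while (anyDuplicated(abs(d))) d <- d + runif(n, 0, 1e-3)
    x <- rnorm(n)
    expect_equal(pairedSignedRank(x, x - d), oracle_signed_rank(d),
                 tolerance = 1e-12, label = sprintf("enumeration rep %d", rep))
  }
})

test_that("cross-group rank tests produce a Bonferroni-adjusted symmetric matrix", {
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  m <- crossSpeciesTest(same)
  expect_true(is.nan(m[1, 1]) && is.nan(m[2, 2]))
  expect_equal(m[1, 2], 1)

  apart <- list(lo = 1:5, hi = 101:105)
  m2 <- crossSpeciesTest(apart)
  # complete rank separation at n1 = n2 = 5: H = 6.82, p ~ 0.009
  expect_lt(m2[1, 2], 0.05)
  expect_equal(m2[1, 2], m2[2, 1])

  three <- list(a = 1:5, b = 1:5 + 0.001, c = 101:105)
  m3 <- crossSpeciesTest(three)
  expect_gt(m3["a", "b"], 0.5)
  expect_lt(m3["a", "c"], 0.05)
  expect_lt(m3["b", "c"], 0.05)
  expect_true(isSymmetric(unname(m3)))

  expect_error(crossSpeciesTest(list(a = 1, b = 1:3)), "at least 2 values")
  expect_error(crossSpeciesTest(list(a = 1:3)), "two groups")
})

test_that("Pearson correlations reproduce the published cross-organism coefficients", {
  tab <- organismTable()
  expect_equal(round(pearsonCor(tab$avgCloseness, tab$avgBetweenness)$r, 2), -0.94)
  expect_equal(round(pearsonCor(tab$avgDegree, tab$avgCloseness)$r, 2), -0.04)
  expect_equal(round(pearsonCor(tab$avgDegree, tab$avgBetweenness)$r, 3), 0.006)
  expect_lt(pearsonCor(tab$avgCloseness, tab$avgBetweenness)$p, 1e-5)

  expect_equal(pearsonCor(1:5, 2 * (1:5) + 1)$r, 1)
  flat <- pearsonCor(rep(1, 5), 1:5)
  expect_false(flat$defined)
  expect_true(is.na(flat$r))
})

test_that("UPGMA dendrograms merge in the expected order and heights", {
  h <- hierarchicalDendrogram(matrix(c(0, 0.1, 5), ncol = 1))
  expect_identical(sort(h$merge[1, ]), c(-2L, -1L))  # {0, 0.1} first

  h2 <- hierarchicalDendrogram(matrix(c(0, 1, 2.5), ncol = 1))
  expect_equal(h2$height[2], 2.0)  # average linkage: mean(2.5, 1.5)

  h3 <- hierarchicalDendrogram(rbind(c(1, 2), c(1, 2)))
  expect_equal(h3$height[1], 0)
})
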