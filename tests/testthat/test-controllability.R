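test_that("system assembly places weights on the influence pattern and B on inputs", {
  p3 <- canonicalGraph("path", 3)
  sys <- buildControlSystem(p3, "v1", weightMode = "binary")
  A <- stateMatrix(sys)
  expect_equal(A != 0,
               matrix(c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                      3, 3, dimnames = dimnames(A)))
  expect_equal(unname(controlMatrix(sys)[, 1]), c(1, 0, 0))

  all_in <- buildControlSystem(p3, c("v1", "v2", "v3"))
  expect_equal(unname(controlMatrix(all_in)), diag(3))
  expect_error(buildControlSystem(p3, c("v1", "v1")), "duplicate")
  expect_error(buildControlSystem(p3, character(0)), "at least one")
})

test_that("Kalman rank condition resolves canonical directed cases", {
  chain <- igraph::make_graph(c("a", "b"), directed = TRUE)
  expect_true(kalmanControllable(buildControlSystem(chain, "a")))
  expect_false(kalmanControllable(buildControlSystem(chain, "b")))

  iso3 <- canonicalGraph("empty", 3)
  expect_false(kalmanControllable(buildControlSystem(iso3, "v1")))
  expect_true(kalmanControllable(buildControlSystem(iso3, c("v1", "v2", "v3"))))
})

test_that("minimum driver sets on hand-solvable fixtures", {
  expect_equal(driverCount(minimumDriverNodes(canonicalGraph("empty", 3))), 3L)
  expect_equal(driverCount(minimumDriverNodes(canonicalGraph("star", 4))), 2L)

  chain3 <- igraph::make_graph(c("1", "2", "2", "3"), directed = TRUE)
  r <- enumerateDriverSets(chain3)
  expect_equal(driverCount(r), 1L)
  expect_equal(driverSets(r), list("1"))

  edge <- igraph::make_graph(c("a", "b"), directed = FALSE)
  re <- enumerateDriverSets(edge)
  expect_equal(driverCount(re), 1L)
  expect_setequal(vapply(driverSets(re), identity, character(1)), c("a", "b"))

  iso2 <- canonicalGraph("empty", 2)
  ri <- enumerateDriverSets(iso2)
  expect_equal(driverSets(ri), list(c("v1", "v2")))

  expect_error(enumerateDriverSets(edge, cap = 0), "cap")
})

test_that("directed graphs where the bare matching bound is unachievable still verify", {
  # two source 2-cycles feeding one sink: matching leaves one unmatched
  # in-copy, but no single dedicated input reaches both cycles
  g <- igraph::make_graph(c("1", "2", "2", "1", "3", "4", "4", "3", "2", "5", "4", "5"),
                          directed = TRUE)
  r <- minimumDriverNodes(g)
  expect_equal(driverCount(r), 2L)
  expect_true(r@verified)
  expect_equal(oracle_min_drivers(g, seed = 3), 2)
})

test_that("driver counts are invariant under node relabeling", {
  set.seed(17)
  g <- igraph::sample_gnp(7, 0.3)
  igraph::V(g)$name <- paste0("n", 1:7)
  k1 <- driverCount(minimumDriverNodes(g, verify = FALSE))
  perm <- sample(7)
  h <- igraph::permute(g, perm)
  expect_equal(driverCount(minimumDriverNodes(h, verify = FALSE)), k1)
})

test_that("matching-based driver count equals the brute-force Kalman minimum on a corpus", {
  corpus <- random_graph_corpus(30, seed = 71)
  for (i in seq_along(corpus)) {
    g <- corpus[[i]]
    res <- enumerateDriverSets(g, cap = 64, verify = FALSE, seed = i)
    expect_equal(driverCount(res), as.integer(oracle_min_drivers(g, seed = i)),
                 label = sprintf("corpus graph %d driver count", i))
    # every enumerated set passes generic-weight rank verification
    for (s in driverSets(res)) {
      expect_true(verifyDriverSet(g, s, seed = i),
                  label = sprintf("corpus graph %d set {%s}", i, paste(s, collapse = ",")))
    }
  }
})

test_that("the explicit controllability matrix has the Kalman rank", {
  p3 <- canonicalGraph("path", 3)
  sys <- buildControlSystem(p3, "v1", weightMode = "generic", seed = 2)
  C <- controllabilityMatrix(sys)
  expect_equal(dim(C), c(3L, 3L))
  expect_equal(qr(C)$rank == 3, kalmanControllable(sys))
  sys2 <- buildControlSystem(canonicalGraph("empty", 3), "v1")
  expect_lt(qr(controllabilityMatrix(sys2))$rank, 3)
})
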