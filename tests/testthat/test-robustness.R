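test_that("attack orders sort by the static metric with deterministic ties", {
  star <- canonicalGraph("star", 5)
  expect_equal(attackOrder(star, "degree", "descending")[1], "v1")
  expect_equal(attackOrder(star, "degree", "ascending")[5], "v1")
  # leaf ties broken lexicographically
  expect_equal(attackOrder(star, "degree", "ascending")[1:4],
               c("v2", "v3", "v4", "v5"))

  p3 <- canonicalGraph("path", 3)
  expect_equal(attackOrder(p3, "betweenness", "descending")[1], "v2")

  r1 <- attackOrder(star, "random", seed = 5)
  expect_identical(r1, attackOrder(star, "random", seed = 5))
  expect_setequal(r1, igraph::V(star)$name)
})

test_that("attack traces match hand-computed LCC sequences", {
  k10 <- canonicalGraph("complete", 10)
  tr <- runAttack(k10, igraph::V(k10)$name)
  expect_equal(lccFraction(tr), seq(0.9, 0, by = -0.1))

  star <- canonicalGraph("star", 5)
  center_first <- runAttack(star, paste0("v", 1:5))
  expect_equal(lccFraction(center_first), c(0.2, 0.2, 0.2, 0.2, 0))
  leaves_first <- runAttack(star, c("v2", "v3", "v4", "v5", "v1"))
  expect_equal(lccFraction(leaves_first), c(0.8, 0.6, 0.4, 0.2, 0))

  expect_error(runAttack(star, c("v1", "v1", "v2", "v3", "v4")), "permutation")
})

test_that("robustness integral matches closed forms", {
  k10 <- canonicalGraph("complete", 10)
  expect_equal(robustnessR(runAttack(k10, igraph::V(k10)$name)), 0.45)
  star <- canonicalGraph("star", 5)
  expect_equal(robustnessR(runAttack(star, paste0("v", 1:5))), 0.16)
  expect_equal(robustnessR(runAttack(star, c("v2", "v3", "v4", "v5", "v1"))), 0.40)
})

test_that("hub-first attacks are at most as robust as hub-last on hub-dominated graphs", {
  graphs <- list(canonicalGraph("star", 12),
                 emulateOrganism("Drosophila melanogaster", seed = 3))
  for (g in graphs) {
    down <- runAttack(g, attackOrder(g, "degree", "descending"))
    up <- runAttack(g, attackOrder(g, "degree", "ascending"))
    expect_lte(robustnessR(down), robustnessR(up))
  }
})

test_that("LCC fraction is non-increasing and efficiency drop monotone on a seeded corpus", {
  corpus <- Filter(Negate(igraph::is_directed), random_graph_corpus(50, seed = 31))
  strategies <- c("random", "degree", "closeness", "betweenness")
  for (i in seq_along(corpus)) {
    g <- corpus[[i]]
    strat <- strategies[(i %% 4) + 1]
    tr <- runAttack(g, attackOrder(g, strat, "ascending", seed = i),
                    strategy = strat)
    expect_true(all(diff(lccFraction(tr)) <= 1e-12))
    expect_equal(lccFraction(tr)[igraph::vcount(g)], 0)
    de <- deltaEfficiency(tr)
    expect_true(all(de >= -1e-12 & de <= 1 + 1e-12))
    expect_true(all(diff(de) >= -1e-12))
  }
})

test_that("per-step LCC agrees with a brute-force components scan", {
  corpus <- Filter(Negate(igraph::is_directed), random_graph_corpus(20, seed = 57))
  for (g in corpus) {
    n <- igraph::vcount(g)
    ord <- attackOrder(g, "degree", "descending")
    tr <- runAttack(g, ord)
    h <- g
    manual <- numeric(n)
    for (i in seq_len(n)) {
      h <- igraph::delete_vertices(h, ord[i])
      manual[i] <- if (igraph::vcount(h) == 0) 0 else oracle_lcc_size(h) / n
    }
    expect_equal(lccFraction(tr), manual)
  }
})

test_that("jump detection flags drops at or above the threshold, inclusively", {
  star <- canonicalGraph("star", 5)
  j <- detectJumps(runAttack(star, paste0("v", 1:5)))
  expect_true(1 %in% j$step)
  expect_equal(j$node[j$step == 1], "v1")
  expect_equal(j$deltaG[j$step == 1], 0.8)

  # K10: every drop is exactly 0.1; inclusive threshold flags all steps
  k10 <- canonicalGraph("complete", 10)
  jk <- detectJumps(runAttack(k10, igraph::V(k10)$name), threshold = 0.10)
  expect_equal(jk$step, 1:10)
  # strictly larger threshold flags none
  expect_equal(nrow(detectJumps(runAttack(k10, igraph::V(k10)$name), threshold = 0.11)), 0)

  p3 <- canonicalGraph("path", 3)
  jp <- detectJumps(runAttack(p3, c("v2", "v1", "v3")))
  expect_true(1 %in% jp$step)
  expect_equal(jp$deltaG[jp$step == 1], 1 - 1 / 3)
})

test_that("adaptive ranking recomputes the target after every removal", {
  # star v1-(v2,v3,v4) with a tail v4-v5-v6: once the hub falls, v4's degree
  # drops to 1 and the adaptive attack turns to v5 instead
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("v1", "v1", "v1", "v4", "v5"),
               to   = c("v2", "v3", "v4", "v5", "v6")), directed = FALSE)
  static <- attackOrder(g, "degree", "descending")
  expect_equal(static[1:2], c("v1", "v4"))
  adaptive <- attackOrder(g, "degree", "descending", adaptive = TRUE)
  expect_equal(adaptive[1], "v1")
  expect_equal(adaptive[2], "v5")
  expect_setequal(adaptive, igraph::V(g)$name)
})
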