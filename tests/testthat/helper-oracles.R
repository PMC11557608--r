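# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph's metric routines): metrics
# are recomputed from raw adjacency structure with plain BFS / enumeration.

# adjacency list from an igraph, by vertex index
oracle_adjlist <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      a <- el[r, 1]; b <- el[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# all-pairs shortest-path distances by BFS (Inf when unreachable)
oracle_distances <- function(g) {
  n <- igraph::vcount(g)
  adj <- oracle_adjlist(g)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!is.finite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

# betweenness by explicit enumeration of all shortest paths (tiny graphs)
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- oracle_adjlist(g)
  d <- oracle_distances(g)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    # enumerate shortest s-t paths by DFS on the BFS DAG
    res <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1]] <<- path
        return()
      }
      for (w in adj[[v]]) {
        if (is.finite(d[s, w]) && d[s, w] == d[s, v] + 1 && is.finite(d[w, t]) &&
            d[s, w] + d[w, t] == d[s, t]) {
          walk(c(path, w))
        }
      }
    }
    walk(s)
    res
  }
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      paths <- all_paths(s, t)
      if (!length(paths)) next
      counts <- numeric(n)
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        counts[inner] <- counts[inner] + 1
      }
      btw <- btw + counts / length(paths)
    }
  }
  btw
}

oracle_clustering <- function(g) {
  n <- igraph::vcount(g)
  adj <- oracle_adjlist(g)
  am <- matrix(FALSE, n, n)
  for (v in seq_len(n)) am[v, adj[[v]]] <- TRUE
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) { out[v] <- 0; next }
    links <- 0
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      if (am[nb[i], nb[j]]) links <- links + 1
    }
    out[v] <- links / (k * (k - 1) / 2)
  }
  out
}

oracle_lcc_size <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(0)
  d <- oracle_distances(g)
  max(rowSums(is.finite(d)))
}

# exact two-sided signed-rank p-value by enumerating all sign assignments,
# mirroring the classical convention (2 * tail of the observed statistic,
# capped at 1); assumes no zero differences and no tied magnitudes
oracle_signed_rank <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  p <- if (w_obs > mu) 2 * mean(w_all >= w_obs) else 2 * mean(w_all <= w_obs)
  min(p, 1)
}

# independent Kalman controllability: explicit controllability matrix and
# base-R qr rank, with its own weight draw (safe for tiny n only)
oracle_controllable <- function(g, inputs_idx, seed) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!igraph::is_directed(g) && nrow(el)) el <- rbind(el, el[, 2:1, drop = FALSE])
  A <- matrix(0, n, n)
  set.seed(seed)
  if (nrow(el)) {
    A[cbind(el[, 2], el[, 1])] <- runif(nrow(el), 0.5, 1.5) *
      sample(c(-1, 1), nrow(el), replace = TRUE)
  }
  B <- matrix(0, n, length(inputs_idx))
  B[cbind(inputs_idx, seq_along(inputs_idx))] <- 1
  C <- B
  blk <- B
  for (k in seq_len(n - 1)) {
    blk <- A %*% blk
    C <- cbind(C, blk)
  }
  qr(C)$rank == n
}

# brute-force minimum driver count: smallest k such that some k-subset of
# nodes is controllable under generic weights (two draws guard against a
# non-generic one)
oracle_min_drivers <- function(g, seed = 1) {
  n <- igraph::vcount(g)
  for (k in seq_len(n)) {
    combs <- utils::combn(n, k)
    for (j in seq_len(ncol(combs))) {
      if (oracle_controllable(g, combs[, j], seed) ||
          oracle_controllable(g, combs[, j], seed + 1)) {
        return(k)
      }
    }
  }
  n
}

# adjusted Rand index between two label vectors
oracle_adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}

# Newman-Girvan modularity of a membership vector, computed from scratch
oracle_modularity <- function(g, memb) {
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- tabulate(c(el[, 1], el[, 2]), igraph::vcount(g))
  q <- 0
  for (c_id in unique(memb)) {
    idx <- which(memb == c_id)
    e_c <- sum(memb[el[, 1]] == c_id & memb[el[, 2]] == c_id)
    q <- q + e_c / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# enumerate all set partitions of 1..n as restricted growth strings
oracle_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      out[[length(out) + 1]] <<- rgs[seq_len(n)]
      return()
    }
    for (v in seq_len(maxv + 1)) {
      rgs[i] <<- v
      recurse(i + 1, max(maxv, v))
    }
  }
  recurse(1, 0)
  out
}

# seeded corpus of small random graphs (directed and undirected)
random_graph_corpus <- function(n_graphs, seed = 42, n_max = 8) {
  set.seed(seed)
  lapply(seq_len(n_graphs), function(i) {
    n <- sample(2:n_max, 1)
    directed <- i %% 2 == 0
    p <- runif(1, 0.15, 0.7)
    g <- igraph::sample_gnp(n, p, directed = directed)
    igraph::V(g)$name <- paste0("n", seq_len(n))
    g
  })
}
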