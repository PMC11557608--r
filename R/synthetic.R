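#' Deterministic canonical graphs
#'
#' Small named graphs with analytically known descriptor values, used as
#' oracles throughout the test suite and useful as teaching fixtures. Nodes
#' are labeled \code{v1..vn}; for the star, \code{v1} is the center; for
#' \code{two_clique_bridge}, nodes split into two K_{n/2} blocks joined by a
#' single bridge edge.
#'
#' @param kind one of "star", "path", "cycle", "complete",
#'   "two_clique_bridge", "empty".
#' @param n number of nodes (>= 1; >= 3 for cycle; even and >= 4 for
#'   two_clique_bridge).
#' @return An undirected simple igraph.
#' @examples
#' igraph::ecount(canonicalGraph("complete", 5))          # 10
#' igraph::degree(canonicalGraph("star", 5))["v1"]        # 4
#' igraph::ecount(canonicalGraph("two_clique_bridge", 10)) # 21
#' @export
canonicalGraph <- function(kind = c("star", "path", "cycle", "complete",
                                    "two_clique_bridge", "empty"),
                           n) {
  kind <- match.arg(kind)
  stopifnot(isCount(n), n >= 1)
  g <- switch(kind,
    star = igraph::make_star(n, mode = "undirected", center = 1),
    path = igraph::make_ring(n, circular = FALSE),
    cycle = {
      if (n < 3) stop("a cycle needs n >= 3", call. = FALSE)
      igraph::make_ring(n, circular = TRUE)
    },
    complete = igraph::make_full_graph(n),
    two_clique_bridge = {
      if (n < 4 || n %% 2 != 0) {
        stop("two_clique_bridge needs an even n >= 4", call. = FALSE)
      }
      h <- n %/% 2
      g1 <- igraph::make_full_graph(h)
      g2 <- igraph::make_full_graph(h)
      g12 <- igraph::disjoint_union(g1, g2)
      igraph::add_edges(g12, c(1, h + 1))
    },
    empty = igraph::make_empty_graph(n, directed = FALSE)
  )
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

#' Synthetic network profile
#'
#' Parameter bundle for \code{\link{sampleGraphicalNetwork}}. Exactly one of
#' three generation modes applies: an explicit degree sequence (realized
#' exactly), a planted-partition/community profile (\code{blockSizes} with
#' \code{pIn}/\code{pOut}), or a heavy-tailed profile (\code{nNodes} with a
#' power-law exponent and optional dominant hub degree).
#'
#' @param nNodes node count (required unless \code{degreeSequence} or
#'   \code{blockSizes} determines it).
#' @param degreeSequence optional explicit degree sequence; must be graphical
#'   (Erdos-Gallai satisfiable).
#' @param blockSizes optional integer vector of community sizes.
#' @param pIn,pOut intra/inter-community edge probabilities in [0,1].
#' @param powerlawExponent exponent of the heavy-tailed degree distribution
#'   (default 2.1, the scale-free regime typical of PPI networks).
#' @param hubDegree optional degree for a single dominant hub node.
#' @param seed integer RNG seed.
#' @return An object of class \code{SyntheticProfile}.
#' @export
syntheticProfile <- function(nNodes = NULL, degreeSequence = NULL,
                             blockSizes = NULL, pIn = 0.9, pOut = 0.05,
                             powerlawExponent = 2.1, hubDegree = NULL,
                             seed = 1L) {
  if (!is.null(degreeSequence)) {
    checkGraphical(degreeSequence)
    nNodes <- length(degreeSequence)
  } else if (!is.null(blockSizes)) {
    stopifnot(all(vapply(blockSizes, isCount, logical(1))), length(blockSizes) >= 1)
    if (!isFraction(pIn) || !isFraction(pOut)) {
      stop("pIn and pOut must be probabilities in [0,1]", call. = FALSE)
    }
    nNodes <- sum(blockSizes)
  }
  if (is.null(nNodes) || !isCount(nNodes) || nNodes < 1) {
    stop("a positive node count is required", call. = FALSE)
  }
  structure(list(nNodes = as.integer(nNodes),
                 degreeSequence = degreeSequence,
                 blockSizes = blockSizes, pIn = pIn, pOut = pOut,
                 powerlawExponent = powerlawExponent, hubDegree = hubDegree,
                 seed = as.integer(seed)),
            class = "SyntheticProfile")
}

# Erdos-Gallai check; errors naming the first violated prefix, or the parity
# violation, for non-graphical sequences.
checkGraphical <- function(d) {
  if (!is.numeric(d) || any(d != floor(d)) || any(d < 0)) {
    stop("degree sequence must consist of non-negative integers", call. = FALSE)
  }
  n <- length(d)
  if (any(d > n - 1)) {
    stop(sprintf("degree sequence not graphical: degree %d exceeds n-1 = %d",
                 max(d), n - 1), call. = FALSE)
  }
  if (sum(d) %% 2 != 0) {
    stop("degree sequence not graphical: odd degree sum", call. = FALSE)
  }
  ds <- sort(as.integer(d), decreasing = TRUE)
  for (k in seq_len(n)) {
    lhs <- sum(ds[seq_len(k)])
    rhs <- k * (k - 1) + sum(pmin(ds[-seq_len(k)], k))
    if (lhs > rhs) {
      stop(sprintf(
        "degree sequence not graphical: Erdos-Gallai violated at k = %d (sum of %d largest degrees %d > %d)",
        k, k, lhs, rhs), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Realize an exact degree sequence as a simple graph, deterministically under
# `seed`: Havel-Hakimi construction (always succeeds on graphical input)
# followed by seeded degree-preserving double-edge swaps, the standard
# switching randomization. Guarantees the exact sequence, simplicity and
# termination even for tight hub-dominated sequences.
realizeDegreeSequence <- function(degs, seed) {
  checkGraphical(degs)
  n <- length(degs)
  el <- havelHakimi(as.integer(degs))
  el <- edgeSwapRandomize(el, n, seed)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, as.vector(t(el)))
  g
}

# Havel-Hakimi: connect the highest remaining degree to the next-highest
# ones; produces one simple realization of any graphical sequence.
havelHakimi <- function(d) {
  n <- length(d)
  rem <- as.integer(d)
  from <- integer(0); to <- integer(0)
  repeat {
    i <- which.max(rem)
    k <- rem[i]
    if (k == 0L) break
    rem[i] <- 0L
    ord <- order(-rem, seq_len(n))
    targets <- setdiff(ord, i)[seq_len(k)]
    if (any(rem[targets] <= 0L)) {
      stop("degree sequence not graphical", call. = FALSE)  # guarded by checkGraphical
    }
    rem[targets] <- rem[targets] - 1L
    from <- c(from, rep.int(i, k)); to <- c(to, targets)
  }
  cbind(from, to, deparse.level = 0)
}

# Degree-preserving switching: repeatedly pick two edges (a,b), (c,d) and
# rewire to (a,d), (c,b) when that creates no self-loop or parallel edge.
edgeSwapRandomize <- function(el, n, seed, nswap = NULL) {
  m <- nrow(el)
  if (m < 2L) return(el)
  if (is.null(nswap)) nswap <- max(200L, 10L * m)
  withLocalSeed(seed, {
    adj <- matrix(FALSE, n, n)
    adj[el] <- TRUE
    adj[el[, c(2L, 1L), drop = FALSE]] <- TRUE
    pick1 <- sample.int(m, nswap, replace = TRUE)
    pick2 <- sample.int(m, nswap, replace = TRUE)
    flip <- stats::runif(nswap) < 0.5
    for (t in seq_len(nswap)) {
      i1 <- pick1[t]; i2 <- pick2[t]
      if (i1 == i2) next
      a <- el[i1, 1L]; b <- el[i1, 2L]
      c_ <- el[i2, 1L]; d_ <- el[i2, 2L]
      if (flip[t]) { tmp <- c_; c_ <- d_; d_ <- tmp }
      if (a == c_ || a == d_ || b == c_ || b == d_) next
      if (adj[a, d_] || adj[c_, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c_, d_] <- adj[d_, c_] <- FALSE
      adj[a, d_] <- adj[d_, a] <- TRUE
      adj[c_, b] <- adj[b, c_] <- TRUE
      el[i1, ] <- c(a, d_)
      el[i2, ] <- c(c_, b)
    }
    el
  })
}

#' Sample a synthetic network from a profile
#'
#' Seeded, bit-reproducible generation of undirected simple graphs. With an
#' explicit degree sequence the realized degrees equal it exactly; with a
#' block profile a planted-partition graph is drawn (planted labels stored in
#' the \code{block} vertex attribute); otherwise a heavy-tailed degree
#' sequence with an optional dominant hub is drawn and realized.
#'
#' @param profile a \code{\link{syntheticProfile}}.
#' @return An undirected simple igraph with nodes \code{v1..vn}.
#' @examples
#' g <- sampleGraphicalNetwork(syntheticProfile(degreeSequence = c(3, 1, 1, 1)))
#' sort(igraph::degree(g), decreasing = TRUE)  # the unique realization: a star
#' @export
sampleGraphicalNetwork <- function(profile) {
  stopifnot(inherits(profile, "SyntheticProfile"))
  seed <- profile$seed
  n <- profile$nNodes
  if (!is.null(profile$degreeSequence)) {
    g <- realizeDegreeSequence(as.integer(profile$degreeSequence), seed)
  } else if (!is.null(profile$blockSizes)) {
    k <- length(profile$blockSizes)
    pref <- matrix(profile$pOut, k, k)
    diag(pref) <- profile$pIn
    g <- withLocalSeed(seed,
      igraph::sample_sbm(n, pref.matrix = pref, block.sizes = profile$blockSizes))
    igraph::V(g)$block <- rep(seq_len(k), profile$blockSizes)
  } else {
    degs <- withLocalSeed(seed,
      drawHeavyTailedDegrees(n, profile$powerlawExponent, profile$hubDegree))
    g <- realizeDegreeSequence(degs, seed)
  }
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  asPPIGraph(g)
}

# Heavy-tailed degrees: a Zipf-like ranked profile d_r ~ r^(-1/(alpha-1)),
# optionally headed by a fixed dominant hub, rescaled to an exact (even)
# target sum with all non-hub degrees clipped to [1, cap]. Node-to-degree
# assignment is randomized by the caller's seed via the realization step, so
# the draw itself is deterministic given its arguments.
drawHeavyTailedDegrees <- function(n, alpha, hubDegree = NULL, targetSum = NULL) {
  m <- if (is.null(hubDegree)) n else n - 1L
  cap <- if (is.null(hubDegree)) n - 1L else max(1L, as.integer(hubDegree) - 1L)
  base <- seq_len(m)^(-1 / (alpha - 1))
  if (is.null(targetSum)) {
    # free-sum mode: scale so the median degree is ~2
    scale <- 2 / stats::median(base)
    d <- pmax(1L, pmin(cap, as.integer(round(scale * base))))
    if ((sum(d) + if (is.null(hubDegree)) 0L else as.integer(hubDegree)) %% 2L != 0L) {
      d[m] <- d[m] + 1L
    }
  } else {
    rest <- as.integer(targetSum) - if (is.null(hubDegree)) 0L else as.integer(hubDegree)
    if (rest < m || rest > m * cap) {
      stop("requested edge count is unreachable for this node count", call. = FALSE)
    }
    # bracket the multiplier so the clipped profile hits the exact sum
    f <- function(s) sum(pmax(1L, pmin(cap, as.integer(round(s * base))))) - rest
    lo <- 1e-6; hi <- 2 * cap
    while (f(hi) < 0) hi <- hi * 2
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) <= 0) lo <- mid else hi <- mid
    }
    d <- pmax(1L, pmin(cap, as.integer(round(lo * base))))
    resid <- rest - sum(d)
    j <- 1L
    while (resid != 0L) {
      step <- sign(resid)
      i <- ((j - 1L) %% m) + 1L
      if (d[i] + step >= 1L && d[i] + step <= cap) {
        d[i] <- d[i] + step
        resid <- resid - step
      }
      j <- j + 1L
    }
  }
  d <- if (is.null(hubDegree)) d else c(as.integer(hubDegree), d)
  repairGraphical(d, n)
}

# Nudge a fixed-sum sequence toward graphicality (move mass from the largest
# non-hub degrees to the smallest ones; converges toward regularity).
repairGraphical <- function(d, n) {
  for (it in seq_len(10L * n)) {
    ok <- tryCatch({ checkGraphical(d); TRUE }, error = function(e) FALSE)
    if (ok) return(as.integer(d))
    i <- which.max(replace(d, which.max(d), -1L))  # second-largest
    j <- which.min(d)
    if (d[i] <= d[j] + 1L) i <- which.max(d)
    d[i] <- d[i] - 1L
    d[j] <- d[j] + 1L
  }
  stop("could not repair degree sequence to a graphical one", call. = FALSE)
}

#' Summary features of the curated per-organism UPR networks
#'
#' The published summary of the twelve curated unfolded-protein-response
#' interactomes: barycenter protein, node count, directed record count (2M),
#' density, diameter, average degree/closeness/betweenness/clustering,
#' modularity, community count, plus average path length, efficiency and the
#' mean Generalized Hamming Distance to the organism's configuration models
#' (path length and efficiency are unavailable for \emph{Arabidopsis
#' thaliana}). These summary rows are the inputs that
#' \code{\link{emulateOrganism}} and the cross-organism correlation analyses
#' work from.
#'
#' @return A data.frame with one row per organism.
#' @export
organismTable <- function() {
  data.frame(
    organism = c("Homo sapiens", "Rattus norvegicus", "Mus musculus",
                 "Macaca fascicularis", "Bos taurus", "Oryctologus cuniculis",
                 "Gallus gallus", "Danio rerio", "Drosophila melanogaster",
                 "Caenorhabditis elegans", "Saccharomyces cerevisiae",
                 "Arabidopsis thaliana"),
    barycenter = c("HSPA5", "Hspa5", "Hspa5", "HSPA5", "HSPA5", "HSPA5",
                   "HSPA5", "hspa5", "Hsc70-3", "hsp-90", "KAR2", "BIP2; BIP3"),
    nNodes = c(216L, 210L, 231L, 186L, 205L, 174L, 179L, 214L, 57L, 109L, 150L, 62L),
    nRecords = c(5286L, 3862L, 4900L, 2468L, 3292L, 2598L, 2048L, 3240L,
                 760L, 1212L, 2834L, 1188L),
    density = c(0.114, 0.088, 0.092, 0.072, 0.079, 0.086, 0.064, 0.071,
                0.238, 0.103, 0.127, 0.314),
    diameter = c(7L, 6L, 6L, 6L, 8L, 6L, 8L, 8L, 5L, 7L, 6L, 5L),
    avgDegree = c(25, 18, 21, 13, 16, 15, 11, 15, 14, 11, 19, 19),
    avgCloseness = c(0.0020, 0.0020, 0.0018, 0.0020, 0.0019, 0.0023,
                     0.0020, 0.0018, 0.0089, 0.0034, 0.0028, 0.0092),
    avgBetweenness = c(145.5, 161.2, 170.7, 160.5, 172.6, 134.7, 173.5,
                       181.3, 29.9, 98.9, 108.0, 25.6),
    avgClustering = c(0.522, 0.496, 0.538, 0.437, 0.447, 0.464, 0.395,
                      0.413, 0.560, 0.594, 0.607, 0.680),
    modularity = c(0.311, 0.374, 0.354, 0.422, 0.374, 0.367, 0.385, 0.375,
                   0.324, 0.450, 0.352, 0.245),
    nCommunities = c(5L, 6L, 6L, 7L, 6L, 5L, 7L, 6L, 3L, 6L, 6L, 3L),
    avgPathLength = c(2.354, 2.543, 2.485, 2.735, 2.693, 2.557, 2.949,
                      2.702, 2.068, 2.832, 2.450, NA),
    efficiency = c(0.488, 0.638, 0.681, 0.446, 0.586, 0.593, 0.504, 0.551,
                   0.571, 0.429, 0.478, NA),
    avgGHD = c(0.057, 0.060, 0.051, 0.076, 0.064, 0.076, 0.071, 0.059,
               0.219, 0.135, 0.095, 0.198),
    stringsAsFactors = FALSE
  )
}

#' Emulate the size and shape of a curated organism network
#'
#' Generates a synthetic stand-in for one of the twelve curated UPR
#' interactomes: exact node and undirected edge counts (hence the exact
#' published density), a single dominant hub labeled with the organism's
#' barycenter protein (the BiP/HSPA5 role), and a heavy-tailed remaining
#' degree sequence. Only these coarse features are emulated; the true
#' database topology is not reproduced.
#'
#' @param name organism name as listed in \code{\link{organismTable}}.
#' @param seed integer RNG seed; the same seed yields an identical graph.
#' @return An undirected simple igraph with \code{igraph::vcount} and
#'   \code{igraph::ecount} matching the published counts.
#' @examples
#' g <- emulateOrganism("Drosophila melanogaster", seed = 7)
#' c(igraph::vcount(g), igraph::ecount(g))  # 57, 380
#' @export
emulateOrganism <- function(name, seed = 1L) {
  tab <- organismTable()
  row <- tab[tab$organism == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown organism '%s'; see organismTable()$organism", name),
         call. = FALSE)
  }
  n <- row$nNodes
  m2 <- row$nRecords  # = 2M
  # dominant hub: BiP interacts with most of the curated network
  hub <- min(n - 1L, max(as.integer(round(0.6 * (n - 1))), as.integer(ceiling(m2 / n))))
  degs <- withLocalSeed(seed,
    drawHeavyTailedDegrees(n, alpha = 2.1, hubDegree = hub, targetSum = m2))
  g <- realizeDegreeSequence(degs, seed)
  nm <- paste0("P", formatC(seq_len(n), width = 3, flag = "0"))
  nm[which.max(igraph::degree(g))] <- row$barycenter
  igraph::V(g)$name <- nm
  asPPIGraph(g)
}
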