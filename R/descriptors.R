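#' Per-node network descriptors
#'
#' Computes, for every node: degree; closeness centrality C(x) =
#' (sum_y d(x,y))^-1 with the sum restricted to nodes reachable from x (on a
#' disconnected graph each node is scored within its own component; isolated
#' nodes get 0); betweenness centrality as raw shortest-path pair counts
#' (unnormalized); local clustering coefficient (0 for degree < 2); and
#' eccentricity within the node's component.
#'
#' @param net an undirected simple igraph.
#' @return A \code{\link{MetricTable}} with the per-node table filled and
#'   network aggregates empty.
#' @examples
#' tab <- nodeMetrics(canonicalGraph("star", 5))
#' nodeTable(tab)[1, ]  # center: closeness 0.25, betweenness 6, clustering 0
#' @export
nodeMetrics <- function(net) {
  net <- asPPIGraph(net)
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  d <- igraph::distances(net)
  reach_sum <- apply(d, 1, function(r) sum(r[is.finite(r) & r > 0]))
  closeness <- ifelse(reach_sum > 0, 1 / reach_sum, 0)
  clustering <- igraph::transitivity(net, type = "local", isolates = "zero")
  ecc <- apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) max(f) else 0
  })
  tab <- data.frame(
    node = nm,
    degree = as.numeric(igraph::degree(net)),
    closeness = as.numeric(closeness),
    betweenness = as.numeric(igraph::betweenness(net, directed = FALSE)),
    clustering = as.numeric(clustering),
    eccentricity = as.numeric(ecc),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  new("MetricTable", nodeTable = tab, networkStats = list(),
      nNodes = as.integer(n), nEdges = as.integer(igraph::ecount(net)))
}

#' Network-level aggregates of the descriptor suite
#'
#' Fills the network-level statistics of a \code{\link{MetricTable}}:
#' density 2M/(N(N-1)); diameter (maximum eccentricity); barycenter (the node
#' of minimum eccentricity, ties broken by smaller total distance then
#' lexicographic identifier); arithmetic means of the per-node metrics;
#' average shortest path length l = (N(N-1))^-1 sum_{i != j} d_ij; efficiency
#' E = (N(N-1))^-1 sum_{i != j} 1/d_ij; and Louvain modularity/community
#' count. On a disconnected network the distance-based aggregates (diameter,
#' barycenter, l, E) are computed on the largest connected component, with a
#' warning.
#'
#' @param net the network the table was computed from.
#' @param table the \code{\link{MetricTable}} from \code{\link{nodeMetrics}}.
#' @param communities logical, also run \code{\link{detectCommunities}}.
#' @param seed RNG seed for community detection.
#' @return The \code{MetricTable} with \code{networkStats} filled.
#' @examples
#' g <- canonicalGraph("path", 3)
#' st <- networkStats(networkAggregates(g, nodeMetrics(g)))
#' c(st$avgPathLength, st$efficiency)  # 8/6, 5/6
#' @export
networkAggregates <- function(net, table, communities = TRUE, seed = 1L) {
  net <- asPPIGraph(net)
  stopifnot(is(table, "MetricTable"), igraph::vcount(net) == table@nNodes)
  n <- table@nNodes
  m <- table@nEdges
  tab <- table@nodeTable

  comp <- igraph::components(net)
  sub <- net
  if (comp$no > 1L) {
    warning("disconnected network: distance-based aggregates computed on the largest connected component")
    keep <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(net, keep)
  }
  ns <- igraph::vcount(sub)
  dsub <- igraph::distances(sub)
  off <- ns >= 2
  l <- if (off) sum(dsub[dsub > 0]) / (ns * (ns - 1)) else NA_real_
  eff <- if (off) sum(1 / dsub[dsub > 0]) / (ns * (ns - 1)) else 0
  ecc_sub <- apply(dsub, 1, max)
  diam <- if (ns >= 1) max(ecc_sub) else 0
  # barycenter: min eccentricity, ties by total distance then identifier
  tot <- rowSums(dsub)
  cand <- order(ecc_sub, tot, igraph::V(sub)$name)[1]
  bary <- igraph::V(sub)$name[cand]

  stats <- list(
    density = if (n >= 2) 2 * m / (n * (n - 1)) else 0,
    diameter = diam,
    barycenter = bary,
    avgDegree = mean(tab$degree),
    avgCloseness = mean(tab$closeness),
    avgBetweenness = mean(tab$betweenness),
    avgClustering = mean(tab$clustering),
    avgPathLength = l,
    efficiency = eff
  )
  if (communities) {
    cm <- detectCommunities(net, seed = seed)
    stats$modularity <- cm$modularity
    stats$nCommunities <- cm$nCommunities
  }
  table@networkStats <- stats
  validObject(table)
  table
}

#' Size-normalized descriptor variants
#'
#' Adds the normalized per-node columns that make networks of different size
#' comparable: \code{normDegree} = k/(N-1), \code{normCloseness} =
#' (N-1) * C(x), and min-max normalized betweenness
#' (B(x) - min B)/(max B - min B), defined as 0 for all nodes when the
#' betweenness values are all equal.
#'
#' @param table a \code{\link{MetricTable}}.
#' @param nNodes network size N used for normalization (defaults to the
#'   table's own N); must be >= 2.
#' @return The \code{MetricTable} with normalized columns filled.
#' @export
normalizeMetrics <- function(table, nNodes = table@nNodes) {
  stopifnot(is(table, "MetricTable"))
  if (!isCount(nNodes) || nNodes < 2) {
    stop("normalization requires N >= 2", call. = FALSE)
  }
  tab <- table@nodeTable
  tab$normDegree <- tab$degree / (nNodes - 1)
  tab$normCloseness <- (nNodes - 1) * tab$closeness
  rng <- range(tab$betweenness)
  tab$normBetweenness <- if (diff(rng) > 0) {
    (tab$betweenness - rng[1]) / diff(rng)
  } else {
    rep(0, nrow(tab))
  }
  table@nodeTable <- tab
  validObject(table)
  table
}

#' Louvain community detection
#'
#' Runs the Louvain algorithm (resolution 1) under a fixed seed and returns
#' the partition together with its Newman-Girvan modularity. An edgeless
#' network yields one singleton community per node with Q = 0.
#'
#' @param net an undirected simple igraph.
#' @param seed integer seed controlling the (stochastic) node traversal.
#' @return list with \code{membership} (named integer vector),
#'   \code{modularity} and \code{nCommunities}.
#' @examples
#' cm <- detectCommunities(canonicalGraph("two_clique_bridge", 10), seed = 1)
#' cm$nCommunities  # 2, one per clique block
#' @export
detectCommunities <- function(net, seed = 1L) {
  net <- asPPIGraph(net)
  n <- igraph::vcount(net)
  if (igraph::ecount(net) == 0L) {
    return(list(membership = setNames(seq_len(n), igraph::V(net)$name),
                modularity = 0, nCommunities = n))
  }
  cl <- withLocalSeed(seed, igraph::cluster_louvain(net, resolution = 1))
  memb <- igraph::membership(cl)
  list(membership = memb,
       modularity = igraph::modularity(net, memb),
       nCommunities = length(unique(memb)))
}

#' One summary row per network, in the curated-table layout
#'
#' Serializes network-level descriptor aggregates into the column layout used
#' by the published per-organism summary: barycenter, node count, directed
#' record count (2M), density, diameter, average degree/closeness/
#' betweenness/clustering, modularity and community count.
#'
#' @param tables named list of \code{\link{MetricTable}} objects with
#'   aggregates filled.
#' @param file optional path; when given the table is written as TSV.
#' @return data.frame with one row per network, invisibly when writing.
#' @export
metricReport <- function(tables, file = NULL) {
  stopifnot(length(tables) >= 1)
  rows <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    st <- tb@networkStats
    if (!length(st)) stop(sprintf("network '%s' has no aggregates", nm), call. = FALSE)
    data.frame(network = nm, barycenter = st$barycenter, nNodes = tb@nNodes,
               nRecords = 2L * tb@nEdges, density = st$density,
               diameter = st$diameter, avgDegree = st$avgDegree,
               avgCloseness = st$avgCloseness, avgBetweenness = st$avgBetweenness,
               avgClustering = st$avgClustering,
               modularity = if (is.null(st$modularity)) NA_real_ else st$modularity,
               nCommunities = if (is.null(st$nCommunities)) NA_integer_ else st$nCommunities,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
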