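# --- internal machinery -----------------------------------------------------

# Directed edge matrix (from, to) in vertex indices; undirected edges are
# treated as two opposed directed edges.
directedEdgeMatrix <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  if (!igraph::is_directed(g) && nrow(el)) {
    el <- rbind(el, el[, c(2L, 1L), drop = FALSE])
  }
  el
}

# Bipartite out/in doubling: vertices 1..n are out-copies, n+1..2n in-copies;
# a directed edge u -> v becomes (u+, v-).
bipartiteDoubling <- function(el, n) {
  g <- igraph::make_empty_graph(2L * n, directed = FALSE)
  if (nrow(el)) {
    g <- igraph::add_edges(g, as.vector(rbind(el[, 1L], n + el[, 2L])))
  }
  igraph::V(g)$type <- c(rep(FALSE, n), rep(TRUE, n))
  g
}

# Maximum matching size in the doubling after removing the in-copies of
# `excludeIn` (candidate driver nodes receive inputs instead of matches).
matchingSizeExcluding <- function(bip, n, excludeIn = integer(0)) {
  if (length(excludeIn)) {
    bip <- igraph::delete_vertices(bip, n + excludeIn)
  }
  igraph::max_bipartite_match(bip)$matching_size
}

# Lin's structural-controllability conditions for dedicated inputs at S:
# (i) every node reachable from S along directed edges (accessibility),
# (ii) a matching saturating all in-copies outside S (no dilation).
isAccessible <- function(gdir, S) {
  n <- igraph::vcount(gdir)
  if (!length(S)) return(n == 0L)
  reach <- unique(unlist(lapply(
    igraph::ego(gdir, order = n, nodes = S, mode = "out"), as.integer)))
  length(reach) == n
}

# Enumerate driver sets of exact size k (ascending-index combinations with
# matching-deficiency pruning); returns up to `cap` sets.
findDriverSets <- function(gdir, bip, n, k, cap) {
  target <- n - k
  el <- directedEdgeMatrix(gdir)
  indeg <- if (nrow(el)) tabulate(el[, 2L], n) else integer(n)
  forced <- which(indeg == 0L)
  sets <- list()
  truncated <- FALSE
  if (length(forced) > k) {
    return(list(sets = sets, truncated = FALSE))
  }
  free <- setdiff(seq_len(n), forced)

  recurse <- function(S, nextFree) {
    if (truncated) return()
    j <- length(S)
    mm <- matchingSizeExcluding(bip, n, S)
    deficiency <- (n - j) - mm
    if (deficiency > k - j) return()
    if (j == k) {
      if (deficiency == 0L && isAccessible(gdir, S)) {
        if (length(sets) < cap) {
          sets[[length(sets) + 1L]] <<- sort(S)
        } else {
          truncated <<- TRUE
        }
      }
      return()
    }
    if (nextFree > length(free)) return()
    if (length(free) - nextFree + 1L < k - j) return()
    for (idx in nextFree:length(free)) {
      recurse(c(S, free[idx]), idx + 1L)
      if (truncated) return()
      # after trying with free[idx], continue without it (next loop step)
    }
  }
  recurse(forced, 1L)
  list(sets = sets, truncated = truncated)
}

# Per-weak-component Liu lower bound: sum over components of
# max(n_c - matching_c, 1).
liuLowerBound <- function(gdir, bip, n) {
  comps <- igraph::components(gdir, mode = "weak")
  total <- 0L
  for (c_id in seq_len(comps$no)) {
    verts <- which(comps$membership == c_id)
    drop_in <- setdiff(seq_len(n), verts)
    sub <- igraph::delete_vertices(bip, c(setdiff(seq_len(n), verts), n + drop_in))
    m_c <- igraph::max_bipartite_match(sub)$matching_size
    total <- total + max(length(verts) - m_c, 1L)
  }
  as.integer(total)
}

# --- exported operations ----------------------------------------------------

#' Build the linear system attached to a network
#'
#' Assembles the state matrix A (nonzero a_ij exactly where node j influences
#' node i; undirected edges act in both directions) and the control matrix B
#' whose columns are the canonical basis vectors of the chosen input nodes,
#' for the dynamics dx/dt = A x + B u. Binary mode sets unit weights; generic
#' mode draws seeded random weights (uniform magnitude in [0.5, 1.5], random
#' sign, independently per directed influence), the standard device for
#' testing structural rank conditions without non-generic cancellations.
#'
#' @param net an igraph (directed or undirected, simple).
#' @param inputNodes character vector of distinct node names receiving
#'   inputs; non-empty.
#' @param weightMode "generic" (default) or "binary".
#' @param seed RNG seed for generic weights.
#' @return A \code{\link{ControlSystem}}.
#' @export
buildControlSystem <- function(net, inputNodes,
                               weightMode = c("generic", "binary"), seed = 1L) {
  net <- asAnyGraph(net)
  weightMode <- match.arg(weightMode)
  nm <- igraph::V(net)$name
  n <- length(nm)
  if (length(inputNodes) < 1) stop("at least one input node is required", call. = FALSE)
  if (anyDuplicated(inputNodes)) stop("duplicate input node requested", call. = FALSE)
  idx <- match(inputNodes, nm)
  if (anyNA(idx)) {
    stop(sprintf("unknown input node(s): %s",
                 paste(inputNodes[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  el <- directedEdgeMatrix(net)
  A <- matrix(0, n, n, dimnames = list(nm, nm))
  if (nrow(el)) {
    w <- if (weightMode == "binary") {
      rep(1, nrow(el))
    } else {
      withLocalSeed(seed,
        stats::runif(nrow(el), 0.5, 1.5) * sample(c(-1, 1), nrow(el), replace = TRUE))
    }
    A[cbind(el[, 2L], el[, 1L])] <- w  # a_ij != 0 iff j -> i
  }
  B <- matrix(0, n, length(idx), dimnames = list(nm, inputNodes))
  B[cbind(idx, seq_along(idx))] <- 1
  new("ControlSystem", A = A, B = B, inputs = as.character(inputNodes),
      weightMode = weightMode)
}

#' Kalman rank condition
#'
#' Tests whether the controllability matrix C = (B, AB, A^2 B, ...,
#' A^{N-1} B) has full rank N. Rank is accumulated block-by-block with
#' re-orthogonalized Gram-Schmidt; each Krylov block is rescaled before
#' orthogonalization (a per-block positive rescaling is a column scaling and
#' leaves the rank unchanged), which keeps A^k B in floating-point range for
#' arbitrarily large k. The Krylov recursion stops early once a block adds no
#' new direction, since later blocks then cannot either.
#'
#' @param sys a \code{\link{ControlSystem}}.
#' @param tol numeric tolerance for treating a residual direction as zero
#'   (relative to unit-normalized columns).
#' @return TRUE iff rank(C) = N.
#' @examples
#' g <- igraph::make_graph(c("a", "b"), directed = TRUE)
#' kalmanControllable(buildControlSystem(g, "a"))  # TRUE: chain from input
#' kalmanControllable(buildControlSystem(g, "b"))  # FALSE: a is unreachable
#' @export
kalmanControllable <- function(sys, tol = 1e-8) {
  stopifnot(is(sys, "ControlSystem"))
  A <- sys@A
  B <- sys@B
  n <- nrow(A)
  s <- max(abs(A))
  if (s > 0) A <- A / s
  Q <- matrix(0, n, 0)
  rank <- 0L
  block <- B
  for (k in seq_len(n)) {
    bmax <- max(abs(block))
    blk <- if (bmax > 0) block / bmax else block
    added <- FALSE
    for (j in seq_len(ncol(blk))) {
      v <- blk[, j]
      nv0 <- sqrt(sum(v^2))
      if (nv0 <= tol) next
      v <- v / nv0
      for (pass in 1:2) {
        if (rank > 0) v <- v - Q %*% crossprod(Q, v)
      }
      nv <- sqrt(sum(v^2))
      if (nv > tol) {
        Q <- cbind(Q, v / nv)
        rank <- rank + 1L
        added <- TRUE
        if (rank == n) return(TRUE)
      }
    }
    if (!added) break  # Krylov subspace is A-invariant from here on
    block <- A %*% block
  }
  rank == n
}

#' Explicit controllability matrix
#'
#' Assembles C = (B, AB, A^2 B, ..., A^{N-1} B) as a dense matrix. Intended
#' for inspection on small systems; entries of A^k grow geometrically, so
#' \code{scale = TRUE} (default) rescales each block to unit maximum — a
#' positive column scaling that preserves the rank.
#'
#' @param sys a \code{\link{ControlSystem}}.
#' @param scale logical, rescale each Krylov block.
#' @return N x (N*M) numeric matrix.
#' @export
controllabilityMatrix <- function(sys, scale = TRUE) {
  stopifnot(is(sys, "ControlSystem"))
  A <- sys@A
  n <- nrow(A)
  if (scale && max(abs(A)) > 0) A <- A / max(abs(A))
  blocks <- vector("list", n)
  blk <- sys@B
  for (k in seq_len(n)) {
    if (scale && max(abs(blk)) > 0) blk <- blk / max(abs(blk))
    blocks[[k]] <- blk
    blk <- A %*% blk
  }
  do.call(cbind, blocks)
}

#' Minimum driver nodes of a network
#'
#' Identifies the smallest set of driver nodes — nodes receiving independent
#' external input signals — that renders the network structurally
#' controllable. Following the maximum-matching approach, the network is
#' bidirectionalized (for undirected input) into its bipartite out/in
#' representation; unmatched in-copies mark the driver nodes, and every
#' perfectly matched component still needs one driver, so the count is
#' N_D = sum over components of max(n_c - matching_c, 1). The returned set is
#' additionally required to satisfy both structural conditions
#' (accessibility and dilation-freeness); for directed inputs where no
#' unmatched set of the matching bound's size satisfies them, the search
#' widens until one does, so the reported N_D is always achievable with
#' dedicated inputs.
#'
#' @param net an igraph (directed or undirected, simple).
#' @param verify logical; confirm the first set by the Kalman rank condition
#'   with generic weights.
#' @param seed RNG seed for verification weights.
#' @return A \code{\link{DriverResult}} with one concrete minimum set.
#' @examples
#' driverCount(minimumDriverNodes(canonicalGraph("star", 4)))  # 2
#' @export
minimumDriverNodes <- function(net, verify = TRUE, seed = 1L) {
  res <- driverSearch(net, cap = 1L)
  verified <- if (verify) {
    verifyDriverSet(net, res$sets[[1L]], seed = seed)
  } else {
    NA
  }
  new("DriverResult", driverCount = res$k, driverSets = res$sets,
      matchingSize = res$matchingSize, verified = verified,
      truncated = FALSE)
}

driverSearch <- function(net, cap) {
  net <- asAnyGraph(net)
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  gdir <- if (igraph::is_directed(net)) net else igraph::as_directed(net, mode = "mutual")
  el <- directedEdgeMatrix(gdir)
  bip <- bipartiteDoubling(el, n)
  mm <- matchingSizeExcluding(bip, n)
  k0 <- liuLowerBound(gdir, bip, n)
  for (k in seq(k0, n)) {
    found <- findDriverSets(gdir, bip, n, k, cap)
    if (length(found$sets)) {
      return(list(k = as.integer(k),
                  sets = lapply(found$sets, function(s) nm[s]),
                  truncated = found$truncated,
                  matchingSize = as.integer(mm)))
    }
  }
  stop("driver search failed to terminate", call. = FALSE)  # unreachable: S = V always valid
}

#' Enumerate alternative minimum driver sets
#'
#' Lists the distinct minimum driver-node sets (deduplicated node sets, not
#' matchings) up to a cap, by exhaustively searching size-N_D node subsets
#' with matching-deficiency pruning and validating each against both
#' structural-controllability conditions.
#'
#' @param net an igraph (directed or undirected, simple).
#' @param cap maximum number of sets returned (default 64); must be >= 1.
#' @param verify logical; Kalman-verify the first set.
#' @param seed RNG seed for verification weights.
#' @return A \code{\link{DriverResult}}; \code{@truncated} flags a hit cap.
#' @examples
#' g <- igraph::make_graph(c("a", "b"), directed = FALSE)
#' driverSets(enumerateDriverSets(g))  # {a} and {b}
#' @export
enumerateDriverSets <- function(net, cap = 64L, verify = TRUE, seed = 1L) {
  if (!isCount(cap) || cap < 1) stop("cap must be a positive count", call. = FALSE)
  res <- driverSearch(net, cap = as.integer(cap))
  verified <- if (verify) verifyDriverSet(net, res$sets[[1L]], seed = seed) else NA
  new("DriverResult", driverCount = res$k, driverSets = res$sets,
      matchingSize = res$matchingSize, verified = verified,
      truncated = res$truncated)
}

#' Verify a candidate driver set by the Kalman rank condition
#'
#' Builds the generic-weight system with inputs on the candidate set and
#' checks rank(C) = N. A failed check is repeated with a second seed before
#' being reported, to guard against a non-generic draw of weights.
#'
#' @param net an igraph (directed or undirected, simple).
#' @param candidate character vector of node names.
#' @param seed RNG seed for the generic weights.
#' @return TRUE iff the candidate set renders the network controllable.
#' @export
verifyDriverSet <- function(net, candidate, seed = 1L) {
  net <- asAnyGraph(net)
  stopifnot(all(candidate %in% igraph::V(net)$name))
  ok <- kalmanControllable(buildControlSystem(net, candidate,
                                              weightMode = "generic", seed = seed))
  if (!ok) {
    ok <- kalmanControllable(buildControlSystem(net, candidate,
                                                weightMode = "generic",
                                                seed = seed + 1L))
  }
  ok
}
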