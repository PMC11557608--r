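#' MetricTable: per-node descriptors and network aggregates
#'
#' Container for the descriptor suite of one network: a per-node table
#' (degree, closeness, betweenness, clustering coefficient, eccentricity and
#' their size-normalized variants) plus network-level aggregates (density,
#' diameter, barycenter, averages, modularity, community count, average path
#' length, efficiency).
#'
#' @slot nodeTable data.frame, one row per node.
#' @slot networkStats named list of network-level aggregates (empty until
#'   \code{\link{networkAggregates}} is called).
#' @slot nNodes integer, number of nodes N.
#' @slot nEdges integer, number of undirected edges M.
#'
#' @seealso \code{\link{nodeMetrics}}, \code{\link{networkAggregates}},
#'   \code{\link{normalizeMetrics}}
#' @export
setClass("MetricTable",
  representation(
    nodeTable = "data.frame",
    networkStats = "list",
    nNodes = "integer",
    nEdges = "integer"
  )
)

setValidity("MetricTable", function(object) {
  tab <- object@nodeTable
  msgs <- character()
  if (nrow(tab) != object@nNodes) {
    msgs <- c(msgs, "nodeTable must have one row per node")
  }
  if (nrow(tab) > 0) {
    if (any(tab$clustering < -1e-12 | tab$clustering > 1 + 1e-12, na.rm = TRUE)) {
      msgs <- c(msgs, "clustering coefficients must lie in [0,1]")
    }
    if ("normBetweenness" %in% names(tab)) {
      nb <- tab$normBetweenness
      if (any(nb < -1e-12 | nb > 1 + 1e-12, na.rm = TRUE)) {
        msgs <- c(msgs, "normalized betweenness must lie in [0,1]")
      }
    }
  }
  d <- object@networkStats$density
  if (!is.null(d) && (d < -1e-12 || d > 1 + 1e-12)) {
    msgs <- c(msgs, "density must lie in [0,1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' NullEnsemble: a native network with configuration-model replicates
#'
#' Holds a native network together with R degree-preserving randomizations
#' (configuration models) and the replicate-level metric aggregates used for
#' z-scores.
#'
#' @slot native igraph, the native network.
#' @slot replicates list of igraph replicates, each with the native degree
#'   sequence exactly.
#' @slot ensembleSize integer, number of replicates R.
#' @slot aggregates data.frame with one row per replicate: average closeness,
#'   average betweenness, average clustering.
#' @seealso \code{\link{nullEnsemble}}, \code{\link{ensembleZScores}}
#' @export
setClass("NullEnsemble",
  representation(
    native = "ANY",
    replicates = "list",
    ensembleSize = "integer",
    aggregates = "data.frame"
  )
)

setValidity("NullEnsemble", function(object) {
  msgs <- character()
  if (length(object@replicates) != object@ensembleSize) {
    msgs <- c(msgs, "number of replicates must equal ensembleSize")
  }
  deg0 <- sort(igraph::degree(object@native))
  for (k in seq_along(object@replicates)) {
    rep_k <- object@replicates[[k]]
    if (!igraph::is_simple(rep_k)) {
      msgs <- c(msgs, sprintf("replicate %d is not a simple graph", k))
      break
    }
    if (!identical(sort(igraph::degree(rep_k)), deg0)) {
      msgs <- c(msgs, sprintf("replicate %d does not preserve the degree sequence", k))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' GHDResult: Generalized Hamming Distance between two networks
#'
#' @slot value numeric, the distance (non-negative in the default squared
#'   mode).
#' @slot nNodes integer, shared node-set size N.
#' @slot mode character, \code{"squared"} (default) or \code{"linear"}.
#' @seealso \code{\link{ghd}}
#' @export
setClass("GHDResult",
  representation(value = "numeric", nNodes = "integer", mode = "character")
)

#' AttackTrace: network degradation under sequential node removal
#'
#' @slot order character vector, the full removal order (a permutation of the
#'   node set).
#' @slot lccFraction numeric, G_i = n_i/N after each removal (n_i = size of
#'   the largest connected component; N the intact node count).
#' @slot deltaEfficiency numeric, (E - E_i)/E after each removal, with E the
#'   intact-network efficiency.
#' @slot strategy character, ranking metric used to build the order.
#' @slot direction character, "ascending" or "descending".
#' @slot nNodes integer, intact node count N.
#' @slot lcc0 numeric, LCC fraction of the intact network.
#' @slot efficiency0 numeric, efficiency E of the intact network.
#' @seealso \code{\link{runAttack}}, \code{\link{robustnessR}},
#'   \code{\link{detectJumps}}
#' @export
setClass("AttackTrace",
  representation(
    order = "character",
    lccFraction = "numeric",
    deltaEfficiency = "numeric",
    strategy = "character",
    direction = "character",
    nNodes = "integer",
    lcc0 = "numeric",
    efficiency0 = "numeric"
  )
)

setValidity("AttackTrace", function(object) {
  msgs <- character()
  n <- object@nNodes
  if (length(object@order) != n) {
    msgs <- c(msgs, "order must be a permutation of the full node set")
  }
  g <- object@lccFraction
  if (length(g) != n) msgs <- c(msgs, "lccFraction must have one value per removal")
  if (length(g) >= 2 && any(diff(g) > 1e-12)) {
    msgs <- c(msgs, "lccFraction must be non-increasing")
  }
  if (length(g) >= 1 && abs(g[length(g)]) > 1e-12) {
    msgs <- c(msgs, "lccFraction must end at 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' ControlSystem: linear time-invariant system built on a network
#'
#' State equation dx/dt = A x(t) + B u(t): A is the N x N state matrix whose
#' nonzero pattern is the (symmetrized) adjacency structure, B the N x M
#' control matrix of canonical basis columns, one per input node.
#'
#' @slot A numeric matrix, N x N state matrix.
#' @slot B numeric matrix, N x M control matrix.
#' @slot inputs character, input (driver) node identifiers.
#' @slot weightMode character, "binary" or "generic".
#' @seealso \code{\link{buildControlSystem}}, \code{\link{kalmanControllable}}
#' @export
setClass("ControlSystem",
  representation(
    A = "matrix",
    B = "matrix",
    inputs = "character",
    weightMode = "character"
  )
)

setValidity("ControlSystem", function(object) {
  msgs <- character()
  n <- nrow(object@A)
  if (ncol(object@A) != n) msgs <- c(msgs, "A must be square")
  if (nrow(object@B) != n) msgs <- c(msgs, "B must have N rows")
  if (ncol(object@B) > n) msgs <- c(msgs, "number of inputs M must satisfy M <= N")
  if (ncol(object@B) != length(object@inputs)) {
    msgs <- c(msgs, "one B column per input node")
  }
  # canonical basis columns, all distinct
  if (ncol(object@B) > 0) {
    ok <- all(colSums(object@B != 0) == 1L) && all(object@B %in% c(0, 1)) &&
      !anyDuplicated(apply(object@B != 0, 2, which))
    if (!ok) msgs <- c(msgs, "B columns must be distinct canonical basis vectors")
  }
  if (length(msgs)) msgs else TRUE
})

#' DriverResult: minimum driver nodes of a network
#'
#' @slot driverCount integer, minimum number of driver nodes N_D.
#' @slot driverSets list of character vectors, each a minimum driver set.
#' @slot matchingSize integer, size of a maximum matching in the bipartite
#'   out/in representation.
#' @slot verified logical, whether the first set passed the Kalman rank check
#'   with generic weights.
#' @slot truncated logical, whether enumeration stopped at the cap.
#' @seealso \code{\link{minimumDriverNodes}}, \code{\link{enumerateDriverSets}}
#' @export
setClass("DriverResult",
  representation(
    driverCount = "integer",
    driverSets = "list",
    matchingSize = "integer",
    verified = "logical",
    truncated = "logical"
  )
)

setValidity("DriverResult", function(object) {
  msgs <- character()
  if (object@driverCount < 1L) msgs <- c(msgs, "driverCount must be >= 1")
  if (length(object@driverSets) < 1L) {
    msgs <- c(msgs, "at least one concrete minimum set is required")
  }
  sizes <- lengths(object@driverSets)
  if (length(sizes) && any(sizes != object@driverCount)) {
    msgs <- c(msgs, "every driver set must have size driverCount")
  }
  if (length(msgs)) msgs else TRUE
})
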