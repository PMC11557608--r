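#' @name accessors
#' @title Accessors for UPRnet result objects
#' @description Slot access for the S4 result containers. Use these rather
#'   than \code{@}.
#' @param x a result object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))
#' @rdname accessors
#' @export
setMethod("nodeTable", "MetricTable", function(x) x@nodeTable)

#' @rdname accessors
#' @export
setGeneric("networkStats", function(x) standardGeneric("networkStats"))
#' @rdname accessors
#' @export
setMethod("networkStats", "MetricTable", function(x) x@networkStats)

#' @rdname accessors
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))
#' @rdname accessors
#' @export
setMethod("replicates", "NullEnsemble", function(x) x@replicates)

#' @rdname accessors
#' @export
setGeneric("nativeNetwork", function(x) standardGeneric("nativeNetwork"))
#' @rdname accessors
#' @export
setMethod("nativeNetwork", "NullEnsemble", function(x) x@native)

#' @rdname accessors
#' @export
setGeneric("ensembleAggregates", function(x) standardGeneric("ensembleAggregates"))
#' @rdname accessors
#' @export
setMethod("ensembleAggregates", "NullEnsemble", function(x) x@aggregates)

#' @rdname accessors
#' @export
setGeneric("ghdValue", function(x) standardGeneric("ghdValue"))
#' @rdname accessors
#' @export
setMethod("ghdValue", "GHDResult", function(x) x@value)

#' @rdname accessors
#' @export
setGeneric("attackOrderUsed", function(x) standardGeneric("attackOrderUsed"))
#' @rdname accessors
#' @export
setMethod("attackOrderUsed", "AttackTrace", function(x) x@order)

#' @rdname accessors
#' @export
setGeneric("lccFraction", function(x) standardGeneric("lccFraction"))
#' @rdname accessors
#' @export
setMethod("lccFraction", "AttackTrace", function(x) x@lccFraction)

#' @rdname accessors
#' @export
setGeneric("deltaEfficiency", function(x) standardGeneric("deltaEfficiency"))
#' @rdname accessors
#' @export
setMethod("deltaEfficiency", "AttackTrace", function(x) x@deltaEfficiency)

#' @rdname accessors
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))
#' @rdname accessors
#' @export
setMethod("stateMatrix", "ControlSystem", function(x) x@A)

#' @rdname accessors
#' @export
setGeneric("controlMatrix", function(x) standardGeneric("controlMatrix"))
#' @rdname accessors
#' @export
setMethod("controlMatrix", "ControlSystem", function(x) x@B)

#' @rdname accessors
#' @export
setGeneric("driverCount", function(x) standardGeneric("driverCount"))
#' @rdname accessors
#' @export
setMethod("driverCount", "DriverResult", function(x) x@driverCount)

#' @rdname accessors
#' @export
setGeneric("driverSets", function(x) standardGeneric("driverSets"))
#' @rdname accessors
#' @export
setMethod("driverSets", "DriverResult", function(x) x@driverSets)

#' @rdname accessors
#' @export
setGeneric("matchingSize", function(x) standardGeneric("matchingSize"))
#' @rdname accessors
#' @export
setMethod("matchingSize", "DriverResult", function(x) x@matchingSize)

setMethod("show", "MetricTable", function(object) {
  cat(sprintf("MetricTable: %d nodes, %d edges\n", object@nNodes, object@nEdges))
  st <- object@networkStats
  if (length(st)) {
    cat(sprintf("  density %.3f, diameter %s, barycenter %s\n",
                st$density, format(st$diameter), st$barycenter))
    cat(sprintf("  <k> %.1f, <C> %.4f, <B> %.1f, <CC> %.3f\n",
                st$avgDegree, st$avgCloseness, st$avgBetweenness, st$avgClustering))
    if (!is.null(st$modularity)) {
      cat(sprintf("  modularity %.3f in %d communities\n",
                  st$modularity, st$nCommunities))
    }
  } else {
    cat("  (network aggregates not yet computed)\n")
  }
  invisible(NULL)
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble: %d configuration-model replicates of a %d-node network\n",
              object@ensembleSize, igraph::vcount(object@native)))
  invisible(NULL)
})

setMethod("show", "GHDResult", function(object) {
  cat(sprintf("Generalized Hamming Distance (%s mode): %.6g over N = %d nodes\n",
              object@mode, object@value, object@nNodes))
  invisible(NULL)
})

setMethod("show", "AttackTrace", function(object) {
  cat(sprintf("AttackTrace: %s attack (%s), %d removals\n",
              object@strategy, object@direction, object@nNodes))
  cat(sprintf("  robustness R = %.4f\n", mean(object@lccFraction)))
  invisible(NULL)
})

setMethod("show", "ControlSystem", function(object) {
  cat(sprintf("ControlSystem: N = %d states, M = %d inputs (%s weights)\n",
              nrow(object@A), ncol(object@B), object@weightMode))
  invisible(NULL)
})

setMethod("show", "DriverResult", function(object) {
  cat(sprintf("DriverResult: N_D = %d driver node(s), %d minimum set(s)%s\n",
              object@driverCount, length(object@driverSets),
              if (object@truncated) " (truncated)" else ""))
  cat(sprintf("  maximum matching size %d; Kalman-verified: %s\n",
              object@matchingSize, object@verified))
  if (length(object@driverSets)) {
    cat("  first set:", paste(object@driverSets[[1]], collapse = ", "), "\n")
  }
  invisible(NULL)
})
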