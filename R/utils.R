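#' @import methods
#' @importFrom stats cor.test dist hclust kruskal.test pnorm sd setNames wilcox.test
#' @importFrom utils head write.table
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes its `seed` argument
# through here so that no call mutates global RNG state.
withLocalSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Validate that `x` is an undirected, simple, named igraph; coerce names if
# absent (v1..vn). Used at every module boundary that accepts a network.
asPPIGraph <- function(x, arg = deparse(substitute(x))) {
  if (!igraph::is_igraph(x)) {
    stop(sprintf("'%s' must be an igraph object", arg), call. = FALSE)
  }
  if (igraph::is_directed(x)) {
    stop(sprintf("'%s' must be an undirected graph", arg), call. = FALSE)
  }
  if (!igraph::is_simple(x)) {
    stop(sprintf("'%s' must be simple (no self-loops or parallel edges)", arg),
         call. = FALSE)
  }
  if (is.null(igraph::V(x)$name)) {
    igraph::V(x)$name <- paste0("v", seq_len(igraph::vcount(x)))
  }
  x
}

# Accepts directed graphs too (controllability works on digraphs).
asAnyGraph <- function(x, arg = deparse(substitute(x))) {
  if (!igraph::is_igraph(x)) {
    stop(sprintf("'%s' must be an igraph object", arg), call. = FALSE)
  }
  if (!igraph::is_simple(x)) {
    stop(sprintf("'%s' must be simple (no self-loops or parallel edges)", arg),
         call. = FALSE)
  }
  if (is.null(igraph::V(x)$name)) {
    igraph::V(x)$name <- paste0("v", seq_len(igraph::vcount(x)))
  }
  x
}

isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

isFraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
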