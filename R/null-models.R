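#' Degree-preserving configuration model
#'
#' Draws a simple undirected randomization of a network preserving every
#' node's degree exactly (connections are shuffled, the degree sequence is
#' not). Node identity is kept: vertex i of the replicate carries the name
#' and degree of vertex i of the input. Seeded and reproducible.
#'
#' @param net an undirected simple igraph.
#' @param seed integer RNG seed.
#' @return An undirected simple igraph with the identical node set and
#'   per-node degrees.
#' @examples
#' g <- canonicalGraph("star", 4)
#' h <- configurationModel(g, seed = 3)
#' identical(igraph::degree(h), igraph::degree(g))  # TRUE
#' @export
configurationModel <- function(net, seed = 1L) {
  net <- asPPIGraph(net)
  degs <- igraph::degree(net)
  g <- realizeDegreeSequence(as.integer(degs), seed)
  igraph::V(g)$name <- igraph::V(net)$name
  g
}

#' Build a configuration-model null ensemble
#'
#' Generates R degree-preserving replicates of a native network and records
#' the replicate-level aggregates (average closeness, betweenness and
#' clustering) used downstream for z-scores.
#'
#' @param net the native network.
#' @param R ensemble size (default 10).
#' @param seed integer; replicate k uses a seed derived from \code{seed} and
#'   k.
#' @return A \code{\link{NullEnsemble}}.
#' @export
nullEnsemble <- function(net, R = 10L, seed = 1L) {
  net <- asPPIGraph(net)
  if (!isCount(R) || R < 2) stop("ensemble size R must be >= 2", call. = FALSE)
  reps <- lapply(seq_len(R), function(k) configurationModel(net, seed = seed + 101L * k))
  agg <- do.call(rbind, lapply(reps, function(g) {
    tb <- nodeMetrics(g)@nodeTable
    data.frame(avgCloseness = mean(tb$closeness),
               avgBetweenness = mean(tb$betweenness),
               avgClustering = mean(tb$clustering))
  }))
  rownames(agg) <- NULL
  new("NullEnsemble", native = net, replicates = reps,
      ensembleSize = as.integer(R), aggregates = agg)
}

#' z-scores of native aggregates against a configuration ensemble
#'
#' For each aggregate (average closeness, betweenness, clustering), computes
#' z = (x - mu)/sigma where x is the native network's aggregate and mu, sigma
#' are the mean and sample standard deviation of the replicate aggregates.
#' When sigma = 0 the z-score is undefined and flagged.
#'
#' @param ensemble a \code{\link{NullEnsemble}}, or a native igraph (in which
#'   case the ensemble is built here).
#' @param R,seed passed to \code{\link{nullEnsemble}} when \code{ensemble} is
#'   a graph.
#' @return data.frame with columns metric, native, mu, sigma, z, defined.
#' @export
ensembleZScores <- function(ensemble, R = 10L, seed = 1L) {
  if (igraph::is_igraph(ensemble)) {
    ensemble <- nullEnsemble(ensemble, R = R, seed = seed)
  }
  stopifnot(is(ensemble, "NullEnsemble"))
  nat <- nodeMetrics(ensemble@native)@nodeTable
  x <- c(avgCloseness = mean(nat$closeness),
         avgBetweenness = mean(nat$betweenness),
         avgClustering = mean(nat$clustering))
  agg <- ensemble@aggregates
  out <- do.call(rbind, lapply(names(x), function(met) {
    mu <- mean(agg[[met]])
    sigma <- sd(agg[[met]])
    defined <- is.finite(sigma) && sigma > 0
    data.frame(metric = met, native = unname(x[met]), mu = mu, sigma = sigma,
               z = if (defined) (x[[met]] - mu) / sigma else NA_real_,
               defined = defined, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test for paired per-node metric distributions
#'
#' Two-sided paired signed-rank test between a native per-node metric vector
#' and its null counterpart (values paired by node). Uses the exact
#' distribution for up to 25 non-zero differences (when ties permit) and the
#' normal approximation with continuity correction otherwise. If all paired
#' differences are zero the test is degenerate and p = 1 is returned with a
#' warning.
#'
#' @param nativeValues,nullValues equal-length numeric vectors paired by
#'   node.
#' @return The two-sided p-value.
#' @examples
#' pairedSignedRank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))  # 2/32 = 0.0625
#' @export
pairedSignedRank <- function(nativeValues, nullValues) {
  stopifnot(is.numeric(nativeValues), is.numeric(nullValues),
            length(nativeValues) == length(nullValues),
            length(nativeValues) >= 1)
  d <- nativeValues - nullValues
  if (all(d == 0)) {
    warning("all paired differences are zero; signed-rank test is degenerate")
    return(1)
  }
  nz <- sum(d != 0)
  ht <- suppressWarnings(
    wilcox.test(nativeValues, nullValues, paired = TRUE,
                alternative = "two.sided", exact = nz <= 25, correct = TRUE)
  )
  unname(ht$p.value)
}

#' Cross-group rank test with Bonferroni correction
#'
#' Pairwise Kruskal-Wallis rank tests between every pair of groups (e.g. the
#' normalized metric distribution of each organism), with Bonferroni
#' adjustment over the number of unordered pairs and p-values capped at 1.
#' The diagonal is NaN (a group against itself is not a comparison).
#'
#' @param distributions named list of numeric vectors, one per group, each
#'   with at least 2 values.
#' @return Symmetric matrix of adjusted p-values with NaN diagonal.
#' @export
crossSpeciesTest <- function(distributions) {
  k <- length(distributions)
  if (k < 2) stop("at least two groups are required", call. = FALSE)
  if (any(lengths(distributions) < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  nms <- names(distributions)
  if (is.null(nms)) nms <- paste0("g", seq_len(k))
  nPairs <- choose(k, 2)
  p <- matrix(NaN, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      raw <- kruskal.test(list(distributions[[i]], distributions[[j]]))$p.value
      p[i, j] <- p[j, i] <- min(1, raw * nPairs)
    }
  }
  p
}

#' Pearson correlation with significance
#'
#' Product-moment correlation between two equal-length vectors with the
#' two-sided p-value from the t transform. Zero variance in either vector is
#' flagged as undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{r}, \code{p} and \code{defined}.
#' @examples
#' tab <- organismTable()
#' pearsonCor(tab$avgCloseness, tab$avgBetweenness)$r  # -0.94
#' @export
pearsonCor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, defined = FALSE))
  }
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, defined = TRUE)
}

#' Agglomerative clustering of per-organism feature vectors
#'
#' Hierarchical (UPGMA, average-linkage) clustering of organisms by their
#' normalized network features under Euclidean distance; deterministic given
#' its inputs.
#'
#' @param featureVectors a numeric matrix (one row per organism) or a named
#'   list of equal-length numeric vectors.
#' @return An \code{hclust} merge tree.
#' @export
hierarchicalDendrogram <- function(featureVectors) {
  if (is.list(featureVectors) && !is.data.frame(featureVectors)) {
    stopifnot(length(featureVectors) >= 2,
              length(unique(lengths(featureVectors))) == 1)
    featureVectors <- do.call(rbind, featureVectors)
  }
  featureVectors <- as.matrix(featureVectors)
  stopifnot(nrow(featureVectors) >= 2)
  hclust(dist(featureVectors, method = "euclidean"), method = "average")
}
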