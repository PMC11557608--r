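#' Configuration for a full multi-network analysis
#'
#' Validated parameter bundle for \code{\link{runFullAnalysis}}. Networks can
#' be given as igraph objects, paths to STRING-style TSV files, or organism
#' names to emulate synthetically — mixed freely in a named list.
#'
#' @param networks named list; each element an igraph, a file path
#'   (character, existing file) or an organism name from
#'   \code{\link{organismTable}}.
#' @param scoreThreshold minimum combined score for TSV ingestion (default
#'   0.400).
#' @param ensembleSize configuration-model replicates per network R (default
#'   10).
#' @param attackStrategies subset of c("random", "degree", "closeness",
#'   "betweenness").
#' @param attackDirection "ascending" (least important removed first, the
#'   headline analysis) or "descending".
#' @param jumpThreshold minimum LCC drop flagged as a jump (default 0.10).
#' @param driverCap cap on enumerated driver sets (default 64).
#' @param seed master seed; every stage derives its own seed from it.
#' @param outDir optional directory; when set, the bundle is written as
#'   TSV/JSON files.
#' @return An object of class \code{AnalysisConfig}.
#' @export
analysisConfig <- function(networks,
                           scoreThreshold = 0.400,
                           ensembleSize = 10L,
                           attackStrategies = c("random", "degree", "closeness", "betweenness"),
                           attackDirection = c("ascending", "descending"),
                           jumpThreshold = 0.10,
                           driverCap = 64L,
                           seed = 1L,
                           outDir = NULL) {
  if (!is.list(networks) || !length(networks)) {
    stop("networks must be a non-empty list", call. = FALSE)
  }
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    stop("every network must be named", call. = FALSE)
  }
  if (!isFraction(scoreThreshold)) stop("scoreThreshold must lie in [0,1]", call. = FALSE)
  if (!isCount(ensembleSize) || ensembleSize < 2) {
    stop("ensembleSize must be an integer >= 2", call. = FALSE)
  }
  attackStrategies <- match.arg(attackStrategies, several.ok = TRUE)
  attackDirection <- match.arg(attackDirection)
  if (!isFraction(jumpThreshold)) stop("jumpThreshold must lie in [0,1]", call. = FALSE)
  if (!isCount(driverCap) || driverCap < 1) stop("driverCap must be >= 1", call. = FALSE)
  if (!isCount(abs(seed))) stop("seed must be an integer", call. = FALSE)
  structure(list(networks = networks, scoreThreshold = scoreThreshold,
                 ensembleSize = as.integer(ensembleSize),
                 attackStrategies = attackStrategies,
                 attackDirection = attackDirection,
                 jumpThreshold = jumpThreshold,
                 driverCap = as.integer(driverCap),
                 seed = as.integer(seed), outDir = outDir),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from a flat-key YAML file
#'
#' Every pipeline default (score threshold 0.400, ensemble size 10, jump
#' threshold 0.10, attack strategies, seeds) is a named key; the
#' \code{networks} key maps names to organism names, TSV paths or omitted
#' fields. Keys absent from the file keep the \code{\link{analysisConfig}}
#' defaults.
#'
#' @param path path to a YAML file.
#' @return An \code{AnalysisConfig}.
#' @export
analysisConfigFromYAML <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$networks)) stop("YAML configuration must define 'networks'", call. = FALSE)
  args <- raw[intersect(names(raw),
                        c("scoreThreshold", "ensembleSize", "attackStrategies",
                          "attackDirection", "jumpThreshold", "driverCap",
                          "seed", "outDir"))]
  args$networks <- as.list(raw$networks)
  do.call(analysisConfig, args)
}

resolveNetwork <- function(x, name, scoreThreshold, seed) {
  if (igraph::is_igraph(x)) return(asPPIGraph(x))
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) return(readInteractionTSV(x, scoreThreshold = scoreThreshold))
    if (x %in% organismTable()$organism) return(emulateOrganism(x, seed = seed))
  }
  stop(sprintf("network '%s' is neither an igraph, an existing file, nor a known organism", name),
       call. = FALSE)
}

#' Run the full per-network and cross-network analysis
#'
#' Orchestrates the whole pipeline over a set of networks: descriptor suite
#' with normalized variants, configuration-model ensemble with z-scores and
#' paired signed-rank tests, ensemble-average Generalized Hamming Distance,
#' average path length and efficiency, attack traces with robustness and
#' jump lists for every configured strategy, minimum driver nodes with
#' enumerated alternatives, and cross-network Kruskal-Wallis/Bonferroni
#' p-value matrices over the normalized metric distributions. Identical
#' configurations (including seeds) produce identical bundles.
#'
#' @param config an \code{\link{analysisConfig}}.
#' @return A list (invisible when written to disk) with elements
#'   \code{descriptors}, \code{normalized}, \code{zscores}, \code{ghd},
#'   \code{pathEfficiency}, \code{robustness}, \code{jumps}, \code{drivers},
#'   \code{crossTests} and \code{manifest}.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "AnalysisConfig"))
  nms <- names(config$networks)
  nets <- lapply(seq_along(nms), function(i) {
    resolveNetwork(config$networks[[i]], nms[i], config$scoreThreshold,
                   seed = config$seed + 13L * i)
  })
  names(nets) <- nms

  tables <- list()
  norm_rows <- list()
  z_rows <- list()
  ghd_rows <- list()
  pe_rows <- list()
  rob_rows <- list()
  jump_rows <- list()
  drv_rows <- list()
  norm_dists <- list(degree = list(), closeness = list(), betweenness = list())

  for (i in seq_along(nets)) {
    nm <- nms[i]
    g <- nets[[i]]
    seed_i <- config$seed + 1000L * i
    tab <- normalizeMetrics(networkAggregates(g, nodeMetrics(g), seed = seed_i))
    tables[[nm]] <- tab
    st <- tab@networkStats
    nt <- tab@nodeTable
    norm_rows[[nm]] <- data.frame(
      network = nm,
      normDegree = mean(nt$normDegree),
      normCloseness = mean(nt$normCloseness),
      normBetweenness = mean(nt$normBetweenness),
      stringsAsFactors = FALSE)
    norm_dists$degree[[nm]] <- nt$normDegree
    norm_dists$closeness[[nm]] <- nt$normCloseness
    norm_dists$betweenness[[nm]] <- nt$normBetweenness

    ens <- nullEnsemble(g, R = config$ensembleSize, seed = seed_i)
    zs <- ensembleZScores(ens)
    # per-node paired tests: native value vs node's ensemble mean
    null_tabs <- lapply(ens@replicates, function(r) nodeMetrics(r)@nodeTable)
    null_mean <- function(col) {
      rowMeans(do.call(cbind, lapply(null_tabs, function(tt) {
        tt[[col]][match(nt$node, tt$node)]
      })))
    }
    p_clos <- pairedSignedRank(nt$closeness, null_mean("closeness"))
    p_bet <- pairedSignedRank(nt$betweenness, null_mean("betweenness"))
    zw <- setNames(zs$z, zs$metric)
    z_rows[[nm]] <- data.frame(
      network = nm,
      zCloseness = zw[["avgCloseness"]], pCloseness = p_clos,
      zBetweenness = zw[["avgBetweenness"]], pBetweenness = p_bet,
      zClustering = zw[["avgClustering"]],
      stringsAsFactors = FALSE)

    gh <- ghdEnsemble(ens)
    ghd_rows[[nm]] <- data.frame(network = nm, avgGHD = gh$mean,
                                 stringsAsFactors = FALSE)
    pe_rows[[nm]] <- data.frame(network = nm, avgPathLength = st$avgPathLength,
                                efficiency = st$efficiency, stringsAsFactors = FALSE)

    for (strat in config$attackStrategies) {
      ord <- attackOrder(g, strat, config$attackDirection, seed = seed_i)
      tr <- runAttack(g, ord, strategy = strat, direction = config$attackDirection)
      rob_rows[[paste(nm, strat)]] <- data.frame(
        network = nm, strategy = strat, direction = config$attackDirection,
        robustness = robustnessR(tr), stringsAsFactors = FALSE)
      jj <- detectJumps(tr, config$jumpThreshold)
      if (nrow(jj)) {
        jump_rows[[paste(nm, strat)]] <- cbind(
          data.frame(network = nm, strategy = strat, stringsAsFactors = FALSE), jj)
      }
    }

    dr <- enumerateDriverSets(g, cap = config$driverCap, seed = seed_i)
    drv_rows[[nm]] <- data.frame(
      network = nm, driverCount = dr@driverCount,
      nSets = length(dr@driverSets), truncated = dr@truncated,
      verified = dr@verified,
      firstSet = paste(dr@driverSets[[1]], collapse = ";"),
      stringsAsFactors = FALSE)
  }

  crossTests <- if (length(nets) >= 2) {
    lapply(norm_dists, crossSpeciesTest)
  } else {
    list()
  }

  bundle <- list(
    descriptors = metricReport(tables),
    normalized = do.call(rbind, unname(norm_rows)),
    zscores = do.call(rbind, unname(z_rows)),
    ghd = do.call(rbind, unname(ghd_rows)),
    pathEfficiency = do.call(rbind, unname(pe_rows)),
    robustness = do.call(rbind, unname(rob_rows)),
    jumps = if (length(jump_rows)) do.call(rbind, unname(jump_rows)) else
      data.frame(network = character(), strategy = character(),
                 step = integer(), node = character(), deltaG = numeric()),
    drivers = do.call(rbind, unname(drv_rows)),
    crossTests = crossTests,
    manifest = list(seed = config$seed, scoreThreshold = config$scoreThreshold,
                    ensembleSize = config$ensembleSize,
                    attackStrategies = config$attackStrategies,
                    attackDirection = config$attackDirection,
                    jumpThreshold = config$jumpThreshold,
                    driverCap = config$driverCap,
                    networks = nms,
                    packageVersion = as.character(utils::packageVersion("UPRnet")))
  )
  for (el in c("robustness", "jumps")) rownames(bundle[[el]]) <- NULL

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    for (el in c("descriptors", "normalized", "zscores", "ghd",
                 "pathEfficiency", "robustness", "jumps", "drivers")) {
      write.table(bundle[[el]], file.path(config$outDir, paste0(el, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (met in names(crossTests)) {
      write.table(crossTests[[met]],
                  file.path(config$outDir, paste0("crosstest_", met, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = TRUE, col.names = NA)
    }
    jsonlite::write_json(bundle$manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(bundle))
  }
  bundle
}
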