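#' Parse a STRING-style tab-separated interaction file into a network
#'
#' Reads records of protein pairs with a combined interaction score and
#' returns the undirected simple graph of interactions at or above the score
#' threshold. Mirrors the STRING export convention: both directions of a pair
#' may be listed ((a,b) and (b,a) collapse to one undirected edge), self-pairs
#' are dropped, and scores printed as integers 0-999 are auto-detected and
#' divided by 1000.
#'
#' @param file path to a tab-separated file, or a character vector of lines.
#' @param scoreThreshold minimum combined score kept, inclusive (default
#'   0.400, STRING's medium confidence).
#' @param columns length-3 character or integer vector naming/indexing the
#'   two identifier columns and the score column.
#' @param nodes optional character vector of node identifiers to retain even
#'   when isolated (an authoritative curated node list).
#' @param strict logical; if TRUE an empty input is an error, otherwise it
#'   yields a 0-node network.
#' @return An undirected simple igraph with vertex names and a
#'   \code{score} edge attribute (the maximum score among collapsed records).
#' @examples
#' lines <- c("protein1\tprotein2\tcombined_score",
#'            "A\tB\t0.9", "B\tA\t0.9", "A\tC\t0.2", "C\tC\t0.8")
#' g <- readInteractionTSV(lines)
#' igraph::vcount(g)  # 2: C only appears in sub-threshold/self records
#' @export
readInteractionTSV <- function(file, scoreThreshold = 0.400,
                               columns = c("protein1", "protein2", "combined_score"),
                               nodes = NULL, strict = FALSE) {
  stopifnot(isFraction(scoreThreshold))
  lines <- if (length(file) == 1L && !grepl("[\t\n]", file)) {
    if (!file.exists(file)) stop(sprintf("file not found: '%s'", file), call. = FALSE)
    readLines(file)
  } else {
    unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) {
    if (strict) stop("empty interaction file", call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  ncols <- lengths(parts)

  # resolve the three columns against the (optional) header
  first <- parts[[1L]]
  has_header <- FALSE
  if (is.character(columns)) {
    idx <- match(columns, first)
    if (!anyNA(idx)) {
      has_header <- TRUE
    } else {
      idx <- c(1L, 2L, min(3L, ncols[1L]))
      # unrecognized names: the first row may still be a header
      if (suppressWarnings(is.na(as.numeric(first[idx[3L]])))) has_header <- TRUE
    }
  } else {
    idx <- as.integer(columns)
    # a header row is still permitted: detect a non-numeric score field
    if (suppressWarnings(is.na(as.numeric(first[idx[3L]])))) has_header <- TRUE
  }
  body <- if (has_header) seq_along(parts)[-1L] else seq_along(parts)
  if (!length(body)) {
    if (strict) stop("empty interaction file (header only)", call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }

  need <- max(idx)
  bad <- body[ncols[body] < need]
  if (length(bad)) {
    stop(sprintf("malformed row at line %d: expected at least %d tab-separated columns, found %d",
                 lines_keep[bad[1L]], need, ncols[bad[1L]]), call. = FALSE)
  }
  a <- vapply(parts[body], `[`, character(1), idx[1L])
  b <- vapply(parts[body], `[`, character(1), idx[2L])
  s_raw <- vapply(parts[body], `[`, character(1), idx[3L])
  s <- suppressWarnings(as.numeric(s_raw))
  if (anyNA(s)) {
    bad <- which(is.na(s))[1L]
    stop(sprintf("malformed row at line %d: non-numeric score '%s'",
                 lines_keep[body[bad]], s_raw[bad]), call. = FALSE)
  }
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    bad <- which(!nzchar(a) | !nzchar(b))[1L]
    stop(sprintf("malformed row at line %d: empty protein identifier",
                 lines_keep[body[bad]]), call. = FALSE)
  }
  # STRING convention: integer scores on the 0-999 scale
  if (all(s == floor(s)) && any(s > 1)) s <- s / 1000
  if (any(s < 0 | s > 1)) {
    bad <- which(s < 0 | s > 1)[1L]
    stop(sprintf("malformed row at line %d: score %g outside [0,1]",
                 lines_keep[body[bad]], s[bad]), call. = FALSE)
  }

  keep <- s >= scoreThreshold & a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (!length(a)) {
    warning("no interaction records at or above the score threshold; returning an edgeless network")
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  score <- if (length(key)) tapply(s, key, max) else numeric(0)
  uq <- !duplicated(key)
  edge_df <- data.frame(from = lo[uq], to = hi[uq], stringsAsFactors = FALSE)
  if (nrow(edge_df)) edge_df$score <- as.numeric(score[key[uq]])
  verts <- sort(unique(c(edge_df$from, edge_df$to, as.character(nodes))))
  g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                     vertices = data.frame(name = verts))
  asPPIGraph(g)
}

#' Number of directed interaction records represented by a network
#'
#' STRING exports (and the summary convention built on them) list each
#' undirected interaction twice, once per direction; the record count of a
#' network with M undirected edges is therefore 2M. Always even.
#'
#' @param net an undirected simple igraph.
#' @return integer, \code{2 * ecount(net)}.
#' @examples
#' edgeRecordCount(igraph::make_full_graph(4))  # 12
#' @export
edgeRecordCount <- function(net) {
  net <- asPPIGraph(net)
  2L * igraph::ecount(net)
}

#' Write a canonical undirected edge-list TSV
#'
#' One undirected edge per line, endpoints sorted within the pair and rows
#' sorted, with a \code{combined_score} column (1.0 when the graph carries no
#' score attribute) so the output is re-parseable by
#' \code{\link{readInteractionTSV}}.
#'
#' @param net an undirected simple igraph.
#' @param file path to write to (or "" for stdout).
#' @return Invisibly, the data.frame written.
#' @export
writeEdgeList <- function(net, file) {
  net <- asPPIGraph(net)
  el <- igraph::as_edgelist(net)
  sc <- igraph::edge_attr(net, "score")
  if (is.null(sc)) sc <- rep(1, nrow(el))
  lo <- pmin(el[, 1], el[, 2]); hi <- pmax(el[, 1], el[, 2])
  df <- data.frame(protein1 = lo, protein2 = hi, combined_score = sc,
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein1, df$protein2), , drop = FALSE]
  rownames(df) <- NULL
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Network density from node and record counts
#'
#' Density of an undirected network, D = 2M/(N(N-1)). When working from
#' summary tables that report directed record counts (2M), pass those via
#' \code{nRecords}.
#'
#' @param nNodes number of nodes N.
#' @param nRecords number of directed interaction records, i.e. 2M.
#' @return numeric density in [0, 1].
#' @examples
#' recordDensity(216, 5286)  # 0.1138...
#' @export
recordDensity <- function(nNodes, nRecords) {
  stopifnot(isCount(nNodes), nNodes >= 2, isCount(nRecords))
  nRecords / (nNodes * (nNodes - 1))
}
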