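#' Read a GMT gene-set file
#'
#' Standard GMT layout: one set per line, tab-separated, with the set
#' name, a description field, then member identifiers.  Uses
#' `fgsea::gmtPathways()` when fgsea is installed, otherwise a plain
#' parser of the same format.
#'
#' @param path GMT file path.
#' @return named list of character id vectors.
#' @export
readGMT <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1L))
}

#' Read an interaction network from a two-column edge list
#'
#' TSV with columns `node_a`, `node_b` (header optional, extra columns
#' ignored).  Duplicate edges (in either orientation) and self-loops are
#' removed.
#'
#' @param path TSV file path.
#' @return an [igraph::graph] (undirected, simple).
#' @export
readEdgeList <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs two columns", call. = FALSE)
  edgesToNetwork(df[[1L]], df[[2L]])
}

#' @rdname readEdgeList
#' @param from,to character vectors of endpoint identifiers.
#' @export
edgesToNetwork <- function(from, to) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Hypergeometric over-representation of a query set
#'
#' For each gene set, the upper-tail hypergeometric probability
#' `P(X >= overlap)` of drawing at least the observed overlap when
#' `query_size` identifiers are sampled without replacement from a
#' universe containing `set_size` set members.  P-values are BH-adjusted
#' across sets.  Query identifiers outside the universe are dropped with
#' a warning; set members outside the universe are filtered out.
#'
#' @param query character vector of selected identifiers.
#' @param sets named list of character vectors (e.g. from [readGMT()]).
#' @param universe character vector of all measured identifiers.
#' @return `data.frame` with `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `p_adjusted`,
#'   `overlap_ids`.
#' @export
hypergeomEnrich <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe) || !length(query)) {
    stop("query and universe must be non-empty", call. = FALSE)
  }
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query ids outside the universe dropped")
    query <- intersect(query, universe)
  }
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- intersect(query, s)
    k <- length(ov)
    # P(X >= k) for X ~ Hypergeom(N, |s|, q)
    p <- phyper(k - 1, length(s), N - length(s), q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               query_size = q, universe_size = N, p_value = p,
               overlap_ids = paste(sort(ov), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bhAdjust(out$p_value)
  out[, c("set_name", "overlap", "set_size", "query_size",
          "universe_size", "p_value", "p_adjusted", "overlap_ids")]
}

#' Core proteins by degree centrality
#'
#' Ranks nodes by degree and returns the top fraction, including every
#' node tied with the k-th ranked degree (`k = ceiling(fraction * n)`),
#' so the result is independent of edge-list ordering.
#'
#' @param network an igraph object (see [readEdgeList()]).
#' @param topFraction fraction of nodes regarded as "core", default 0.10.
#' @return character vector of core node ids, ordered by decreasing
#'   degree then id.
#' @export
degreeCore <- function(network, topFraction = 0.10) {
  deg <- igraph::degree(network)
  if (!length(deg)) stop("network has no nodes", call. = FALSE)
  if (all(deg == 0)) warning("network has no edges; all nodes are core")
  k <- ceiling(topFraction * length(deg))
  ord <- order(-deg, names(deg))
  cutoffDegree <- deg[ord][k]
  core <- ord[deg[ord] >= cutoffDegree]
  names(deg)[core]
}
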