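#' @importFrom igraph V E vcount ecount gorder gsize graph_from_edgelist
#'   as_edgelist is_simple is_directed simplify permute degree
#'   delete_edges make_empty_graph add_edges vertex_attr
NULL

## Networks are undirected simple igraph objects with named vertices,
## kept in a canonical (radix-sorted by name) vertex order so that all
## pair enumerations and tie-breaks are locale-independent.

.checkNetwork <- function(net) {
  if (!igraph::is_igraph(net))
    stop("expected an igraph network (see readEdgeList() or makeNetwork())")
  if (igraph::is_directed(net))
    stop("network must be undirected")
  if (!igraph::is_simple(net))
    stop("network must be simple (no self-loops or multi-edges)")
  if (igraph::vcount(net) > 0L && is.null(igraph::V(net)$name))
    stop("network vertices must be named")
  invisible(net)
}

#' Put a network into canonical vertex order
#'
#' Sorts vertices by name (radix order, locale-independent). All scoring
#' and ranking functions apply this internally so that outputs are
#' deterministic regardless of how the graph was assembled.
#'
#' @param net an undirected, simple, named igraph network.
#' @return The same network with vertices permuted into sorted order.
#' @export
canonicalNetwork <- function(net) {
  .checkNetwork(net)
  nm <- igraph::V(net)$name
  ord <- order(nm, method = "radix")
  igraph::permute(net, match(seq_along(nm), ord))
}

## All unordered node pairs in canonical vertex order, as a 2-column
## character matrix (u before v in sorted-vertex order).
.allPairs <- function(net) {
  nm <- igraph::V(net)$name
  n <- length(nm)
  if (n < 2L) return(matrix(character(0), ncol = 2L))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])   # row-major: (1,2),(1,3),...,(2,3),...
  cbind(nm[idx[ord, 1L]], nm[idx[ord, 2L]])
}

## Edge set as sorted "u\tv" keys (u < v by radix order).
.edgeKeys <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) return(character(0))
  swap <- .radixGT(el[, 1L], el[, 2L])
  tmp <- el[swap, 1L]; el[swap, 1L] <- el[swap, 2L]; el[swap, 2L] <- tmp
  paste(el[, 1L], el[, 2L], sep = "\t")
}

.radixGT <- function(a, b) {
  ## a > b in radix (C-locale) order, vectorised
  if (length(a) == 0L) return(logical(0))
  lev <- sort(unique(c(a, b)), method = "radix")
  match(a, lev) > match(b, lev)
}

.pairKeys <- function(u, v) {
  swap <- .radixGT(u, v)
  tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
  paste(u, v, sep = "\t")
}

## ---- edge-list / annotation / prediction I/O -------------------------------

#' Read an undirected network from a tab-separated edge list
#'
#' Each non-comment line holds at least two whitespace-separated tokens,
#' the endpoint identifiers; further tokens are ignored. Lines starting
#' with `#` are comments. Self-loops are dropped and duplicate or
#' reversed edges collapsed; a summary of dropped lines is reported via
#' `message()`.
#'
#' @param path path to the edge-list file.
#' @return An undirected simple igraph network with vertices in
#'   canonical (sorted) order.
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  lineNo <- which(keep)
  bad <- which(lengths(toks) < 2L)
  if (length(bad))
    stop(sprintf("edge list parse error: line %d has fewer than 2 fields",
                 lineNo[bad[1L]]))
  if (length(toks) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(igraph::set_vertex_attr(g, "name", value = character(0)))
  }
  u <- vapply(toks, `[[`, character(1), 1L)
  v <- vapply(toks, `[[`, character(1), 2L)
  loops <- u == v
  keyAll <- .pairKeys(u[!loops], v[!loops])
  dup <- duplicated(keyAll)
  nDropped <- sum(loops) + sum(dup)
  if (nDropped > 0L)
    message(sprintf("readEdgeList: dropped %d line(s) (%d self-loop, %d duplicate)",
                    nDropped, sum(loops), sum(dup)))
  key <- keyAll[!dup]
  el <- do.call(rbind, strsplit(key, "\t", fixed = TRUE))
  nodes <- sort(unique(c(u, v)), method = "radix")
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (!is.null(el))
    g <- igraph::add_edges(g, rbind(match(el[, 1L], nodes),
                                    match(el[, 2L], nodes)))
  canonicalNetwork(g)
}

#' Write a network as a tab-separated edge list
#'
#' @param net an undirected simple named igraph network.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeEdgeList <- function(net, path) {
  .checkNetwork(net)
  keys <- sort(.edgeKeys(net), method = "radix")
  writeLines(keys, path)
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' Two- or three-column whitespace-separated lines: gene identifier,
#' term identifier, and optionally an evidence code. When
#' `evidenceFilter` is given, rows whose code is outside the filter are
#' excluded (the way GO associations are restricted to experimental
#' evidence codes); genes left with no terms are absent from the result.
#'
#' @param path path to the annotation file (`#` comments allowed).
#' @param evidenceFilter optional character vector of evidence codes to
#'   keep.
#' @return Named list mapping gene identifier to a character vector of
#'   term identifiers.
#' @export
readAnnotations <- function(path, evidenceFilter = NULL) {
  if (!file.exists(path)) stop("cannot read annotations: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  lineNo <- which(keep)
  bad <- which(lengths(toks) < 2L)
  if (length(bad))
    stop(sprintf("annotation parse error: line %d has fewer than 2 fields",
                 lineNo[bad[1L]]))
  if (length(toks) == 0L) return(setNames(list(), character(0)))
  gene <- vapply(toks, `[[`, character(1), 1L)
  term <- vapply(toks, `[[`, character(1), 2L)
  if (!is.null(evidenceFilter)) {
    code <- vapply(toks, function(x)
      if (length(x) >= 3L) x[[3L]] else NA_character_, character(1))
    sel <- !is.na(code) & code %in% evidenceFilter
    gene <- gene[sel]; term <- term[sel]
  }
  if (length(gene) == 0L) return(setNames(list(), character(0)))
  ann <- lapply(split(term, gene), unique)
  ann[order(names(ann), method = "radix")]
}

#' Write a ranked prediction table
#'
#' Tab-separated lines `u v score`, ordered by descending score with
#' deterministic lexicographic tie-breaking (the [rankPairs()] order).
#'
#' @param scores a pair-score table (data.frame with columns `u`, `v`,
#'   `score`), e.g. from [scorePairs()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writePredictions <- function(scores, path) {
  ranked <- rankPairs(scores)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(ranked) > 0L)
    writeLines(sprintf("%s\t%s\t%.10g", ranked$u, ranked$v, ranked$score), con)
  invisible(path)
}
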