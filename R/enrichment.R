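#' @importFrom stats phyper
#' @importFrom Matrix sparseMatrix tcrossprod
NULL

.asEdgeMatrix <- function(edges) {
  if (igraph::is_igraph(edges)) {
    el <- igraph::as_edgelist(edges, names = TRUE)
  } else {
    el <- as.matrix(edges)[, 1:2, drop = FALSE]
  }
  if (nrow(el)) {
    swap <- .radixGT(el[, 1L], el[, 2L])
    tmp <- el[swap, 1L]; el[swap, 1L] <- el[swap, 2L]; el[swap, 2L] <- tmp
  }
  unique(el)
}

## Pairs of `genes` (a character vector) sharing at least one term,
## counted via the term-incidence matrix.
.sharingPairCount <- function(genes, ann) {
  if (length(genes) < 2L) return(0L)
  terms <- sort(unique(unlist(ann[genes])))
  gi <- rep(seq_along(genes), lengths(ann[genes]))
  ti <- match(unlist(ann[genes]), terms)
  inc <- sparseMatrix(i = gi, j = ti,
                      dims = c(length(genes), length(terms)))
  sh <- tcrossprod(inc * 1)
  sum(sh[upper.tri(sh)] > 0)
}

#' GO-term sharing enrichment of an edge set
#'
#' Biological-correctness score of a (predicted or de-noised) edge set:
#' among the eligible edges — those whose both endpoints carry at least
#' one annotation term — the fraction whose endpoints share a term.
#' Significance is an upper-tail hypergeometric test: the population is
#' all unordered pairs of annotated nodes of the universe network, the
#' population successes are such pairs sharing a term, the draws are
#' the eligible edges, and the observation is the sharing edges.
#'
#' @param edges the edge set to score: an igraph network or a 2-column
#'   character matrix.
#' @param ann annotation table (named list of term vectors, see
#'   [readAnnotations()]).
#' @param universe the network supplying the node universe for the
#'   population margins.
#' @return List of class `enrichmentResult`: `eligible`, `hits`,
#'   `fraction` (`NA` when no edge is eligible), `pValue`,
#'   `population`, `populationHits`.
#' @export
goEnrichment <- function(edges, ann, universe) {
  .checkNetwork(universe)
  el <- .asEdgeMatrix(edges)
  annotated <- intersect(igraph::V(universe)$name, names(ann))
  M <- choose(length(annotated), 2L)
  K <- .sharingPairCount(annotated, ann)
  eligible <- el[el[, 1L] %in% annotated & el[, 2L] %in% annotated, ,
                 drop = FALSE]
  nE <- nrow(eligible)
  hits <- if (nE) sum(vapply(seq_len(nE), function(r)
    length(intersect(ann[[eligible[r, 1L]]], ann[[eligible[r, 2L]]])) > 0,
    logical(1))) else 0L
  p <- if (nE == 0L || M == 0) 1
       else phyper(hits - 1, K, M - K, nE, lower.tail = FALSE)
  structure(list(eligible = nE, hits = as.integer(hits),
                 fraction = if (nE) hits / nE else NA_real_,
                 pValue = p, population = as.integer(M),
                 populationHits = as.integer(K)),
            class = "enrichmentResult")
}

#' Validate new edges against an independent reference network
#'
#' Checks how many predicted edges absent from the original network are
#' present in an independent reference data source, with an upper-tail
#' hypergeometric test. The population is the non-edges of the original
#' network over the nodes shared with the reference, the population
#' successes are those present in the reference, the draws are the new
#' edges (restricted to shared nodes; edges already in the original are
#' filtered out with a message), and the observation is the validated
#' edges.
#'
#' @param newEdges predicted edges: igraph network or 2-column character
#'   matrix.
#' @param original the original network the predictions came from.
#' @param reference the independent reference network.
#' @return List of class `enrichmentResult` (fields as in
#'   [goEnrichment()]).
#' @export
externalValidation <- function(newEdges, original, reference) {
  .checkNetwork(original); .checkNetwork(reference)
  shared <- intersect(igraph::V(original)$name, igraph::V(reference)$name)
  if (length(shared) < 2L)
    stop("original and reference networks share only ", length(shared),
         " node(s); validation is impossible")
  el <- .asEdgeMatrix(newEdges)
  keys <- if (nrow(el)) paste(el[, 1L], el[, 2L], sep = "\t") else character(0)
  origKeys <- .edgeKeys(original)
  inOrig <- keys %in% origKeys
  if (any(inOrig)) {
    message(sprintf("externalValidation: dropping %d edge(s) already in the original network",
                    sum(inOrig)))
    el <- el[!inOrig, , drop = FALSE]
    keys <- keys[!inOrig]
  }
  inShared <- el[, 1L] %in% shared & el[, 2L] %in% shared
  el <- el[inShared, , drop = FALSE]
  keys <- keys[inShared]

  refKeys <- .edgeKeys(reference)
  ## population: non-edges of the original over shared nodes
  nS <- length(shared)
  origWithin <- sum(vapply(strsplit(origKeys, "\t", fixed = TRUE),
                           function(x) all(x %in% shared), logical(1)))
  M <- choose(nS, 2L) - origWithin
  refWithin <- refKeys[vapply(strsplit(refKeys, "\t", fixed = TRUE),
                              function(x) all(x %in% shared), logical(1))]
  K <- sum(!refWithin %in% origKeys)
  draws <- nrow(el)
  hits <- sum(keys %in% refKeys)
  p <- if (draws == 0L || M == 0) 1
       else phyper(hits - 1, K, M - K, draws, lower.tail = FALSE)
  structure(list(eligible = draws, hits = as.integer(hits),
                 fraction = if (draws) hits / draws else NA_real_,
                 pValue = p, population = as.integer(M),
                 populationHits = as.integer(K)),
            class = "enrichmentResult")
}

#' @export
print.enrichmentResult <- function(x, ...) {
  cat(sprintf("enrichment: %d/%d hits (%s), hypergeometric p = %.3g\n",
              x$hits, x$eligible,
              if (is.na(x$fraction)) "NA" else sprintf("%.1f%%", 100 * x$fraction),
              x$pValue))
  invisible(x)
}
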