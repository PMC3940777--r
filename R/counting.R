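#' @useDynLib graphletLP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Prepare the 0-based lookup tables the C++ kernel expects. Element [[k]]
## of each list is the table for k-node subsets; -1 codes "no orbit".
.lutArgs <- function(catalog) {
  maxK <- catalog@maxNodes
  zero <- function(m, base) {
    m <- m - base
    m[is.na(m)] <- -1L
    storage.mode(m) <- "integer"
    m
  }
  pad <- matrix(-1L, 1L, 1L)
  node <- edge <- nonEdge <- rep(list(pad), maxK)
  for (k in 2:maxK) {
    node[[k]] <- zero(catalog@nodeLUT[[k]], 0L)
    edge[[k]] <- zero(catalog@edgeLUT[[k]], 1L)
    nonEdge[[k]] <- zero(catalog@nonEdgeLUT[[k]], 1L)
  }
  pfe <- catalog@pairFromEdge - 1L
  pfe[is.na(pfe)] <- -1L
  list(node = node, edge = edge, nonEdge = nonEdge, pairFromEdge = pfe)
}

.runEsu <- function(net, catalog, wantNode = FALSE, wantEdge = FALSE,
                    wantPair = FALSE) {
  .checkNetwork(net)
  stopifnot(is(catalog, "GraphletCatalog"))
  net <- canonicalNetwork(net)
  n <- igraph::vcount(net)
  tot0 <- catalog@totals
  if (n == 0L) {
    out <- list(net = net)
    if (wantNode)
      out$node <- matrix(0, 0L, tot0[["node"]],
                         dimnames = list(NULL, paste0("O", seq_len(tot0[["node"]]) - 1L)))
    if (wantEdge)
      out$edge <- matrix(0, 0L, tot0[["edge"]])
    if (wantPair)
      out$pair <- matrix(0, 0L, tot0[["pair"]])
    return(out)
  }
  adj <- lapply(igraph::adjacent_vertices(net, seq_len(n)),
                function(x) as.integer(x) - 1L)
  el <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(el) <- "integer"
  swap <- el[, 1L] > el[, 2L]
  el[swap, ] <- el[swap, c(2L, 1L)]
  lut <- .lutArgs(catalog)
  tot <- catalog@totals
  res <- .esuCount(adj, n, catalog@maxNodes,
                   lut$node, lut$edge, lut$nonEdge, lut$pairFromEdge,
                   el - 1L, tot[["node"]], tot[["edge"]], tot[["pair"]],
                   wantNode, wantEdge, wantPair)
  nm <- igraph::V(net)$name
  out <- list(net = net)
  if (wantNode) {
    m <- t(res$node)
    dimnames(m) <- list(nm, paste0("O", seq_len(tot[["node"]]) - 1L))
    out$node <- m
  }
  if (wantEdge) {
    m <- t(res$edge)
    dimnames(m) <- list(paste(nm[el[, 1L]], nm[el[, 2L]], sep = "|"),
                        paste0("E", seq_len(tot[["edge"]])))
    out$edge <- m
  }
  if (wantPair) {
    m <- t(res$pair)
    pairs <- .allPairs(net)
    dimnames(m) <- list(paste(pairs[, 1L], pairs[, 2L], sep = "|"),
                        paste0("P", seq_len(tot[["pair"]])))
    attr(m, "pairs") <- pairs
    out$pair <- m
  }
  out
}

#' Node graphlet degree vectors
#'
#' For every node, counts the number of induced connected subgraphs on
#' up to `maxNodes(catalog)` nodes in which the node occupies each node
#' orbit. Column `O0` is the degree.
#'
#' @param net an undirected simple named igraph network.
#' @param catalog a [GraphletCatalog-class] (defaults to the full
#'   2-5-node catalog).
#' @return Integer-valued numeric matrix, one row per node (canonical
#'   order), one column per node orbit (`O0` ... `O72` for the 5-node
#'   catalog).
#' @examples
#' tri <- makeNetwork("ring_chords", n = 3, param = 0, seed = 1)
#' countNodeGDV(tri)[, 1:6]
#' @export
countNodeGDV <- function(net, catalog = buildCatalog(5L)) {
  .runEsu(net, catalog, wantNode = TRUE)$node
}

#' Edge graphlet degree vectors
#'
#' Orbit-touch counts of every edge over the edge orbits (`E1` ...
#' `E68` for the 5-node catalog; edge orbits start at the 3-node
#' graphlets, so a lone edge touches nothing).
#'
#' @inheritParams countNodeGDV
#' @return Numeric matrix, one row per edge (named `u|v`), one column
#'   per edge orbit.
#' @export
countEdgeGDV <- function(net, catalog = buildCatalog(5L)) {
  .runEsu(net, catalog, wantEdge = TRUE)$edge
}

#' Node-pair graphlet degree vectors for all pairs
#'
#' For every unordered node pair, counts graphlet touches at each
#' node-pair orbit. The pair's own edge status is masked: each node
#' subset containing the pair is classified by the non-edge orbit of the
#' pair in the induced subgraph with the pair's edge (if any) removed,
#' provided that masked subgraph is connected. Consequently the counts
#' for a pair are identical whether or not the pair is currently an
#' edge, given the same surrounding structure.
#'
#' @inheritParams countNodeGDV
#' @return Numeric matrix, one row per unordered pair (named `u|v`, in
#'   canonical order), one column per node-pair orbit (`P1` ...). The
#'   pair endpoints are in `attr(, "pairs")`.
#' @export
countPairGDV <- function(net, catalog = buildCatalog(5L)) {
  .runEsu(net, catalog, wantPair = TRUE)$pair
}

#' Node-pair GDV of a single pair
#'
#' @inheritParams countNodeGDV
#' @param u,v node names; `u != v`, both present in the network.
#' @return Numeric vector, one entry per node-pair orbit.
#' @export
pairGDV <- function(net, u, v, catalog = buildCatalog(5L)) {
  .checkNetwork(net)
  nm <- igraph::V(net)$name
  if (!u %in% nm || !v %in% nm) stop("both nodes must be in the network")
  if (u == v) stop("'u' and 'v' must differ")
  m <- countPairGDV(net, catalog)
  key <- paste(sort(c(u, v), method = "radix"), collapse = "|")
  m[key, ]
}

#' Non-edge GDV of a single non-adjacent pair
#'
#' Orbit-touch counts of a non-edge over the non-edge orbits. For a
#' non-adjacent pair these coincide orbit-for-orbit with the node-pair
#' GDV (masking removes nothing).
#'
#' @inheritParams pairGDV
#' @return Numeric vector, one entry per non-edge orbit (`N1` ...).
#' @export
nonEdgeGDV <- function(net, u, v, catalog = buildCatalog(5L)) {
  .checkNetwork(net)
  if (igraph::are_adjacent(net, u, v))
    stop("(", u, ", ", v, ") is an edge; non-edge GDV is undefined for edges")
  out <- pairGDV(net, u, v, catalog)
  names(out) <- paste0("N", seq_along(out))
  out
}
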