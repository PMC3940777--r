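# Naive counting oracle, independent of the ESU kernel: enumerate every
# node subset of size 2..maxNodes, test connectivity, and classify the
# induced subgraph by igraph (VF2) isomorphism against the catalog
# representatives. Classification is memoised on the labelled adjacency
# mask, so the oracle stays brute-force in its enumeration but affordable.

makeOracle <- function(catalog) {
  reps <- lapply(catalog@graphlets, function(g) {
    pairs <- graphletLP:::.pairsOf(g$k)
    edges <- which(vapply(seq_len(ncol(pairs)), function(p)
      bitwAnd(bitwShiftR(g$mask, p - 1L), 1L) == 1L, logical(1)))
    gr <- igraph::make_empty_graph(g$k, directed = FALSE)
    if (length(edges))
      gr <- igraph::add_edges(gr, as.vector(pairs[, edges, drop = FALSE]) + 1L)
    list(k = g$k, eCount = g$eCount, graph = gr,
         nodeOrbit = g$nodeOrbit, posNonEdgeOrbit = g$posNonEdgeOrbit)
  })
  cache <- new.env(parent = emptyenv())
  ## classify a labelled induced adjacency matrix (k x k logical);
  ## returns NULL if disconnected, else per-position global node orbits
  ## and, per pair position, the non-edge orbit (NA for edges).
  classify <- function(adjSub) {
    k <- nrow(adjSub)
    pairs <- graphletLP:::.pairsOf(k)
    maskKey <- paste(k, paste(as.integer(adjSub[upper.tri(adjSub)]),
                              collapse = ""))
    hit <- cache[[maskKey]]
    if (!is.null(hit)) return(if (identical(hit, FALSE)) NULL else hit)
    gr <- igraph::graph_from_adjacency_matrix(adjSub, mode = "undirected")
    if (!igraph::is_connected(gr)) {
      cache[[maskKey]] <- FALSE
      return(NULL)
    }
    ec <- igraph::ecount(gr)
    res <- NULL
    for (rp in reps) {
      if (rp$k != k || rp$eCount != ec) next
      maps <- igraph::isomorphisms(gr, rp$graph)
      if (length(maps) == 0L) next
      ## the returned sequence is indexed by rep vertices; invert it so
      ## that map[i] is the rep vertex of sub vertex i
      r <- as.integer(maps[[1L]])
      map <- match(seq_along(r), r)
      nodeOrb <- rp$nodeOrbit[map]
      nonEdgeOrb <- rep(NA_integer_, ncol(pairs))
      for (p in seq_len(ncol(pairs))) {
        i <- pairs[1L, p] + 1L; j <- pairs[2L, p] + 1L
        if (!adjSub[i, j])
          nonEdgeOrb[p] <- rp$posNonEdgeOrbit[
            graphletLP:::.pairPos(map[i] - 1L, map[j] - 1L)]
      }
      res <- list(nodeOrb = nodeOrb, nonEdgeOrb = nonEdgeOrb)
      break
    }
    stopifnot(!is.null(res))
    cache[[maskKey]] <- res
    res
  }
  list(classify = classify)
}

oracleNodeGDV <- function(net, catalog, oracle = makeOracle(catalog)) {
  net <- canonicalNetwork(net)
  A <- as.matrix(igraph::as_adjacency_matrix(net)) > 0
  n <- nrow(A)
  counts <- matrix(0, n, nodeOrbitCount(catalog),
                   dimnames = list(igraph::V(net)$name, NULL))
  for (s in 2:min(catalog@maxNodes, n)) {
    for (S in utils::combn(n, s, simplify = FALSE)) {
      cl <- oracle$classify(A[S, S, drop = FALSE])
      if (is.null(cl)) next
      for (i in seq_along(S))
        counts[S[i], cl$nodeOrb[i] + 1L] <- counts[S[i], cl$nodeOrb[i] + 1L] + 1
    }
  }
  counts
}

oraclePairGDV <- function(net, u, v, catalog, oracle = makeOracle(catalog)) {
  net <- canonicalNetwork(net)
  A <- as.matrix(igraph::as_adjacency_matrix(net)) > 0
  nm <- igraph::V(net)$name
  ui <- match(u, nm); vi <- match(v, nm)
  A[ui, vi] <- A[vi, ui] <- FALSE       # mask the pair's own edge status
  n <- nrow(A)
  counts <- numeric(pairOrbitCount(catalog))
  rest <- setdiff(seq_len(n), c(ui, vi))
  for (s in 0:(catalog@maxNodes - 2L)) {
    combs <- if (s == 0L) list(integer(0))
             else utils::combn(rest, s, simplify = FALSE)
    for (S0 in combs) {
      S <- sort(c(ui, vi, S0))
      cl <- oracle$classify(A[S, S, drop = FALSE])
      if (is.null(cl)) next
      p <- graphletLP:::.pairPos(match(ui, S) - 1L, match(vi, S) - 1L)
      po <- cl$nonEdgeOrb[p]
      if (!is.na(po)) counts[po] <- counts[po] + 1
    }
  }
  counts
}
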