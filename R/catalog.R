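#' @import methods
#' @importFrom stats setNames
NULL

## ---- combinatorial helpers (0-based node labels, bitmask edge encodings) ----

## Unordered pairs of {0,...,k-1} in canonical position order:
## position p (0-based) for pair (i,j), i<j, is j*(j-1)/2 + i.
.pairsOf <- function(k) {
  if (k < 2L) return(matrix(integer(0), nrow = 2))
  idx <- which(upper.tri(diag(k)), arr.ind = TRUE)
  rbind(i = as.integer(idx[, 1] - 1L), j = as.integer(idx[, 2] - 1L))
}

.pairPos <- function(i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  (b * (b - 1L)) %/% 2L + a + 1L   # 1-based position
}

## All permutations of 0..k-1 as a matrix (one per row).
.permutationsOf <- function(k) {
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v),
                          function(i) cbind(v[i], rec(v[-i]))))
  }
  m <- rec(0:(k - 1L))
  storage.mode(m) <- "integer"
  m
}

.maskBit <- function(mask, p) bitwAnd(bitwShiftR(mask, p - 1L), 1L)

.maskConnected <- function(mask, k, pairs) {
  if (k == 1L) return(TRUE)
  adj <- matrix(FALSE, k, k)
  for (p in seq_len(ncol(pairs))) {
    if (.maskBit(mask, p) == 1L) {
      i <- pairs[1L, p] + 1L; j <- pairs[2L, p] + 1L
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  seen <- logical(k); seen[1L] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nxt <- which(!seen & apply(adj[frontier, , drop = FALSE], 2L, any))
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

## Induced mask of a node subset S (1-based node ids into 0..k-1 space).
.inducedMask <- function(mask, S, pairs) {
  s <- length(S)
  if (s < 2L) return(0L)
  Ssort <- sort(S)
  sub <- 0L
  subPairs <- .pairsOf(s)
  for (p in seq_len(ncol(subPairs))) {
    a <- Ssort[subPairs[1L, p] + 1L]; b <- Ssort[subPairs[2L, p] + 1L]
    if (.maskBit(mask, .pairPos(a, b)) == 1L)
      sub <- bitwOr(sub, bitwShiftL(1L, p - 1L))
  }
  sub
}

## ---- GraphletCatalog class -------------------------------------------------

#' GraphletCatalog: the 2-5-node graphlet and orbit reference
#'
#' Holds every non-isomorphic connected graph ("graphlet") on 2 to
#' `maxNodes` nodes, its automorphism group, and the four orbit
#' taxonomies derived from it: node orbits (positions a node can occupy),
#' edge orbits, non-edge orbits, and node-pair orbits. Node-pair orbits
#' reconcile each non-edge orbit with the edge orbit obtained by adding
#' the missing edge ("edge completion"), so that the position of a node
#' pair can be described while masking whether the pair is currently
#' linked.
#'
#' Orbit numbering is deterministic: graphlets are sorted by node count,
#' then edge count, then descending-sorted degree sequence, then a
#' canonical adjacency encoding; within a graphlet, orbits are sorted by
#' the degree of a representative element. Node orbits are numbered from
#' 0 (the 2-node graphlet, so that node orbit 0 counts the degree); edge,
#' non-edge, and node-pair orbits are numbered from 1 and start at the
#' 3-node graphlets. Under this numbering the 4-node path has its end
#' nodes in node orbit 4 and its middle nodes in node orbit 5, its outer
#' edges in edge orbit 3 and its middle edge in edge orbit 4, and the
#' 3-node path's non-edge (orbit 1) reconciles with the triangle's edge
#' orbit 2 into node-pair orbit 1.
#'
#' @slot maxNodes largest graphlet size in the catalog (3, 4, or 5).
#' @slot graphlets list of graphlet records (adjacency mask, degrees,
#'   automorphism count, per-element global orbit indices).
#' @slot totals named integer vector with the number of distinct node,
#'   edge, non-edge, and node-pair orbits.
#' @slot nodeLUT,edgeLUT,nonEdgeLUT per-size lookup tables mapping every
#'   labelled adjacency mask to global orbit indices (used by the
#'   counting kernel).
#' @slot pairFromEdge for each edge orbit, the node-pair orbit it
#'   reconciles into, or `NA` when deleting the edge disconnects the
#'   graphlet (bridge edge orbits have no node-pair counterpart).
#' @slot pairMap data.frame describing each node-pair orbit: the
#'   non-edge-side graphlet and orbit, the edge-completed graphlet and
#'   edge orbit, and the density of the completed graphlet.
#' @slot density per-node-pair-orbit density of the edge-completed
#'   graphlet, in (0, 1].
#' @slot nodeDeps,pairDeps per-orbit dependency counts: the number of
#'   distinct orbits whose touching is implied by touching this orbit
#'   within its own graphlet (used to derive orbit weights).
#'
#' @seealso [buildCatalog()], [orbitWeights()], [countNodeGDV()]
#' @export
setClass("GraphletCatalog",
  representation(
    maxNodes = "integer",
    graphlets = "list",
    totals = "integer",
    nodeLUT = "list",
    edgeLUT = "list",
    nonEdgeLUT = "list",
    pairFromEdge = "integer",
    pairMap = "data.frame",
    density = "numeric",
    nodeDeps = "integer",
    pairDeps = "integer"
  )
)

setValidity("GraphletCatalog", function(object) {
  msg <- character(0)
  if (!object@maxNodes %in% 3:5)
    msg <- c(msg, "maxNodes must be 3, 4 or 5")
  tot <- object@totals
  if (!identical(sort(names(tot)), sort(c("node", "edge", "nonEdge", "pair"))))
    msg <- c(msg, "totals must be named node/edge/nonEdge/pair")
  if (tot[["pair"]] != tot[["nonEdge"]])
    msg <- c(msg, "node-pair orbits must be in bijection with non-edge orbits")
  pf <- object@pairFromEdge
  if (length(pf) != tot[["edge"]])
    msg <- c(msg, "pairFromEdge must have one entry per edge orbit")
  mapped <- pf[!is.na(pf)]
  if (anyDuplicated(mapped) || length(mapped) != tot[["pair"]])
    msg <- c(msg, "edge-completion map must hit each node-pair orbit exactly once")
  if (length(object@density) != tot[["pair"]] ||
      any(object@density <= 0 | object@density > 1))
    msg <- c(msg, "densities must lie in (0, 1], one per node-pair orbit")
  if (length(msg)) msg else TRUE
})

## ---- catalog construction --------------------------------------------------

#' Build the graphlet-orbit catalog
#'
#' Enumerates all non-isomorphic connected graphs on 2 to `maxNodes`
#' nodes, computes each automorphism group by explicit permutation
#' enumeration, partitions nodes, edges, and non-edges into automorphism
#' orbits, and reconciles non-edge orbits with edge orbits via edge
#' completion into node-pair orbits. For `maxNodes = 5` this yields 73
#' node, 68 edge, 49 non-edge, and 49 node-pair orbits; for
#' `maxNodes = 4`, 15/12/7/7.
#'
#' @param maxNodes largest graphlet size: 3, 4, or 5.
#' @param useCache reuse a previously built catalog of the same size
#'   from the in-session cache (the catalog is fully deterministic).
#' @return A [GraphletCatalog-class] object.
#' @examples
#' cat5 <- buildCatalog(5)
#' orbitCounts(cat5)
#' @export
buildCatalog <- function(maxNodes = 5L, useCache = TRUE) {
  if (length(maxNodes) != 1L || !maxNodes %in% 3:5)
    stop("'maxNodes' must be 3, 4 or 5")
  maxNodes <- as.integer(maxNodes)
  key <- as.character(maxNodes)
  if (useCache && !is.null(.catalogCache[[key]]))
    return(.catalogCache[[key]])

  perK <- lapply(2:maxNodes, .enumerateSize)
  names(perK) <- as.character(2:maxNodes)

  ## flatten classes and order them canonically
  classes <- do.call(rbind, lapply(perK, function(x) x$classes))
  degKey <- do.call(rbind, lapply(seq_len(nrow(classes)), function(r) {
    d <- sort(classes$degrees[[r]], decreasing = TRUE)
    c(d, rep(-1L, 5L - length(d)))
  }))
  ord <- do.call(order, c(list(classes$k, classes$eCount),
                          lapply(seq_len(5L), function(c) degKey[, c]),
                          list(classes$mask)))
  classes <- classes[ord, , drop = FALSE]
  classes$id <- seq_len(nrow(classes)) - 1L   # 0-based graphlet ids

  ## assign global orbit indices graphlet by graphlet
  graphlets <- vector("list", nrow(classes))
  nodeCtr <- 0L; edgeCtr <- 0L; neCtr <- 0L
  for (r in seq_len(nrow(classes))) {
    k <- classes$k[r]; mask <- classes$mask[r]
    sz <- perK[[as.character(k)]]
    autos <- sz$autosOf(mask)            # perm indices fixing the mask
    pairs <- sz$pairs
    deg <- classes$degrees[[r]]

    ## node orbits
    nodeRep <- vapply(0:(k - 1L), function(i)
      min(sz$perms[autos, i + 1L]), integer(1))
    reps <- unique(nodeRep)
    reps <- reps[order(deg[reps + 1L], reps)]
    nodeOrbit <- integer(k)
    for (x in reps) {
      nodeOrbit[nodeRep == x] <- nodeCtr
      nodeCtr <- nodeCtr + 1L
    }

    ## edge / non-edge orbits over pair positions
    npos <- ncol(pairs)
    posRep <- vapply(seq_len(npos), function(p)
      min(sz$posMaps[autos, p]), integer(1))
    isEdge <- vapply(seq_len(npos), function(p) .maskBit(mask, p) == 1L,
                     logical(1))
    posEdgeOrbit <- rep(NA_integer_, npos)
    posNonEdgeOrbit <- rep(NA_integer_, npos)
    if (k >= 3L) {
      orderedReps <- function(which) {
        rp <- unique(posRep[which])
        key <- t(vapply(rp, function(p) {
          dd <- sort(deg[pairs[, p] + 1L], decreasing = TRUE)
          c(dd[1L], dd[2L], p)
        }, integer(3)))
        rp[order(key[, 1L], key[, 2L], key[, 3L])]
      }
      if (any(isEdge)) {
        for (p0 in orderedReps(isEdge)) {
          edgeCtr <- edgeCtr + 1L
          posEdgeOrbit[posRep == p0 & isEdge] <- edgeCtr
        }
      }
      if (any(!isEdge)) {
        for (p0 in orderedReps(!isEdge)) {
          neCtr <- neCtr + 1L
          posNonEdgeOrbit[posRep == p0 & !isEdge] <- neCtr
        }
      }
    }
    graphlets[[r]] <- list(
      id = classes$id[r], k = k, mask = mask, eCount = classes$eCount[r],
      degrees = deg, autCount = length(autos),
      nodeOrbit = nodeOrbit,
      posEdgeOrbit = posEdgeOrbit,
      posNonEdgeOrbit = posNonEdgeOrbit
    )
  }
  totals <- c(node = nodeCtr, edge = edgeCtr, nonEdge = neCtr, pair = neCtr)

  ## lookup tables: labelled mask -> global orbit per node / pair position
  byKMask <- new.env(parent = emptyenv())   # "k:mask" -> graphlet record
  for (g in graphlets) assign(paste(g$k, g$mask), g, envir = byKMask)
  nodeLUT <- vector("list", maxNodes)
  edgeLUT <- vector("list", maxNodes)
  nonEdgeLUT <- vector("list", maxNodes)
  for (k in 2:maxNodes) {
    sz <- perK[[as.character(k)]]
    nm <- 2L^ncol(sz$pairs)
    nl <- matrix(NA_integer_, nm, k)
    el <- matrix(NA_integer_, nm, ncol(sz$pairs))
    nel <- el
    for (m in which(sz$conn) - 1L) {
      q <- sz$canonPerm[m + 1L]
      g <- get(paste(k, sz$canon[m + 1L]), envir = byKMask)
      sigma <- sz$perms[q, ]                 # node i (0-based) -> sigma[i+1]
      nl[m + 1L, ] <- g$nodeOrbit[sigma + 1L]
      pm <- sz$posMaps[q, ]
      for (p in seq_len(ncol(sz$pairs))) {
        if (.maskBit(m, p) == 1L) el[m + 1L, p] <- g$posEdgeOrbit[pm[p]]
        else nel[m + 1L, p] <- g$posNonEdgeOrbit[pm[p]]
      }
    }
    nodeLUT[[k]] <- nl; edgeLUT[[k]] <- el; nonEdgeLUT[[k]] <- nel
  }

  ## edge completion: non-edge orbit -> (completed graphlet, edge orbit)
  pairFromEdge <- rep(NA_integer_, edgeCtr)
  rows <- list()
  for (g in graphlets) {
    if (g$k < 3L) next
    sz <- perK[[as.character(g$k)]]
    seen <- integer(0)
    for (p in seq_along(g$posNonEdgeOrbit)) {
      po <- g$posNonEdgeOrbit[p]
      if (is.na(po) || po %in% seen) next
      seen <- c(seen, po)
      m2 <- bitwOr(g$mask, bitwShiftL(1L, p - 1L))
      eo <- edgeLUT[[g$k]][m2 + 1L, p]
      g2 <- get(paste(g$k, sz$canon[m2 + 1L]), envir = byKMask)
      if (!is.na(pairFromEdge[eo]) && pairFromEdge[eo] != po)
        stop("internal error: edge completion is not injective")
      pairFromEdge[eo] <- po
      rows[[length(rows) + 1L]] <- data.frame(
        pairOrbit = po, neGraphlet = g$id, nonEdgeOrbit = po,
        edgeGraphlet = g2$id, edgeOrbit = eo,
        density = 2 * g2$eCount / (g2$k * (g2$k - 1L))
      )
    }
  }
  pairMap <- do.call(rbind, rows)
  pairMap <- pairMap[order(pairMap$pairOrbit), , drop = FALSE]
  rownames(pairMap) <- NULL
  density <- pairMap$density

  cat_ <- new("GraphletCatalog",
    maxNodes = maxNodes, graphlets = graphlets, totals = totals,
    nodeLUT = nodeLUT, edgeLUT = edgeLUT, nonEdgeLUT = nonEdgeLUT,
    pairFromEdge = pairFromEdge, pairMap = pairMap, density = density,
    nodeDeps = integer(0), pairDeps = integer(0))
  cat_@nodeDeps <- .nodeDependencies(cat_)
  cat_@pairDeps <- .pairDependencies(cat_)
  validObject(cat_)
  if (useCache) .catalogCache[[key]] <- cat_
  cat_
}

.catalogCache <- new.env(parent = emptyenv())

## Enumerate isomorphism classes of connected graphs on k labelled nodes.
## Returns masks, canonical forms, canonizing permutations, and closures
## used during orbit assignment.
.enumerateSize <- function(k) {
  pairs <- .pairsOf(k)
  npos <- ncol(pairs)
  nm <- 2L^npos
  bits <- matrix(0L, nm, npos)
  for (p in seq_len(npos))
    bits[, p] <- bitwAnd(bitwShiftR(0:(nm - 1L), p - 1L), 1L)
  conn <- vapply(0:(nm - 1L), .maskConnected, logical(1), k = k, pairs = pairs)
  perms <- .permutationsOf(k)
  nperm <- nrow(perms)
  posMaps <- matrix(0L, nperm, max(npos, 1L))
  for (q in seq_len(nperm))
    for (p in seq_len(npos))
      posMaps[q, p] <- .pairPos(perms[q, pairs[1L, p] + 1L],
                                perms[q, pairs[2L, p] + 1L])
  permuted <- matrix(0L, nm, nperm)
  for (q in seq_len(nperm))
    permuted[, q] <- as.integer(bits %*% bitwShiftL(1L, posMaps[q, seq_len(npos)] - 1L))
  canon <- apply(permuted, 1L, min)
  canonPerm <- apply(permuted, 1L, which.min)

  cmasks <- sort(unique(canon[conn]))
  classes <- data.frame(k = k, mask = cmasks)
  classes$eCount <- vapply(cmasks, function(m)
    sum(bits[m + 1L, ]), integer(1))
  classes$degrees <- lapply(cmasks, function(m) {
    d <- integer(k)
    for (p in seq_len(npos)) if (.maskBit(m, p) == 1L) {
      d[pairs[1L, p] + 1L] <- d[pairs[1L, p] + 1L] + 1L
      d[pairs[2L, p] + 1L] <- d[pairs[2L, p] + 1L] + 1L
    }
    d
  })
  list(
    pairs = pairs, conn = conn, perms = perms, posMaps = posMaps,
    canon = canon, canonPerm = canonPerm, classes = classes,
    autosOf = function(mask) which(permuted[mask + 1L, ] == mask)
  )
}

## Orbit-dependency counts: for each node orbit, the number of distinct
## node orbits a node at that position touches within its own graphlet
## (over connected induced subgraphs containing the node, itself included).
.nodeDependencies <- function(catalog) {
  deps <- integer(catalog@totals[["node"]])
  for (g in catalog@graphlets) {
    pairs <- .pairsOf(g$k)
    for (x in unique(g$nodeOrbit)) {
      rep_ <- which(g$nodeOrbit == x)[1L] - 1L
      touched <- integer(0)
      others <- setdiff(0:(g$k - 1L), rep_)
      for (s in 0:(g$k - 1L)) {
        if (s > 0L) combs <- utils::combn(others, s, simplify = FALSE)
        else combs <- list(integer(0))
        for (S0 in combs) {
          S <- c(rep_, S0)
          if (length(S) < 2L) next
          sub <- .inducedMask(g$mask, S, pairs)
          pos <- match(rep_, sort(S))
          orb <- catalog@nodeLUT[[length(S)]][sub + 1L, pos]
          if (!is.na(orb)) touched <- union(touched, orb)
        }
      }
      deps[x + 1L] <- length(touched)
    }
  }
  deps
}

## Same idea for node-pair orbits, via the non-edge representative pair.
.pairDependencies <- function(catalog) {
  deps <- integer(catalog@totals[["pair"]])
  for (g in catalog@graphlets) {
    if (g$k < 3L) next
    pairs <- .pairsOf(g$k)
    for (po in unique(stats::na.omit(g$posNonEdgeOrbit))) {
      p <- which(g$posNonEdgeOrbit == po)[1L]
      x <- pairs[1L, p]; y <- pairs[2L, p]
      touched <- integer(0)
      others <- setdiff(0:(g$k - 1L), c(x, y))
      for (s in 0:length(others)) {
        if (s > 0L) combs <- utils::combn(others, s, simplify = FALSE)
        else combs <- list(integer(0))
        for (S0 in combs) {
          S <- sort(c(x, y, S0))
          sub <- .inducedMask(g$mask, S, pairs)
          pp <- .pairPos(match(x, S) - 1L, match(y, S) - 1L)
          orb <- catalog@nonEdgeLUT[[length(S)]][sub + 1L, pp]
          if (!is.na(orb)) touched <- union(touched, orb)
        }
      }
      deps[po] <- length(touched)
    }
  }
  deps
}

## ---- accessors -------------------------------------------------------------

#' Orbit totals of a catalog
#'
#' @param catalog a [GraphletCatalog-class].
#' @return Named integer vector with the number of distinct node, edge,
#'   non-edge, and node-pair orbits.
#' @export
orbitCounts <- function(catalog) {
  stopifnot(is(catalog, "GraphletCatalog"))
  catalog@totals
}

#' @rdname orbitCounts
#' @export
nodeOrbitCount <- function(catalog) orbitCounts(catalog)[["node"]]

#' @rdname orbitCounts
#' @export
edgeOrbitCount <- function(catalog) orbitCounts(catalog)[["edge"]]

#' @rdname orbitCounts
#' @export
nonEdgeOrbitCount <- function(catalog) orbitCounts(catalog)[["nonEdge"]]

#' @rdname orbitCounts
#' @export
pairOrbitCount <- function(catalog) orbitCounts(catalog)[["pair"]]

#' Node-pair orbit reconciliation map
#'
#' One row per node-pair orbit: the graphlet and non-edge orbit on the
#' unlinked side, the graphlet and edge orbit reached by adding the
#' missing edge, and the density of that edge-completed graphlet.
#'
#' @param catalog a [GraphletCatalog-class].
#' @return A data.frame with columns `pairOrbit`, `neGraphlet`,
#'   `nonEdgeOrbit`, `edgeGraphlet`, `edgeOrbit`, `density`.
#' @export
pairOrbitMap <- function(catalog) {
  stopifnot(is(catalog, "GraphletCatalog"))
  catalog@pairMap
}

#' Graphlet densities per node-pair orbit
#'
#' Density of the edge-completed graphlet of each node-pair orbit,
#' `2 m / (n (n - 1))`; complete graphlets have density 1. Used by the
#' density-weighted node-pair-GDV-centrality to favour dense shared
#' graphlets (e.g. 4-cliques) over sparse ones (e.g. 4-paths).
#'
#' @param catalog a [GraphletCatalog-class].
#' @return Numeric vector of length [pairOrbitCount()].
#' @export
graphletDensities <- function(catalog) {
  stopifnot(is(catalog, "GraphletCatalog"))
  catalog@density
}

#' Orbit weights accounting for orbit dependencies
#'
#' Weight of orbit `i` is `1 - log(o_i) / log(N)`, where `o_i` is the
#' number of distinct orbits whose touching is implied by touching orbit
#' `i` within its own graphlet (itself included) and `N` is the total
#' number of orbits of that taxonomy in the catalog. Redundant orbits
#' (those implying many others) are down-weighted; with a single orbit
#' the weight is 1.
#'
#' @param catalog a [GraphletCatalog-class].
#' @param type `"node"` for node-orbit weights (used by
#'   node-GDV-similarity) or `"pair"` for node-pair-orbit weights (used
#'   by node-pair-GDV-centrality).
#' @param override optional numeric vector replacing the computed
#'   weights (e.g. a published weight table); must have one positive
#'   entry per orbit.
#' @return Numeric vector of weights in (0, 1] (or the override).
#' @export
orbitWeights <- function(catalog, type = c("node", "pair"), override = NULL) {
  stopifnot(is(catalog, "GraphletCatalog"))
  type <- match.arg(type)
  n <- if (type == "node") nodeOrbitCount(catalog) else pairOrbitCount(catalog)
  if (!is.null(override)) {
    if (length(override) != n || any(!is.finite(override)) || any(override <= 0))
      stop("weight override must supply one positive finite weight per orbit")
    return(as.numeric(override))
  }
  o <- if (type == "node") catalog@nodeDeps else catalog@pairDeps
  if (n == 1L) return(1)
  1 - log(o) / log(n)
}

#' Reference table of the catalog
#'
#' Tab-separable dump of the canonical numbering: one row per graphlet
#' with its adjacency (as `i-j` pairs), automorphism count, and the
#' global node, edge, and non-edge orbit indices it carries.
#'
#' @param catalog a [GraphletCatalog-class].
#' @return A data.frame, one row per graphlet.
#' @export
catalogTable <- function(catalog) {
  stopifnot(is(catalog, "GraphletCatalog"))
  do.call(rbind, lapply(catalog@graphlets, function(g) {
    pairs <- .pairsOf(g$k)
    edges <- which(vapply(seq_len(ncol(pairs)),
                          function(p) .maskBit(g$mask, p) == 1L, logical(1)))
    data.frame(
      graphlet = g$id, nodes = g$k, edges = g$eCount,
      adjacency = paste(sprintf("%d-%d", pairs[1L, edges], pairs[2L, edges]),
                        collapse = ","),
      automorphisms = g$autCount,
      nodeOrbits = paste(sort(unique(g$nodeOrbit)), collapse = ","),
      edgeOrbits = paste(sort(unique(stats::na.omit(g$posEdgeOrbit))),
                         collapse = ","),
      nonEdgeOrbits = paste(sort(unique(stats::na.omit(g$posNonEdgeOrbit))),
                            collapse = ",")
    )
  }))
}

setMethod("show", "GraphletCatalog", function(object) {
  tot <- object@totals
  cat(sprintf("GraphletCatalog (2-%d-node graphlets)\n", object@maxNodes))
  cat(sprintf("  %d graphlets; %d node, %d edge, %d non-edge, %d node-pair orbits\n",
              length(object@graphlets), tot[["node"]], tot[["edge"]],
              tot[["nonEdge"]], tot[["pair"]]))
})
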