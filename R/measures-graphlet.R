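## Pair-score tables are plain data.frames with columns u, v, score (one
## row per unordered node pair, u before v in radix order) and a
## "measure" attribute naming their provenance.

.scoreTable <- function(pairs, score, measure) {
  if (any(!is.finite(score)))
    stop("non-finite scores produced by measure '", measure, "'")
  out <- data.frame(u = pairs[, 1L], v = pairs[, 2L], score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "measure") <- measure
  out
}

#' Node-GDV-similarity of two nodes
#'
#' Weighted log-scale agreement of two node graphlet degree vectors.
#' The per-orbit distance is
#' `D_i = w_i * |log(u_i + 1) - log(v_i + 1)| / log(max(u_i, v_i) + 2)`,
#' the total distance is `sum(D_i) / sum(w_i)`, and the similarity is
#' one minus the total distance. The log damps counts that differ by
#' orders of magnitude; weights down-weight redundant orbits. The result
#' is in \[0, 1\], symmetric, and equals 1 exactly when the two vectors
#' are identical.
#'
#' @param gdvU,gdvV node GDVs (rows of [countNodeGDV()]) of equal
#'   length.
#' @param weights per-orbit weights, e.g. `orbitWeights(catalog,
#'   "node")`.
#' @return Similarity in \[0, 1\].
#' @export
gdvSimilarity <- function(gdvU, gdvV, weights) {
  if (length(gdvU) != length(gdvV) || length(gdvU) != length(weights))
    stop("GDVs and weights must have one entry per node orbit")
  d <- weights * abs(log(gdvU + 1) - log(gdvV + 1)) /
    log(pmax(gdvU, gdvV) + 2)
  1 - sum(d) / sum(weights)
}

#' Node-pair-GDV-centrality
#'
#' Size of the shared extended neighbourhood of a node pair: a weighted
#' sum of log-damped node-pair orbit counts,
#' `C = sum_i d_i * w_i * log(c_i + 1)`, with `d_i = 1` for the
#' unweighted variant and the edge-completed graphlet density for the
#' density-weighted variant (which favours dense shared graphlets such
#' as cliques over sparse ones such as paths). Strictly increasing in
#' every orbit count; zero for an all-zero pair GDV. With the 3-node
#' catalog there is a single pair orbit of density one, so the weighted
#' and unweighted variants coincide and the ranking equals the
#' shared-neighbours ranking.
#'
#' @param pairGDV a pair-GDV matrix ([countPairGDV()]) or single vector.
#' @param weights per-pair-orbit weights, e.g. `orbitWeights(catalog,
#'   "pair")`.
#' @param density optional per-orbit densities
#'   ([graphletDensities()]) enabling the density-weighted variant.
#' @return Numeric vector of non-negative centralities (one per row, or
#'   length one for a vector input).
#' @export
pairCentrality <- function(pairGDV, weights, density = NULL) {
  if (is.null(dim(pairGDV))) pairGDV <- matrix(pairGDV, nrow = 1L)
  if (ncol(pairGDV) != length(weights))
    stop("pair GDV and weights must have one entry per node-pair orbit")
  w <- weights
  if (!is.null(density)) {
    if (length(density) != length(weights))
      stop("densities must have one entry per node-pair orbit")
    w <- w * density
  }
  as.numeric(log(pairGDV + 1) %*% w)
}

#' Combined graphlet link-prediction score
#'
#' Scores every unordered node pair as
#' `alpha * Chat(u, v) + (1 - alpha) * S(u, v)`, where `S` is
#' node-GDV-similarity and `Chat` is node-pair-GDV-centrality min-max
#' normalised to \[0, 1\] over all pairs of the network. `alpha = 0`
#' uses similarity alone (link topologically similar nodes),
#' `alpha = 1` centrality alone (link nodes sharing many graphlets);
#' intermediate values favour pairs with both properties. The amount of
#' topology used is set by the catalog size (3-, 3-4-, or 3-5-node
#' graphlets).
#'
#' @param net an undirected simple named igraph network.
#' @param catalog a [GraphletCatalog-class]; its `maxNodes` selects the
#'   graphlet sizes used.
#' @param alpha mixing weight in \[0, 1\].
#' @param weighted use density-weighted centrality.
#' @param nodeWeights,pairWeights optional overrides for the orbit
#'   weights (defaults derive from the catalog's dependency counts).
#' @return A pair-score table (data.frame `u`, `v`, `score`).
#' @examples
#' net <- makeNetwork("geometric", n = 25, param = 0.3, seed = 2)
#' head(rankPairs(combinedScores(net, alpha = 0.8)))
#' @export
combinedScores <- function(net, catalog = buildCatalog(5L), alpha = 0.8,
                           weighted = TRUE, nodeWeights = NULL,
                           pairWeights = NULL) {
  if (length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("'alpha' must be a single value in [0, 1]")
  .checkNetwork(net)
  net <- canonicalNetwork(net)
  pairs <- .allPairs(net)
  nPairs <- nrow(pairs)
  if (nPairs == 0L)
    return(.scoreTable(pairs, numeric(0), "gdv"))

  sim <- rep(0, nPairs)
  if (alpha < 1) {
    w <- orbitWeights(catalog, "node", override = nodeWeights)
    gdv <- countNodeGDV(net, catalog)
    L <- log(gdv + 1)
    nm <- igraph::V(net)$name
    iIdx <- match(pairs[, 1L], nm)
    jIdx <- match(pairs[, 2L], nm)
    sw <- sum(w)
    sim <- vapply(seq_len(nPairs), function(r) {
      i <- iIdx[r]; j <- jIdx[r]
      1 - sum(w * abs(L[i, ] - L[j, ]) / log(pmax(gdv[i, ], gdv[j, ]) + 2)) / sw
    }, numeric(1))
  }
  cent <- rep(0, nPairs)
  if (alpha > 0) {
    wp <- orbitWeights(catalog, "pair", override = pairWeights)
    pg <- countPairGDV(net, catalog)
    cent <- pairCentrality(pg, wp,
                           density = if (weighted) graphletDensities(catalog))
    rng <- range(cent)
    cent <- if (rng[2L] > rng[1L]) (cent - rng[1L]) / (rng[2L] - rng[1L])
            else rep(0, nPairs)
  }
  .scoreTable(pairs, alpha * cent + (1 - alpha) * sim,
              sprintf("gdv(alpha=%g,%s,g%d)", alpha,
                      if (weighted) "weighted" else "unweighted",
                      catalog@maxNodes))
}
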