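#' @importFrom Matrix Diagonal crossprod
NULL

## Shared scaffolding: canonicalize the network, enumerate all unordered
## pairs, pull the (u, v) entries of a symmetric score matrix.
.pairIdx <- function(net) {
  pairs <- .allPairs(net)
  nm <- igraph::V(net)$name
  list(pairs = pairs, i = match(pairs[, 1L], nm), j = match(pairs[, 2L], nm))
}

.matrixScores <- function(net, M, measure) {
  px <- .pairIdx(net)
  s <- if (nrow(px$pairs)) as.numeric(M[cbind(px$i, px$j)]) else numeric(0)
  .scoreTable(px$pairs, s, measure)
}

#' Classical link-prediction measures
#'
#' The baseline scores against which the graphlet measures are compared.
#' All score every unordered node pair of the network (existing edges
#' included, so the tables can also flag spurious edges during
#' de-noising) and are symmetric in the pair:
#'
#' * `dpScores` — degree product `d(u) * d(v)` (preferential
#'   attachment).
#' * `snScores` — shared neighbours `|N(u) ∩ N(v)|`.
#' * `jcScores` — Jaccard coefficient
#'   `|N(u) ∩ N(v)| / |N(u) ∪ N(v)|` (0 when both neighbourhoods are
#'   empty).
#' * `aaScores` — Adamic–Adar `sum_z 1 / log d(z)` over shared
#'   neighbours `z` (a shared neighbour always has degree >= 2).
#' * `raiScores` — resource allocation `sum_z 1 / d(z)`.
#' * `katzScores` — Katz index `sum_l beta^l * (walks of length l)`,
#'   by the closed-form resolvent `(I - beta A)^{-1} - I` or the
#'   truncated series when `maxLength` is given. The closed form
#'   requires `beta` below the reciprocal spectral radius.
#' * `lpiScores` — local path index `(A^2)_{uv} + epsilon (A^3)_{uv}`,
#'   a trade-off between shared neighbours (length-2 walks only) and
#'   Katz (all lengths).
#'
#' @param net an undirected simple named igraph network.
#' @param beta Katz damping factor (default 0.005).
#' @param maxLength optional Katz truncation: use walks up to this
#'   length instead of the closed form.
#' @param epsilon weight of the length-3 term in the local path index
#'   (default 0.005; `epsilon = 0` ranks identically to shared
#'   neighbours).
#' @return A pair-score table (data.frame `u`, `v`, `score`).
#' @name baselineMeasures
NULL

#' @rdname baselineMeasures
#' @export
dpScores <- function(net) {
  net <- canonicalNetwork(net)
  d <- igraph::degree(net)
  px <- .pairIdx(net)
  .scoreTable(px$pairs, d[px$i] * d[px$j], "dp")
}

#' @rdname baselineMeasures
#' @export
snScores <- function(net) {
  net <- canonicalNetwork(net)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  .matrixScores(net, A %*% A, "sn")
}

#' @rdname baselineMeasures
#' @export
jcScores <- function(net) {
  net <- canonicalNetwork(net)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  d <- igraph::degree(net)
  px <- .pairIdx(net)
  sn <- if (nrow(px$pairs)) as.numeric((A %*% A)[cbind(px$i, px$j)])
        else numeric(0)
  den <- d[px$i] + d[px$j] - sn
  .scoreTable(px$pairs, ifelse(den > 0, sn / den, 0), "jc")
}

.weightedSN <- function(net, weightFun, measure) {
  net <- canonicalNetwork(net)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  d <- igraph::degree(net)
  w <- ifelse(d >= 2, weightFun(d), 0)   # a shared neighbour has degree >= 2
  .matrixScores(net, A %*% Diagonal(x = w) %*% A, measure)
}

#' @rdname baselineMeasures
#' @export
aaScores <- function(net) .weightedSN(net, function(d) 1 / log(d), "aa")

#' @rdname baselineMeasures
#' @export
raiScores <- function(net) .weightedSN(net, function(d) 1 / d, "rai")

#' @rdname baselineMeasures
#' @export
katzScores <- function(net, beta = 0.005, maxLength = NULL) {
  if (beta <= 0) stop("'beta' must be positive")
  net <- canonicalNetwork(net)
  n <- igraph::vcount(net)
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = TRUE))
  if (is.null(maxLength)) {
    rho <- if (n > 0 && igraph::ecount(net) > 0)
      max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values)) else 0
    if (beta * rho >= 1)
      stop(sprintf(
        "Katz closed form diverges: beta must be below 1/spectral radius = %.6g",
        1 / rho))
    M <- solve(diag(n) - beta * A) - diag(n)
  } else {
    M <- matrix(0, n, n)
    P <- diag(n)
    for (l in seq_len(maxLength)) {
      P <- P %*% A
      M <- M + beta^l * P
    }
  }
  .matrixScores(net, M, sprintf("katz(beta=%g)", beta))
}

#' @rdname baselineMeasures
#' @export
lpiScores <- function(net, epsilon = 0.005) {
  net <- canonicalNetwork(net)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A2 <- A %*% A
  .matrixScores(net, A2 + epsilon * (A2 %*% A),
                sprintf("lpi(epsilon=%g)", epsilon))
}

## ---- measure registry ------------------------------------------------------

#' Available link-prediction measures
#'
#' @return Character vector of measure names accepted by [scorePairs()].
#' @export
measureRegistry <- function() {
  c("dp", "sn", "jc", "aa", "katz", "lpi", "rai", "gdv")
}

#' Score all node pairs with a named measure
#'
#' Uniform entry point over the classical baselines and the combined
#' graphlet measure; externally computed score tables (e.g. from other
#' tools) can be used anywhere a pair-score table is expected, since
#' tables are plain data.frames.
#'
#' @param net an undirected simple named igraph network.
#' @param measure a name from [measureRegistry()].
#' @param ... measure parameters: `beta`/`maxLength` for Katz,
#'   `epsilon` for LPI, `alpha`/`weighted`/`catalog` for the graphlet
#'   measure.
#' @return A pair-score table (data.frame `u`, `v`, `score`).
#' @export
scorePairs <- function(net, measure, ...) {
  fns <- list(dp = dpScores, sn = snScores, jc = jcScores, aa = aaScores,
              katz = katzScores, lpi = lpiScores, rai = raiScores,
              gdv = combinedScores)
  if (length(measure) != 1L || !measure %in% names(fns))
    stop("unknown measure '", measure, "'; available: ",
         paste(measureRegistry(), collapse = ", "))
  fns[[measure]](net, ...)
}
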