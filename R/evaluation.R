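#' @importFrom stats t.test sd
NULL

## ---- noise injection -------------------------------------------------------

#' Remove a random fraction of edges
#'
#' Draws `round(fraction * |E|)` edges uniformly without replacement and
#' removes them, keeping the node set unchanged. Fully deterministic
#' given the seed. Fractions above 0.5 are allowed with a warning (the
#' usual evaluation range is 5%-50%).
#'
#' @param net an undirected simple named igraph network.
#' @param fraction fraction of edges to remove, in (0, 1].
#' @param seed integer seed.
#' @return A list of class `noiseReplicate`: `noisy` (the degraded
#'   network), `removed` (2-column character matrix of removed edges),
#'   `fraction`, `seed`.
#' @export
removeEdges <- function(net, fraction, seed) {
  .checkNetwork(net)
  if (length(fraction) != 1L || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  if (fraction > 0.5)
    warning("removing more than half of the edges; outside the usual range")
  net <- canonicalNetwork(net)
  m <- round(fraction * igraph::ecount(net))
  drop <- withr::with_seed(as.integer(seed),
                           sample(igraph::ecount(net), m))
  el <- igraph::as_edgelist(net, names = TRUE)[drop, , drop = FALSE]
  structure(list(noisy = igraph::delete_edges(net, drop),
                 removed = el, fraction = fraction, seed = as.integer(seed)),
            class = "noiseReplicate")
}

## ---- ranking ---------------------------------------------------------------

#' Rank a pair-score table
#'
#' Descending score, ties broken lexicographically on (u, v) in radix
#' order, so the ranking is deterministic and independent of the input
#' row order.
#'
#' @param scores a pair-score table (data.frame `u`, `v`, `score`).
#' @return The table reordered, with a `rank` column added.
#' @export
rankPairs <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("u", "v", "score") %in% names(scores)))
  ord <- order(-scores$score, scores$u, scores$v, method = "radix")
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## ---- evaluation curves -----------------------------------------------------

#' LPEval: confusion statistics and ranking areas for one measure
#'
#' Produced by [evalCurve()]. Holds the per-k confusion table on the
#' 0-100% prediction grid together with AUROC and AUPR computed at full
#' ranking resolution.
#'
#' @slot table data.frame with one row per k (0-100%): predicted pair
#'   count, TP, FP, TN, FN, precision, recall, fscore, sensitivity,
#'   specificity.
#' @slot auroc,aupr areas under the receiver-operator and
#'   precision-recall curves over the complete ranking.
#' @slot nPositives,totalPairs the evaluation margins.
#' @export
setClass("LPEval",
  representation(table = "data.frame", auroc = "numeric", aupr = "numeric",
                 nPositives = "integer", totalPairs = "integer"))

setValidity("LPEval", function(object) {
  msg <- character(0)
  if (length(object@auroc) != 1L || object@auroc < 0 || object@auroc > 1)
    msg <- c(msg, "auroc must be a single value in [0, 1]")
  if (length(object@aupr) != 1L || object@aupr < 0 || object@aupr > 1)
    msg <- c(msg, "aupr must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname LPEval-class
#' @param object,eval an `LPEval`.
#' @export
auroc <- function(eval) { stopifnot(is(eval, "LPEval")); eval@auroc }

#' @rdname LPEval-class
#' @export
aupr <- function(eval) { stopifnot(is(eval, "LPEval")); eval@aupr }

#' @rdname LPEval-class
#' @export
curveTable <- function(eval) { stopifnot(is(eval, "LPEval")); eval@table }

setMethod("show", "LPEval", function(object) {
  cat(sprintf("LPEval: %d positives / %d pairs; AUROC %.4f, AUPR %.4f\n",
              object@nPositives, object@totalPairs, object@auroc, object@aupr))
})

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Confusion statistics and areas for a ranked prediction
#'
#' Ranks the score table ([rankPairs()] order), then, for each k from
#' 0% to 100% in 1% steps, predicts the top `round(k% * totalPairs)`
#' pairs as edges and counts TP/FP/TN/FN against the positive set,
#' deriving precision (1 at k = 0 by convention), recall, F-score
#' (0 when precision + recall is 0), sensitivity, and specificity.
#' AUROC and AUPR are computed by the trapezoid rule over the complete
#' ranking (every rank, not just the percent grid), so a ranking that
#' places all positives first scores exactly 1.
#'
#' @param scores a pair-score table covering all evaluated pairs.
#' @param positives the ground-truth edges: a 2-column character matrix
#'   or an igraph network. Must be non-empty and a subset of the scored
#'   pairs.
#' @return An [LPEval-class].
#' @export
evalCurve <- function(scores, positives) {
  ranked <- rankPairs(scores)
  total <- nrow(ranked)
  posKeys <- if (igraph::is_igraph(positives)) .edgeKeys(positives)
             else .pairKeys(positives[, 1L], positives[, 2L])
  posKeys <- unique(posKeys)
  if (length(posKeys) == 0L)
    stop("empty positive set: recall is undefined")
  keys <- paste(ranked$u, ranked$v, sep = "\t")
  y <- keys %in% posKeys
  if (sum(y) != length(posKeys))
    stop("positives must be a subset of the scored pairs")
  P <- length(posKeys); N <- total - P
  cumTP <- cumsum(y)

  ## full-resolution areas
  tpr <- c(0, cumTP / P)
  fpr <- c(0, (seq_len(total) - cumTP) / max(N, 1L))
  aurocVal <- if (N > 0) .trapz(fpr, tpr) else 1
  rec <- c(0, cumTP / P)
  prec <- c(1, cumTP / seq_len(total))
  auprVal <- .trapz(rec, prec)

  ## 1%-grid confusion table
  k <- 0:100
  npred <- round(k / 100 * total)
  TP <- c(0L, cumTP)[npred + 1L]
  FP <- npred - TP
  FN <- P - TP
  TN <- total - npred - FN
  precision <- ifelse(npred == 0L, 1, TP / npred)
  recall <- TP / P
  fscore <- ifelse(precision + recall > 0,
                   2 * precision * recall / (precision + recall), 0)
  specificity <- if (N > 0) TN / N else rep(1, length(TN))
  tab <- data.frame(k = k, predicted = npred, TP = TP, FP = FP, TN = TN,
                    FN = FN, precision = precision, recall = recall,
                    fscore = fscore, sensitivity = recall,
                    specificity = specificity)
  new("LPEval", table = tab, auroc = aurocVal, aupr = auprVal,
      nPositives = as.integer(P), totalPairs = as.integer(total))
}

#' Average evaluation curves over replicates
#'
#' Pointwise mean of the per-k confusion statistics together with the
#' mean of the per-replicate areas (the per-replicate areas, not the
#' area of the mean curve, are what the paired t-test compares).
#'
#' @param curves list of [LPEval-class] objects with identical margins.
#' @return An [LPEval-class] holding the means.
#' @export
replicateMean <- function(curves) {
  stopifnot(length(curves) >= 1L, all(vapply(curves, is, logical(1), "LPEval")))
  tabs <- lapply(curves, curveTable)
  base <- tabs[[1L]]
  num <- Reduce(`+`, lapply(tabs, function(t) as.matrix(t[-1L]))) / length(tabs)
  tab <- cbind(base["k"], as.data.frame(num))
  new("LPEval", table = tab,
      auroc = mean(vapply(curves, auroc, numeric(1))),
      aupr = mean(vapply(curves, aupr, numeric(1))),
      nPositives = curves[[1L]]@nPositives,
      totalPairs = curves[[1L]]@totalPairs)
}

#' Paired t-test on replicate AUROCs
#'
#' Two-sided paired t-test on the per-replicate area differences of two
#' measures. When the differences have zero variance the t statistic is
#' undefined; the p-value is then reported as 1 if the replicates are
#' identical and 0 otherwise (a degenerate, flagged case).
#'
#' @param a,b numeric vectors of per-replicate AUROCs (equal length,
#'   at least 2).
#' @return Two-sided p-value.
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need two equal-length replicate vectors of length >= 2")
  d <- a - b
  if (sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
    if (mean(d) != 0)
      warning("zero-variance, non-zero difference: p-value degenerates to 0")
    return(if (mean(d) == 0) 1 else 0)
  }
  t.test(a, b, paired = TRUE)$p.value
}

## ---- de-noising ------------------------------------------------------------

#' De-noise a network from a score table
#'
#' Replaces the edge set by the top-`m` ranked node pairs (default:
#' keep the original edge count), over the original node set. Existing
#' edges ranked low are removed (spurious-edge cleanup) and high-ranked
#' non-edges are added (missing-edge recovery).
#'
#' @param net the original network (provides the node set and default
#'   `m`).
#' @param scores a pair-score table over the network's pairs.
#' @param m number of edges in the de-noised network.
#' @return An igraph network on the same node set.
#' @export
denoiseNetwork <- function(net, scores, m = igraph::ecount(net)) {
  .checkNetwork(net)
  if (m < 0) stop("'m' must be non-negative")
  if (m > nrow(scores)) stop("'m' exceeds the number of scored pairs")
  net <- canonicalNetwork(net)
  top <- rankPairs(scores)[seq_len(m), , drop = FALSE]
  nodes <- igraph::V(net)$name
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (m > 0)
    g <- igraph::add_edges(g, rbind(match(top$u, nodes), match(top$v, nodes)))
  canonicalNetwork(g)
}

#' Edge-set intersection of two networks
#'
#' @param a,b networks.
#' @return List with `shared` (number of common edges) and `jaccard`
#'   (Jaccard index of the edge sets; 0 when both are empty).
#' @export
intersectEdges <- function(a, b) {
  ka <- .edgeKeys(a); kb <- .edgeKeys(b)
  shared <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  list(shared = shared, jaccard = if (uni > 0) shared / uni else 0)
}

## ---- reference scorers for harness calibration -----------------------------

#' Oracle and random reference scorers
#'
#' `oracleScores` scores 1 for pairs in the given positive set and 0
#' otherwise (a perfect ranking up to ties); `randomScores` draws iid
#' uniform scores from a seed. Both are used to calibrate the
#' evaluation harness (AUROC 1.0 and ~0.5 respectively).
#'
#' @param net an undirected simple named igraph network.
#' @param positives edges to score 1: a network or 2-column character
#'   matrix.
#' @param seed integer seed for the random scorer.
#' @return A pair-score table.
#' @export
oracleScores <- function(net, positives) {
  net <- canonicalNetwork(net)
  pairs <- .allPairs(net)
  posKeys <- if (igraph::is_igraph(positives)) .edgeKeys(positives)
             else .pairKeys(positives[, 1L], positives[, 2L])
  keys <- paste(pairs[, 1L], pairs[, 2L], sep = "\t")
  .scoreTable(pairs, as.numeric(keys %in% posKeys), "oracle")
}

#' @rdname oracleScores
#' @export
randomScores <- function(net, seed) {
  net <- canonicalNetwork(net)
  pairs <- .allPairs(net)
  s <- withr::with_seed(as.integer(seed), stats::runif(nrow(pairs)))
  .scoreTable(pairs, s, "random")
}
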