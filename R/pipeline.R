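## End-to-end evaluation pipelines: synthetic-noise reconstruction,
## external ground truth, and de-noising with biological scoring.

.resolveMeasures <- function(measures, measureArgs = list()) {
  if (is.list(measures) && !is.null(names(measures))) {
    stopifnot(all(vapply(measures, is.function, logical(1))))
    return(measures)
  }
  stopifnot(is.character(measures))
  setNames(lapply(measures, function(m) {
    args <- measureArgs[[m]]
    function(net) do.call(scorePairs, c(list(net = net, measure = m), args))
  }), measures)
}

#' Synthetic-noise reconstruction evaluation
#'
#' For each noise fraction, removes edges at random (replicate seeds
#' `seed + 0 ... seed + nReplicates - 1`), scores all pairs of the
#' degraded network with each measure, and evaluates the ranking
#' against the original edges as ground truth. Reports per-replicate
#' AUROC/AUPR, their means and standard deviations, and pairwise paired
#' t-tests on the replicate AUROCs at each noise level.
#'
#' @param net the original network.
#' @param measures character vector of names from [measureRegistry()],
#'   or a named list of scoring functions `function(net)` returning a
#'   pair-score table (the hook for externally computed measures).
#' @param fractions noise fractions to test.
#' @param nReplicates random removals per fraction (default 5).
#' @param seed master seed; all randomness derives from it.
#' @param measureArgs named list of per-measure argument lists, e.g.
#'   `list(gdv = list(alpha = 0.8, catalog = cat5))`.
#' @return List of class `noiseEvalReport`: `results` (one row per
#'   measure x fraction x replicate), `summary` (means and sds),
#'   `ttests` (pairwise paired t p-values per fraction), `config`.
#' @export
runNoiseEvaluation <- function(net, measures = c("sn", "gdv"),
                               fractions = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.5),
                               nReplicates = 5L, seed = 1L,
                               measureArgs = list()) {
  .checkNetwork(net)
  net <- canonicalNetwork(net)
  fns <- .resolveMeasures(measures, measureArgs)
  positives <- igraph::as_edgelist(net, names = TRUE)
  rows <- list()
  for (fr in fractions) {
    for (r in seq_len(nReplicates)) {
      rep_ <- removeEdges(net, fr, seed + r - 1L)
      for (m in names(fns)) {
        ev <- evalCurve(fns[[m]](rep_$noisy), positives)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, fraction = fr, replicate = r, seed = rep_$seed,
          auroc = auroc(ev), aupr = aupr(ev))
      }
    }
  }
  results <- do.call(rbind, rows)
  summary_ <- do.call(rbind, lapply(split(results,
      list(results$measure, results$fraction), drop = TRUE), function(d)
    data.frame(measure = d$measure[1L], fraction = d$fraction[1L],
               meanAUROC = mean(d$auroc), sdAUROC = sd(d$auroc),
               meanAUPR = mean(d$aupr), sdAUPR = sd(d$aupr))))
  rownames(summary_) <- NULL
  tt <- list()
  ms <- names(fns)
  if (length(ms) >= 2L && nReplicates >= 2L) {
    for (fr in fractions) {
      for (i in seq_len(length(ms) - 1L)) for (j in (i + 1L):length(ms)) {
        a <- results$auroc[results$measure == ms[i] & results$fraction == fr]
        b <- results$auroc[results$measure == ms[j] & results$fraction == fr]
        tt[[length(tt) + 1L]] <- data.frame(
          fraction = fr, measureA = ms[i], measureB = ms[j],
          pValue = pairedTTest(a, b))
      }
    }
  }
  structure(list(results = results, summary = summary_,
                 ttests = if (length(tt)) do.call(rbind, tt) else NULL,
                 config = list(measures = ms, fractions = fractions,
                               nReplicates = nReplicates, seed = seed)),
            class = "noiseEvalReport")
}

#' Evaluation against an external ground truth
#'
#' Scores all pairs of the input network (no noise injection) and
#' evaluates each measure's ranking against a user-supplied positive
#' set, e.g. low-confidence interactions accompanying a high-confidence
#' network.
#'
#' @inheritParams runNoiseEvaluation
#' @param groundTruth the positive edges: an igraph network or 2-column
#'   character matrix. Edges whose endpoints are not both in `net` are
#'   dropped with a message; the remainder must be non-empty.
#' @return List of class `truthEvalReport`: `curves` (named list of
#'   [LPEval-class]), `summary` (AUROC/AUPR per measure), `config`.
#' @export
runTruthEvaluation <- function(net, groundTruth, measures = c("sn", "gdv"),
                               measureArgs = list()) {
  .checkNetwork(net)
  net <- canonicalNetwork(net)
  el <- .asEdgeMatrix(groundTruth)
  nm <- igraph::V(net)$name
  ok <- el[, 1L] %in% nm & el[, 2L] %in% nm & el[, 1L] != el[, 2L]
  if (any(!ok))
    message(sprintf("runTruthEvaluation: dropped %d ground-truth edge(s) outside the network",
                    sum(!ok)))
  el <- el[ok, , drop = FALSE]
  if (nrow(el) == 0L) stop("ground truth shares no usable edges with the network")
  fns <- .resolveMeasures(measures, measureArgs)
  curves <- lapply(fns, function(f) evalCurve(f(net), el))
  summary_ <- data.frame(measure = names(fns),
                         auroc = vapply(curves, auroc, numeric(1)),
                         aupr = vapply(curves, aupr, numeric(1)),
                         row.names = NULL)
  structure(list(curves = curves, summary = summary_,
                 config = list(measures = names(fns))),
            class = "truthEvalReport")
}

#' De-noising evaluation with biological scoring
#'
#' Applies each measure to the original network, replaces the edge set
#' by the top-ranked pairs (keeping the original edge count), and
#' scores biological correctness: GO-term sharing enrichment of the
#' original versus each de-noised network, pairwise edge-set
#' intersections among the de-noised networks, and, when a reference
#' network is supplied, hypergeometric validation of the newly
#' predicted edges against it.
#'
#' @inheritParams runNoiseEvaluation
#' @param ann annotation table (named list of term vectors); must
#'   annotate at least one node.
#' @param reference optional independent reference network for
#'   validating new edges.
#' @return List of class `denoiseEvalReport`: `enrichment` (data.frame
#'   incl. an `original` row), `intersections` (Jaccard matrix over
#'   original + de-noised networks), `validation` (per-measure
#'   `enrichmentResult` or NULL), `denoised` (named list of networks),
#'   `config`.
#' @export
runDenoiseEvaluation <- function(net, ann, measures = c("sn", "gdv"),
                                 reference = NULL, measureArgs = list()) {
  .checkNetwork(net)
  net <- canonicalNetwork(net)
  if (length(ann) == 0L) stop("annotation table is empty")
  fns <- .resolveMeasures(measures, measureArgs)
  denoised <- lapply(fns, function(f)
    denoiseNetwork(net, f(net)))
  nets <- c(list(original = net), denoised)
  enr <- do.call(rbind, lapply(names(nets), function(nmm) {
    e <- goEnrichment(nets[[nmm]], ann, universe = net)
    data.frame(measure = nmm, eligible = e$eligible, hits = e$hits,
               fraction = e$fraction, pValue = e$pValue)
  }))
  k <- length(nets)
  inter <- matrix(1, k, k, dimnames = list(names(nets), names(nets)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    inter[i, j] <- inter[j, i] <- intersectEdges(nets[[i]], nets[[j]])$jaccard
  }
  validation <- NULL
  if (!is.null(reference)) {
    origKeys <- .edgeKeys(net)
    validation <- lapply(denoised, function(d) {
      newKeys <- setdiff(.edgeKeys(d), origKeys)
      el <- do.call(rbind, strsplit(newKeys, "\t", fixed = TRUE))
      if (is.null(el)) el <- matrix(character(0), ncol = 2L)
      externalValidation(el, net, reference)
    })
  }
  structure(list(enrichment = enr, intersections = inter,
                 validation = validation, denoised = denoised,
                 config = list(measures = names(fns))),
            class = "denoiseEvalReport")
}

#' Write a reproducibility manifest
#'
#' JSON record of a run's configuration, seeds, and software versions,
#' sufficient to reproduce outputs bit-for-bit.
#'
#' @param config named list of run parameters (seeds included).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeManifest <- function(config, path) {
  manifest <- c(config,
                list(package = "graphletLP",
                     packageVersion = as.character(utils::packageVersion("graphletLP")),
                     rVersion = R.version.string))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
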