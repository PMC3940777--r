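#' Seeded synthetic test networks
#'
#' Deterministic generators for the random-graph models used to exercise
#' every stage of the package without external data: Erdős–Rényi
#' G(n, p), Barabási–Albert preferential attachment, random geometric
#' graphs on the unit square, and a ring with random chords. Identical
#' arguments always give the identical network.
#'
#' @param model one of `"erdos_renyi"`, `"barabasi_albert"`,
#'   `"geometric"`, `"ring_chords"`.
#' @param n number of nodes (at least 2).
#' @param param density parameter: edge probability for Erdős–Rényi,
#'   edges added per step for Barabási–Albert, connection radius for the
#'   geometric model, number of random chords for the ring model.
#' @param seed integer seed; all randomness derives from it.
#' @return An undirected simple igraph network with zero-padded vertex
#'   names (`v01`, `v02`, ...) in canonical order.
#' @examples
#' net <- makeNetwork("geometric", n = 30, param = 0.25, seed = 7)
#' igraph::ecount(net)
#' @export
makeNetwork <- function(model = c("erdos_renyi", "barabasi_albert",
                                  "geometric", "ring_chords"),
                        n, param, seed) {
  model <- match.arg(model)
  if (n < 2L) stop("'n' must be at least 2")
  g <- withr::with_seed(as.integer(seed), {
    switch(model,
      erdos_renyi = {
        if (param < 0 || param > 1) stop("edge probability must be in [0, 1]")
        igraph::sample_gnp(n, param)
      },
      barabasi_albert = {
        if (param < 1) stop("edges per step must be at least 1")
        igraph::sample_pa(n, m = param, directed = FALSE)
      },
      geometric = {
        if (param <= 0) stop("radius must be positive")
        igraph::sample_grg(n, param)
      },
      ring_chords = {
        if (param < 0) stop("chord count must be non-negative")
        g <- igraph::make_ring(n)
        if (param > 0) {
          cand <- which(upper.tri(diag(n)), arr.ind = TRUE)
          cand <- cand[abs(cand[, 1] - cand[, 2]) %% (n - 1) > 1, , drop = FALSE]
          pick <- cand[sample(nrow(cand), min(param, nrow(cand))), ,
                       drop = FALSE]
          igraph::add_edges(g, as.vector(t(pick)))
        } else g
      })
  })
  g <- igraph::simplify(g)
  width <- nchar(as.character(n))
  igraph::V(g)$name <- sprintf(paste0("v%0", width, "d"), seq_len(n))
  canonicalNetwork(g)
}

#' Seeded synthetic annotation tables
#'
#' Assigns random term sets to every node, with an assortativity knob
#' controlling how much more often adjacent nodes share a term than
#' random pairs do. With `assortativity = 0` the edge sharing fraction
#' matches the random-pair sharing fraction in expectation; with
#' `assortativity = 1` every edge shares at least one term (for each
#' edge, a term of one endpoint is copied to the other).
#'
#' @param net an undirected simple named igraph network.
#' @param nTerms size of the term vocabulary.
#' @param termsPerGene number of terms drawn (with replacement, then
#'   de-duplicated) for each node.
#' @param assortativity probability, per edge, of forcing a shared term.
#' @param seed integer seed.
#' @return Named list mapping node name to a character vector of terms,
#'   usable wherever an annotation table is expected.
#' @export
makeAnnotations <- function(net, nTerms = 20L, termsPerGene = 2L,
                            assortativity = 0, seed = 1L) {
  .checkNetwork(net)
  if (assortativity < 0 || assortativity > 1)
    stop("'assortativity' must be in [0, 1]")
  terms <- sprintf("T%04d", seq_len(nTerms))
  nm <- sort(igraph::V(net)$name, method = "radix")
  withr::with_seed(as.integer(seed), {
    ann <- setNames(lapply(nm, function(g)
      unique(sample(terms, termsPerGene, replace = TRUE))), nm)
    el <- igraph::as_edgelist(net, names = TRUE)
    if (nrow(el) > 0L && assortativity > 0) {
      force_ <- stats::runif(nrow(el)) < assortativity
      for (e in which(force_)) {
        u <- el[e, 1L]; v <- el[e, 2L]
        t0 <- sample(ann[[u]], 1L)
        ann[[v]] <- unique(c(ann[[v]], t0))
      }
    }
    ann
  })
}
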