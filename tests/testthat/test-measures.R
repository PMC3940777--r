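# Similarity, centrality, the alpha-combination, and the classical
# baselines, including the cross-measure equivalences.

cat5 <- buildCatalog(5)
cat3 <- buildCatalog(3)

test_that("node-GDV-similarity is a bounded symmetric agreement measure", {
  w <- orbitWeights(cat5, "node")
  gdv <- countNodeGDV(seededER(15, 0.3, 9), cat5)
  for (i in 1:5) {
    u <- gdv[i, ]; v <- gdv[i + 5, ]
    s <- gdvSimilarity(u, v, w)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, gdvSimilarity(v, u, w))
    expect_equal(gdvSimilarity(u, u, w), 1)
  }
  ## a single growing entry drives similarity down monotonically
  zero <- numeric(73)
  vals <- vapply(c(1, 10, 100, 1000), function(x) {
    v <- zero; v[10] <- x
    gdvSimilarity(zero, v, w)
  }, numeric(1))
  expect_true(all(vals < 1))
  expect_true(all(diff(vals) < 0))
  expect_error(gdvSimilarity(1:3, 1:4, w), "per node orbit")
})

test_that("pair centrality is zero at zero and strictly monotone", {
  w <- orbitWeights(cat5, "pair")
  d <- graphletDensities(cat5)
  expect_equal(pairCentrality(numeric(49), w), 0)
  base <- numeric(49)
  for (i in c(1, 25, 49)) {
    up <- base; up[i] <- 1
    expect_gt(pairCentrality(up, w), pairCentrality(base, w))
    expect_gt(pairCentrality(up, w, d), pairCentrality(base, w, d))
  }
})

test_that("3-node graphlets: weighted and unweighted centrality coincide and rank like SN", {
  net <- makeNetwork("geometric", 30, 0.3, seed = 3)
  pg <- countPairGDV(net, cat3)
  w <- orbitWeights(cat3, "pair")
  expect_equal(pairCentrality(pg, w),
               pairCentrality(pg, w, graphletDensities(cat3)))
  ## alpha = 1, 3-node catalog ranks identically to shared neighbours
  gdvTab <- combinedScores(net, cat3, alpha = 1, weighted = TRUE)
  snTab <- snScores(net)
  expect_equal(rankPairs(gdvTab)[, c("u", "v")], rankPairs(snTab)[, c("u", "v")])
  ## and the pair-GDV count itself equals the shared-neighbour count
  expect_equal(unname(pg[, 1L]), snTab$score)
})

test_that("alpha endpoints reduce to similarity-only and centrality-only rankings", {
  net <- seededER(18, 0.3, 11)
  w <- orbitWeights(cat5, "node")
  s0 <- combinedScores(net, cat5, alpha = 0)
  s1 <- combinedScores(net, cat5, alpha = 1, weighted = FALSE)
  sMid <- combinedScores(net, cat5, alpha = 0.4, weighted = FALSE)
  ## affine mixing: score(alpha) = alpha*C + (1-alpha)*S
  expect_equal(sMid$score, 0.4 * s1$score + 0.6 * s0$score)
  ## alpha = 0 equals pairwise similarity of node GDVs
  gdv <- countNodeGDV(net, cat5)
  i <- match(s0$u, rownames(gdv)); j <- match(s0$v, rownames(gdv))
  direct <- vapply(seq_len(nrow(s0)), function(r)
    gdvSimilarity(gdv[i[r], ], gdv[j[r], ], w), numeric(1))
  expect_equal(s0$score, direct)
  expect_error(combinedScores(net, cat5, alpha = 1.2), "alpha")
})

test_that("degree product and neighbour-based baselines match hand calculations", {
  star <- starGraph()
  dp <- dpScores(star)
  key <- paste(dp$u, dp$v)
  expect_equal(dp$score[key == "c0 l1"], 3)
  expect_equal(dp$score[key == "l1 l2"], 1)

  ## N(u)={a,b}, N(v)={b,c}: SN=1, JC=1/3; shared z with d(z)=2:
  ## AA=1/log 2, RAI=1/2
  g <- ugraph("u", "a", "u", "b", "v", "b", "v", "c")
  pick <- function(tab) tab$score[tab$u == "u" & tab$v == "v"]
  expect_equal(pick(snScores(g)), 1)
  expect_equal(pick(jcScores(g)), 1 / 3)
  expect_equal(pick(aaScores(g)), 1 / log(2))
  expect_equal(pick(raiScores(g)), 1 / 2)
  ## no shared neighbours
  pick2 <- function(tab) tab$score[tab$u == "a" & tab$v == "c"]
  expect_equal(pick2(snScores(g)), 0)
  expect_equal(pick2(jcScores(g)), 0)
  expect_equal(pick2(aaScores(g)), 0)
  expect_equal(pick2(raiScores(g)), 0)
})

test_that("Katz matches an independent series summation", {
  p3 <- path3Graph()
  beta <- 0.005
  tab <- katzScores(p3, beta = beta)
  ## independent oracle: explicit walk-count series, summed far past
  ## numerical convergence
  A <- matrix(0, 3, 3, dimnames = list(c("a","b","c"), c("a","b","c")))
  A["a","b"] <- A["b","a"] <- A["b","c"] <- A["c","b"] <- 1
  S <- matrix(0, 3, 3, dimnames = dimnames(A)); P <- diag(3)
  for (l in 1:60) { P <- P %*% A; S <- S + beta^l * P }
  pick <- function(u, v) tab$score[tab$u == u & tab$v == v]
  expect_equal(pick("a", "c"), S["a", "c"], tolerance = 1e-12)
  expect_equal(pick("a", "b"), S["a", "b"], tolerance = 1e-12)
  expect_gt(pick("a", "c"), 2.4e-5)   # dominated by the single 2-walk
  expect_lt(pick("a", "c"), 2.6e-5)
  ## truncation at length 2 equals beta*A + beta^2*A^2
  t2 <- katzScores(p3, beta = beta, maxLength = 2)
  expect_equal(t2$score[t2$u == "a" & t2$v == "c"], beta^2)
  ## divergence guard: a triangle has spectral radius 2
  expect_error(katzScores(triangleGraph(), beta = 0.6), "spectral radius")
})

test_that("LPI interpolates between shared neighbours and longer walks", {
  p3 <- path3Graph()
  tab <- lpiScores(p3, epsilon = 0.005)
  expect_equal(tab$score[tab$u == "a" & tab$v == "c"], 1)   # A2=1, A3=0
  c4 <- ugraph("a", "b", "b", "c", "c", "d", "d", "a")
  tab4 <- lpiScores(c4, epsilon = 0.005)
  ## adjacent pair in C4: no shared neighbour, four length-3 walks
  expect_equal(tab4$score[tab4$u == "a" & tab4$v == "b"], 4 * 0.005)
  ## epsilon = 0 ranks identically to SN
  net <- seededER(20, 0.25, 13)
  expect_equal(rankPairs(lpiScores(net, epsilon = 0))[, c("u", "v")],
               rankPairs(snScores(net))[, c("u", "v")])
})

test_that("score tables cover every unordered pair once, symmetrically", {
  net <- seededER(12, 0.3, 21)
  n <- igraph::vcount(net)
  for (m in setdiff(measureRegistry(), "gdv")) {
    tab <- scorePairs(net, m)
    expect_equal(nrow(tab), choose(n, 2))
    expect_false(any(duplicated(paste(tab$u, tab$v))))
    expect_true(all(tab$u < tab$v))
    expect_true(all(is.finite(tab$score)))
  }
  ## elementwise sanity bounds: RAI <= SN <= degree-scaled AA
  sn <- snScores(net)$score
  expect_true(all(raiScores(net)$score <= sn + 1e-12))
  dmax <- max(igraph::degree(net))
  expect_true(all(aaScores(net)$score >= sn / log(dmax) - 1e-12))
  expect_error(scorePairs(net, "nope"), "unknown measure")
})
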