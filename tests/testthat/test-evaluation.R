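# Noise injection, ranking, confusion curves, replicate statistics,
# de-noising, and edge-set intersections.

test_that("edge removal draws the exact count, deterministically", {
  net <- makeNetwork("erdos_renyi", 30, 0.25, seed = 1)
  E0 <- igraph::ecount(net)
  rep1 <- removeEdges(net, 0.5, seed = 7)
  expect_equal(igraph::ecount(rep1$noisy), E0 - round(0.5 * E0))
  expect_equal(nrow(rep1$removed), round(0.5 * E0))
  expect_equal(igraph::vcount(rep1$noisy), igraph::vcount(net))
  ## removed edges are original edges
  expect_true(all(graphletLP:::.pairKeys(rep1$removed[, 1], rep1$removed[, 2])
                  %in% graphletLP:::.edgeKeys(net)))
  rep2 <- removeEdges(net, 0.5, seed = 7)
  expect_identical(rep1$removed, rep2$removed)
  rep3 <- removeEdges(net, 0.5, seed = 8)
  expect_false(identical(rep1$removed, rep3$removed))
  expect_equal(round(0.05 * 2518), 126)   # the 5% level of a 2518-edge network
  expect_error(removeEdges(net, 0, 1), "fraction")
  expect_error(removeEdges(net, 1.2, 1), "fraction")
  expect_warning(removeEdges(net, 0.9, 1), "more than half")
})

test_that("pair ranking is deterministic under ties and input permutation", {
  scores <- data.frame(u = c("b", "a", "a"), v = c("c", "c", "b"),
                       score = c(5, 5, 5))
  r <- rankPairs(scores)
  expect_equal(paste(r$u, r$v), c("a b", "a c", "b c"))
  shuffled <- scores[c(2, 3, 1), ]
  expect_equal(rankPairs(shuffled), r)
})

test_that("confusion curve matches hand enumeration on a 4-node example", {
  ## 6 pairs, 2 positives; ranking places one positive 1st, one 4th
  pairs <- data.frame(u = c("a", "a", "a", "b", "b", "c"),
                      v = c("b", "c", "d", "c", "d", "d"),
                      score = c(6, 5, 4, 3, 2, 1))
  pos <- rbind(c("a", "b"), c("b", "c"))
  ev <- evalCurve(pairs, pos)
  tab <- curveTable(ev)
  r50 <- tab[tab$k == 50, ]        # top 3 predicted
  expect_equal(r50$predicted, 3)
  expect_equal(r50$TP, 1); expect_equal(r50$FP, 2)
  expect_equal(r50$FN, 1); expect_equal(r50$TN, 2)
  expect_equal(r50$precision, 1 / 3)
  expect_equal(r50$recall, 1 / 2)
  expect_equal(r50$specificity, 2 / 4)
  ## conservation and endpoint conventions at every k
  expect_true(all(tab$TP + tab$FP + tab$TN + tab$FN == 6))
  expect_equal(tab$precision[tab$k == 0], 1)
  expect_equal(tab$specificity[tab$k == 0], 1)
  expect_equal(tab$sensitivity[tab$k == 100], 1)
  ## AUROC by hand: positives at ranks 1 and 4 of 6 -> 1 - (0+2/4*1/2)/2
  expect_equal(auroc(ev), 0.75)
})

test_that("perfect and reversed rankings give the extreme areas", {
  net <- makeNetwork("erdos_renyi", 15, 0.3, seed = 2)
  pos <- igraph::as_edgelist(net, names = TRUE)
  perfect <- oracleScores(net, pos)
  ev <- evalCurve(perfect, pos)
  expect_equal(auroc(ev), 1)
  expect_equal(aupr(ev), 1)
  reversed <- perfect; reversed$score <- -reversed$score
  expect_equal(auroc(evalCurve(reversed, pos)), 0)
  expect_error(evalCurve(perfect, pos[0, , drop = FALSE]), "empty positive")
})

test_that("random rankings centre at AUROC one half", {
  net <- makeNetwork("erdos_renyi", 25, 0.25, seed = 3)
  pos <- igraph::as_edgelist(net, names = TRUE)
  as_ <- vapply(1:50, function(s)
    auroc(evalCurve(randomScores(net, s), pos)), numeric(1))
  se <- stats::sd(as_) / sqrt(length(as_))
  expect_lt(abs(mean(as_) - 0.5), 3 * se + 1e-9)
})

test_that("replicate averaging and the paired t-test behave at the margins", {
  net <- makeNetwork("erdos_renyi", 15, 0.3, seed = 4)
  pos <- igraph::as_edgelist(net, names = TRUE)
  curves <- lapply(1:3, function(s) evalCurve(randomScores(net, s), pos))
  m <- replicateMean(curves)
  expect_equal(auroc(m), mean(vapply(curves, auroc, numeric(1))))
  expect_equal(curveTable(m)$TP,
               Reduce(`+`, lapply(curves, function(c) curveTable(c)$TP)) / 3)
  expect_equal(pairedTTest(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 1)
  expect_warning(p0 <- pairedTTest(c(.6, .7, .8), c(.5, .6, .7)), "zero-variance")
  expect_equal(p0, 0)
  ## textbook paired t: d = (0.1, 0.2, 0.3, 0.2, 0.2)
  a <- c(0.8, 0.9, 0.85, 0.7, 0.75); b <- a - c(0.1, 0.2, 0.3, 0.2, 0.2)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(pairedTTest(a, b), 2 * stats::pt(-abs(tstat), df = 4))
  expect_error(pairedTTest(1:3, 1:4), "equal-length")
})

test_that("de-noising keeps the node set and honours the ranking", {
  net <- makeNetwork("erdos_renyi", 20, 0.25, seed = 5)
  ## identity scorer reproduces the original network exactly
  sc <- oracleScores(net, igraph::as_edgelist(net, names = TRUE))
  dn <- denoiseNetwork(net, sc)
  expect_setequal(graphletLP:::.edgeKeys(dn), graphletLP:::.edgeKeys(net))
  expect_setequal(igraph::V(dn)$name, igraph::V(net)$name)
  ## m = 0 empties the edge set
  expect_equal(igraph::ecount(denoiseNetwork(net, sc, m = 0)), 0L)
  expect_error(denoiseNetwork(net, sc, m = -1), "non-negative")
  expect_error(denoiseNetwork(net, sc, m = nrow(sc) + 1), "exceeds")
  ## intersection statistics
  expect_equal(intersectEdges(net, net),
               list(shared = igraph::ecount(net), jaccard = 1))
  other <- ugraph("x", "y")
  expect_equal(intersectEdges(net, other)$shared, 0)
  expect_equal(intersectEdges(net, other)$jaccard, 0)
})
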