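# The orbit taxonomy is fully analytic: totals and the anchor positions
# of the small path/triangle graphlets pin down the canonical numbering.

test_that("orbit totals match the 2-5-node and 2-4-node taxonomies", {
  expect_equal(unname(orbitCounts(buildCatalog(5))),
               c(73L, 68L, 49L, 49L))
  expect_equal(unname(orbitCounts(buildCatalog(4))),
               c(15L, 12L, 7L, 7L))
  expect_equal(unname(orbitCounts(buildCatalog(3))),
               c(4L, 2L, 1L, 1L))
  expect_error(buildCatalog(6), "maxNodes")
  expect_error(buildCatalog(2), "maxNodes")
})

test_that("canonical numbering reproduces the anchor orbit positions", {
  cat5 <- buildCatalog(5)
  tab <- catalogTable(cat5)
  ## 4-node path: end nodes in node orbit 4, middle nodes in node orbit 5;
  ## outer edges in edge orbit 3, middle edge in edge orbit 4;
  ## end-to-end non-edge in orbit 2, end-to-middle non-edges in orbit 3.
  p4 <- cat5@graphlets[[4L]]
  expect_equal(p4$k, 4L)
  expect_equal(p4$eCount, 3L)
  expect_equal(sort(p4$degrees), c(1L, 1L, 2L, 2L))
  expect_equal(sort(unique(p4$nodeOrbit)), c(4L, 5L))
  expect_equal(p4$nodeOrbit[p4$degrees == 1L], c(4L, 4L))
  expect_equal(p4$nodeOrbit[p4$degrees == 2L], c(5L, 5L))
  pairs <- graphletLP:::.pairsOf(4L)
  edgeDegSum <- function(p) as.numeric(sum(p4$degrees[pairs[, p] + 1L]))
  eo <- p4$posEdgeOrbit
  expect_equal(sort(unique(stats::na.omit(eo))), c(3L, 4L))
  expect_true(all(eo[which(!is.na(eo))][
    vapply(which(!is.na(eo)), edgeDegSum, numeric(1)) == 3] == 3L))
  expect_true(all(eo[which(!is.na(eo))][
    vapply(which(!is.na(eo)), edgeDegSum, numeric(1)) == 4] == 4L))
  ne <- p4$posNonEdgeOrbit
  expect_equal(sort(stats::na.omit(ne)), c(2L, 3L, 3L))
  expect_equal(ne[which(vapply(seq_along(ne), edgeDegSum, numeric(1)) == 2)],
               2L)
  ## 3-node path non-edge is orbit 1; triangle's edge orbit is 2
  p3 <- cat5@graphlets[[2L]]
  expect_equal(sort(stats::na.omit(p3$posNonEdgeOrbit)), 1L)
  tri <- cat5@graphlets[[3L]]
  expect_equal(sort(unique(stats::na.omit(tri$posEdgeOrbit))), 2L)
  expect_equal(tab$automorphisms[tab$nodes == 4 & tab$edges == 6], 24L)
})

test_that("edge completion reconciles non-edge and edge orbits bijectively", {
  for (mx in c(4L, 5L)) {
    cat_ <- buildCatalog(mx)
    pm <- pairOrbitMap(cat_)
    expect_equal(pm$pairOrbit, seq_len(pairOrbitCount(cat_)))
    expect_equal(pm$nonEdgeOrbit, pm$pairOrbit)
    ## each node-pair orbit links to exactly one edge orbit, injectively
    expect_false(anyDuplicated(pm$edgeOrbit) > 0)
    pf <- cat_@pairFromEdge
    expect_equal(sum(!is.na(pf)), pairOrbitCount(cat_))
    expect_equal(pf[pm$edgeOrbit], pm$pairOrbit)
    ## node-pair orbit 1 = triangle edge orbit 2 / 3-path non-edge orbit 1
    expect_equal(pm$edgeOrbit[1L], 2L)
    expect_equal(pm$density[1L], 1)
  }
})

test_that("densities and orbit weights are well-formed", {
  cat5 <- buildCatalog(5)
  d <- graphletDensities(cat5)
  expect_true(all(d > 0 & d <= 1))
  ## completion of the densest non-edge orbits are complete graphs
  pm <- pairOrbitMap(cat5)
  expect_true(any(d == 1))
  w <- orbitWeights(cat5, "node")
  expect_length(w, 73L)
  expect_true(all(w > 0 & w <= 1))
  expect_equal(w[1L], 1)   # the degree orbit depends only on itself
  wp <- orbitWeights(cat5, "pair")
  expect_length(wp, 49L)
  expect_true(all(wp > 0 & wp <= 1))
  ## single-orbit catalog: weight degenerates to 1
  expect_equal(orbitWeights(buildCatalog(3), "pair"), 1)
  ## override path
  expect_equal(orbitWeights(cat5, "node", override = rep(0.5, 73)),
               rep(0.5, 73))
  expect_error(orbitWeights(cat5, "node", override = 1:3), "one positive")
})

test_that("orbit partitions are exact automorphism orbits", {
  ## spot-check: within each graphlet, nodes in one orbit have equal
  ## degree, and distinct orbits of equal degree are not mergeable by
  ## any automorphism (by construction min-image representatives differ)
  cat5 <- buildCatalog(5)
  for (g in cat5@graphlets) {
    for (orb in unique(g$nodeOrbit)) {
      expect_length(unique(g$degrees[g$nodeOrbit == orb]), 1L)
    }
    expect_true(g$autCount >= 1)
  }
})
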