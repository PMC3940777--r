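# GDV counting: anchor examples on tiny graphs, then property checks
# (degree identity, symmetry, masking, occupancy conservation) and
# agreement with the naive subset-enumeration oracle.

cat5 <- buildCatalog(5)

test_that("node GDVs match hand-derived counts on tiny graphs", {
  k2 <- ugraph("a", "b")
  gdv <- countNodeGDV(k2, cat5)
  expect_equal(unname(gdv["a", ]), c(1, rep(0, 72)))
  expect_equal(unname(gdv["b", ]), c(1, rep(0, 72)))

  tri <- triangleGraph()
  gdv <- countNodeGDV(tri, cat5)
  for (v in c("a", "b", "c")) {
    expect_equal(unname(gdv[v, 1:4]), c(2, 0, 0, 1))
    expect_equal(sum(gdv[v, -(1:4)]), 0)
  }

  p4 <- path4Graph()
  gdv <- countNodeGDV(p4, cat5)
  expect_equal(unname(gdv["a", 1:7]), c(1, 1, 0, 0, 1, 0, 0))
  expect_equal(unname(gdv["b", 1:7]), c(2, 1, 1, 0, 0, 1, 0))
})

test_that("pair GDVs reconcile edges and non-edges into the same orbit", {
  tri <- triangleGraph()
  pg <- countPairGDV(tri, cat5)
  ## masking the triangle edge leaves the 3-node path: node-pair orbit 1
  expect_equal(unname(pg["a|b", ]), c(1, rep(0, 48)))
  p3 <- path3Graph()
  pg3 <- countPairGDV(p3, cat5)
  expect_equal(unname(pg3["a|c", ]), unname(pg["a|b", ]))
  ## a bridge edge has no masked-connected subgraph
  expect_equal(sum(pg3["a|b", ]), 0)
  ## isolated pair in an edgeless graph
  g0 <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g0)$name <- c("u", "v")
  expect_equal(sum(countPairGDV(g0, cat5)), 0)
})

test_that("edge and non-edge GDVs separate the 4-path positions", {
  p4 <- path4Graph()
  eg <- countEdgeGDV(p4, cat5)
  expect_equal(eg["a|b", "E3"], 1)
  expect_equal(eg["b|c", "E4"], 1)
  expect_equal(eg["a|b", "E4"], 0)
  ## end-to-end vs end-to-middle non-edges
  expect_equal(unname(nonEdgeGDV(p4, "a", "d", cat5)[2:3]), c(1, 0))
  expect_equal(unname(nonEdgeGDV(p4, "a", "c", cat5)[2:3]), c(0, 1))
  expect_error(nonEdgeGDV(p4, "a", "b", cat5), "is an edge")
  ## a lone edge touches no 3-5-node graphlet
  expect_equal(sum(countEdgeGDV(ugraph("a", "b"), cat5)), 0)
})

test_that("single-pair accessors validate their arguments", {
  p3 <- path3Graph()
  expect_error(pairGDV(p3, "a", "a", cat5), "must differ")
  expect_error(pairGDV(p3, "a", "zz", cat5), "in the network")
  expect_equal(pairGDV(p3, "c", "a", cat5), pairGDV(p3, "a", "c", cat5))
})

test_that("GDV[0] equals the degree and occupancy is conserved", {
  for (seed in 1:3) {
    net <- seededER(15, 0.3, seed)
    gdv <- countNodeGDV(net, cat5)
    expect_equal(unname(gdv[, 1L]),
                 unname(igraph::degree(net)[rownames(gdv)]))
    ## per graphlet: node-touch total / node count must equal the
    ## edge-touch total / edge count (both count occurrences)
    eg <- countEdgeGDV(net, cat5)
    for (g in cat5@graphlets) {
      if (g$k < 3L) next
      nTouch <- sum(gdv[, sort(unique(g$nodeOrbit)) + 1L])
      eTouch <- sum(eg[, unique(stats::na.omit(g$posEdgeOrbit)), drop = FALSE])
      expect_equal(nTouch / g$k, eTouch / g$eCount)
    }
  }
})

test_that("pair GDV is symmetric and invariant under edge masking", {
  net <- seededER(12, 0.35, 42)
  nm <- igraph::V(net)$name
  pg <- countPairGDV(net, cat5)
  ## masking property: toggling the (u,v) edge leaves the (u,v) row as is
  u <- nm[2L]; v <- nm[7L]
  toggled <- if (igraph::are_adjacent(net, u, v))
    igraph::delete_edges(net, paste(u, v, sep = "|"))
  else igraph::add_edges(net, c(u, v))
  pg2 <- countPairGDV(toggled, cat5)
  key <- paste(sort(c(u, v)), collapse = "|")
  expect_equal(pg2[key, ], pg[key, ])
})

test_that("counts agree with the naive subset-enumeration oracle", {
  oracle <- makeOracle(cat5)
  for (seed in 1:4) {
    net <- seededER(10, 0.35, seed + 100)
    gdv <- countNodeGDV(net, cat5)
    expect_equal(unname(gdv), unname(oracleNodeGDV(net, cat5, oracle)))
    nm <- igraph::V(net)$name
    pg <- countPairGDV(net, cat5)
    for (pr in list(c(1L, 2L), c(3L, 8L))) {
      key <- paste(nm[pr], collapse = "|")
      expect_equal(unname(pg[key, ]),
                   oraclePairGDV(net, nm[pr[1L]], nm[pr[2L]], cat5, oracle))
    }
  }
})

test_that("restricted catalogs count only their graphlet sizes", {
  cat4 <- buildCatalog(4)
  p5 <- ugraph("a", "b", "b", "c", "c", "d", "d", "e")
  gdv4 <- countNodeGDV(p5, cat4)
  gdv5 <- countNodeGDV(p5, cat5)
  expect_equal(ncol(gdv4), 15L)
  expect_equal(unname(gdv5[, 1:15]), unname(gdv4))
  expect_true(sum(gdv5[, 16:73]) > 0)
})
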