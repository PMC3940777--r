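# Small named graphs used across the suite.

ugraph <- function(...) igraph::make_graph(c(...), directed = FALSE)

triangleGraph <- function() ugraph("a", "b", "b", "c", "a", "c")
path3Graph <- function() ugraph("a", "b", "b", "c")
path4Graph <- function() ugraph("a", "b", "b", "c", "c", "d")
starGraph <- function() ugraph("c0", "l1", "c0", "l2", "c0", "l3")

seededER <- function(n, p, seed) makeNetwork("erdos_renyi", n, p, seed)
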