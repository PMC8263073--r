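test_that("density thresholding keeps exactly the strongest edges", {
  # complete positive graph on 4 nodes at k = 2 -> floor(4*2/2) = 4 edges
  w4 <- matrix(0.5, 4, 4)
  net4 <- thresholdToDensity(connFromWeights(w4), 2)
  expect_equal(net4@m, 4L)

  # 5 nodes, distinct weights: the top-5 pairs by sort oracle
  set.seed(11)
  w5 <- matrix(0, 5, 5)
  w5[upper.tri(w5)] <- sample(seq(0.1, 0.9, length.out = 10))
  w5 <- w5 + t(w5)
  net5 <- thresholdToDensity(connFromWeights(w5), 2)
  ut <- which(upper.tri(w5), arr.ind = TRUE)
  keep <- ut[order(-w5[upper.tri(w5)])[1:5], , drop = FALSE]
  got <- igraph::as_edgelist(netGraph(net5))
  gotIdx <- t(apply(got, 1, function(e)
    sort(as.integer(sub("R", "", e)))))
  expect_setequal(paste(gotIdx[, 1], gotIdx[, 2]),
                  paste(keep[, 1], keep[, 2]))
  expect_equal(sort(igraph::E(netGraph(net5))$weight, decreasing = TRUE),
               sort(w5[upper.tri(w5)], decreasing = TRUE)[1:5])

  # insufficient positive edges
  sparse <- matrix(0, 6, 6)
  sparse[1, 2] <- sparse[2, 1] <- 0.5
  expect_error(thresholdToDensity(connFromWeights(sparse), 4), "achievable")

  # deterministic tie-break: equal weights resolved by (i, j) order
  tied <- matrix(0.4, 4, 4)
  a <- thresholdToDensity(connFromWeights(tied), 1)
  b <- thresholdToDensity(connFromWeights(tied), 1)
  expect_identical(igraph::as_edgelist(netGraph(a)),
                   igraph::as_edgelist(netGraph(b)))
})

test_that("thresholded edge sets are nested across densities", {
  set.seed(12)
  w <- matrix(runif(30 * 30, 0, 0.9), 30, 30); w <- (w + t(w)) / 2
  cm <- connFromWeights(w)
  keyOf <- function(net) apply(igraph::as_edgelist(netGraph(net)), 1,
                               function(e) paste(sort(e), collapse = "-"))
  e4 <- keyOf(thresholdToDensity(cm, 4))
  e8 <- keyOf(thresholdToDensity(cm, 8))
  expect_true(all(e4 %in% e8))
})

test_that("component counting is a plain graph search", {
  cl <- matrix(0, 6, 6)
  cl[1:3, 1:3] <- 0.5; cl[4:6, 4:6] <- 0.5
  net <- thresholdToDensity(connFromWeights(cl), 2)
  expect_equal(countComponents(net), 2)

  empty <- thresholdedNetwork(
    igraph::make_empty_graph(5, directed = FALSE))
  expect_equal(countComponents(empty), 5)
})

test_that("ring lattice clustering matches the closed form", {
  for (k in c(4, 6, 10)) {
    lat <- ringLattice(72, k)
    C <- mean(igraph::transitivity(lat, type = "localundirected",
                                   isolates = "zero"))
    expect_equal(C, 3 * (k - 2) / (4 * (k - 1)), tolerance = 1e-12,
                 info = paste("k", k))
  }
  expect_equal(igraph::ecount(ringLattice(72, 10)), 360)
})

test_that("small-world normalization self-normalizes random graphs", {
  # an ER graph measured against ER nulls: gamma, lambda, sigma all ~ 1
  sigmas <- vapply(1:12, function(s) {
    attempt <- 0
    repeat {
      g <- withr::with_seed(s + 1000 * attempt, igraph::sample_gnm(72, 360))
      if (igraph::is_connected(g)) break
      attempt <- attempt + 1
    }
    globalMetrics(thresholdedNetwork(g, 10), nNull = 200,
                  seed = s + 500)$sigma
  }, numeric(1))
  expect_true(mean(sigmas > 0.8 & sigmas < 1.2) >= 0.95 - 1e-9)

  # rewired lattice sits in the small-world regime
  sw <- rewireEdges(ringLattice(72, 10), 0.1, seed = 13)
  gm <- globalMetrics(thresholdedNetwork(sw, 10), nNull = 200, seed = 14)
  expect_gt(gm$sigma, 1)
  expect_equal(gm$sigma, gm$gamma / gm$lambda, tolerance = 1e-12)

  # determinism given (graph, seed)
  gm2 <- globalMetrics(thresholdedNetwork(sw, 10), nNull = 50, seed = 15)
  gm3 <- globalMetrics(thresholdedNetwork(sw, 10), nNull = 50, seed = 15)
  expect_identical(gm2, gm3)

  expect_error(globalMetrics(thresholdedNetwork(sw, 10), nNull = 0), "nNull")
})

test_that("node metrics equal brute-force oracles on small graphs", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:6)
  nm <- nodeMetrics(thresholdedNetwork(star))
  expect_equal(nm$degree, c(5, rep(1, 5)))
  expect_equal(which.max(nm$betweenness), 1)

  path3 <- igraph::graph_from_literal(a - b, b - c)
  nm3 <- nodeMetrics(thresholdedNetwork(path3))
  expect_equal(nm3$betweenness[nm3$region == "b"], 1)
  expect_equal(sum(nm3$betweenness[nm3$region != "b"]), 0)

  for (s in 1:5) {
    g <- withr::with_seed(s, igraph::sample_gnp(10, 0.35))
    igraph::V(g)$name <- paste0("n", 1:10)
    net <- thresholdedNetwork(g)
    nm <- nodeMetrics(net)
    adj <- adjacencyOf(net)
    expect_equal(sum(nm$degree), 2 * igraph::ecount(g))
    expect_equal(nm$degree, unname(rowSums(adj)))
    expect_equal(nm$clustering, bruteClustering(adj), tolerance = 1e-12)
    expect_equal(nm$pathLength, brutePathLength(adj), tolerance = 1e-12)
    expect_equal(nm$betweenness, bruteBetweenness(adj), tolerance = 1e-10)
    expect_equal(nm$strength, unname(igraph::strength(g)))
  }
})

test_that("hub scores rank connector nodes on top", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:6)
  hs <- hubScores(nodeMetrics(thresholdedNetwork(star)))
  expect_equal(names(which.max(hs)), "s1")
  expect_true(hs["s1"] > max(hs[-1]))

  # ring lattice: perfectly regular, every component zero-variance
  lat <- thresholdedNetwork(ringLattice(12, 4))
  w <- capture_warnings(hsLat <- hubScores(nodeMetrics(lat)))
  expect_true(any(grepl("zero variance", w)))
  expect_true(all(hsLat == 0))

  # 8-node barbell: two 4-cliques joined by one edge; the two bridge
  # endpoints must outrank clique interiors
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- paste0("b", 1:8)
  hs2 <- hubScores(nodeMetrics(thresholdedNetwork(g)))
  expect_true(min(hs2[c("b4", "b5")]) > max(hs2[c("b1", "b2", "b3",
                                                  "b6", "b7", "b8")]))
})

test_that("graph exports carry attributes for layout tools", {
  atlas <- generateAtlas(2, c(limbic = 1, thalamus = 1))
  w <- matrix(0.3, 4, 4)
  net <- thresholdToDensity(connFromWeights(w, labels = atlas$region), 2)
  attrs <- data.frame(region = atlas$region, hemisphere = atlas$hemisphere,
                      group = atlas$group)
  f1 <- tempfile(fileext = ".graphml")
  exportGraph(net, f1, "graphml", nodeAttrs = attrs)
  g2 <- igraph::read_graph(f1, format = "graphml")
  expect_setequal(igraph::V(g2)$hemisphere, c("left", "right"))
  expect_equal(igraph::ecount(g2), 4)

  f2 <- tempfile(fileext = ".gexf")
  exportGraph(net, f2, "gexf", nodeAttrs = attrs)
  doc <- xml2::read_xml(f2)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='node']")
  expect_equal(length(nodes), 4)
  edges <- xml2::xml_find_all(doc, ".//*[local-name()='edge']")
  expect_equal(length(edges), 4)
})
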