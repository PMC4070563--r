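test_that("hand-checkable path graph has the expected battery values", {
  # path a-b-c-d: every metric is known in closed form
  net <- CoexpressionNetwork(letters[1:4],
                             rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_equal(networkDensity(net), 0.5)
  dd <- degreeDistribution(net)
  expect_identical(dd$degree, c(1L, 2L))
  expect_identical(dd$frequency, c(2L, 2L))
  pm <- pathMetrics(net)
  expect_identical(pm$distribution$length, c(1L, 2L, 3L))
  expect_identical(pm$distribution$frequency, c(6L, 4L, 2L))  # ordered pairs
  expect_equal(unname(pm$closeness[["a"]]), 3 / 6)
  expect_equal(unname(pm$closeness[["b"]]), 3 / 4)
  b <- betweennessAll(net)
  expect_equal(unname(b[c("a", "b", "c", "d")]), c(0, 2, 2, 0))
  bn <- betweennessAll(net, normalized = TRUE)
  expect_equal(unname(bn[["b"]]), 2 / 3)
  cc <- clusteringByDegree(net)
  expect_true(all(cc$per_node == 0))           # path has no triangles
})

test_that("a triangle with a pendant node is fully characterised", {
  net <- CoexpressionNetwork(c("a", "b", "c", "d"),
                             rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                                   c("c", "d")))
  cc <- clusteringByDegree(net)$per_node
  expect_equal(unname(cc[c("a", "b", "c", "d")]), c(1, 1, 1 / 3, 0))
  ns <- neighborhoodStats(net)
  # neighbourhood connectivity: a's neighbours b (deg 2) and c (deg 3)
  expect_equal(unname(ns$neighborhood_connectivity[["a"]]), 2.5)
  expect_equal(unname(ns$neighborhood_connectivity[["d"]]), 3)
  # topological coefficient of a: partners sharing a neighbour are b
  # (shared c, adjacent -> J = 2), c (shared b, adjacent -> J = 2) and
  # d (shared c, not adjacent -> J = 1); mean(2, 2, 1) / deg(a) = 5/6
  expect_equal(unname(ns$topological_coefficient[["a"]]), 5 / 6)
  expect_equal(unname(ns$topological_coefficient[["d"]]), 0)  # degree 1
})

test_that("topology battery equals brute force on the graph suite", {
  suite <- oracleGraphSuite()
  for (A in suite) {
    n <- nrow(A)
    net <- netFromAdjacency(A)
    want <- bruteNodeMetrics(A)
    ids <- oracleNodeIds(n)

    deg <- igraph::degree(asIgraph(net))[ids]
    expect_equal(unname(deg), unname(want$degree))

    cc <- clusteringByDegree(net)$per_node[ids]
    expect_equal(unname(cc), unname(want$clustering))

    pmx <- pathMetrics(net)
    expect_equal(unname(pmx$closeness[ids]), unname(want$closeness))
    if (length(want$path_lengths)) {
      tab <- table(want$path_lengths)
      expect_identical(pmx$distribution$length, as.integer(names(tab)))
      expect_identical(pmx$distribution$frequency, as.integer(tab))
    } else {
      expect_equal(nrow(pmx$distribution), 0)
    }

    bt <- betweennessAll(net)[ids]
    expect_equal(unname(bt), unname(want$betweenness))

    ns <- neighborhoodStats(net)
    expect_equal(unname(ns$neighborhood_connectivity[ids]),
                 unname(want$neighborhood_connectivity))
    expect_equal(unname(ns$topological_coefficient[ids]),
                 unname(want$topological_coefficient))
    if (n >= 2) {
      stab <- table(want$shared_pairs)
      expect_identical(ns$shared_distribution$shared,
                       as.integer(names(stab)))
      expect_identical(ns$shared_distribution$frequency, as.integer(stab))
      expect_equal(networkDensity(net), want$density)
    }

    comp <- networkComponents(net, member_threshold = 2)
    expect_equal(comp$n_components, max(want$components))
    expect_identical(comp$sizes,
                     sort(as.integer(table(want$components)),
                          decreasing = TRUE))
  }
})

test_that("power-law fit recovers exact synthetic log-log lines", {
  deg <- c(1, 2, 4, 8, 16)
  freq <- round(1000 * deg^-1.5)
  fit <- powerlawFit(data.frame(degree = deg, frequency = freq))
  expect_equal(fit$exponent, 1.5, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)
  expect_error(powerlawFit(data.frame(degree = c(1, 2), frequency = c(5, 3))),
               "3 distinct degrees")
})

test_that("components, main component and edge share are consistent", {
  # K4 plus a separate triangle plus two isolated nodes
  k4 <- t(combn(paste0("k", 1:4), 2))
  tri <- rbind(c("t1", "t2"), c("t2", "t3"), c("t1", "t3"))
  net <- CoexpressionNetwork(c(paste0("k", 1:4), paste0("t", 1:3), "i1", "i2"),
                             rbind(k4, tri))
  comp <- networkComponents(net, member_threshold = 3)
  expect_equal(comp$n_components, 4)
  expect_identical(comp$sizes, c(4L, 3L, 1L, 1L))
  expect_equal(comp$n_at_threshold, 2)
  expect_equal(comp$main_nodes, 4)
  expect_equal(comp$main_edges, 6)
  expect_equal(comp$main_edge_share, 6 / 9)
  main <- mainComponent(net)
  expect_setequal(networkNodes(main), paste0("k", 1:4))
  # size tie: lexicographically smallest member wins
  tie <- CoexpressionNetwork(c("b1", "b2", "a1", "a2"),
                             rbind(c("b1", "b2"), c("a1", "a2")))
  expect_setequal(networkNodes(mainComponent(tie)), c("a1", "a2"))
})

test_that("density readings for unordered and ordered edge counts differ x2", {
  expect_equal(densityFromCounts(10, 9), 2 * 9 / 90)
  expect_equal(densityFromCounts(10, 9, ordered = TRUE), 9 / 90)
  net <- CoexpressionNetwork(c("a", "b", "c"), cbind("a", "b"))
  expect_equal(networkDensity(net), 2 / 6)
  expect_error(networkDensity(CoexpressionNetwork("a")), "2 nodes")
})

test_that("hub and top-betweenness extraction respect cutoffs and ties", {
  # star: centre degree 5, leaves degree 1
  leaves <- paste0("l", 1:5)
  net <- CoexpressionNetwork(c("hub", leaves), cbind("hub", leaves))
  expect_identical(hubs(net, min_degree = 5), "hub")
  expect_identical(hubs(net, min_degree = 6), character(0))
  tb <- topBetweenness(net, n = 3)
  # all leaves tie at betweenness 0: cutoff 0 pulls every node in
  expect_equal(tb$n_returned, 6)
  expect_identical(tb$genes[1], "hub")
  expect_equal(tb$cutoff, 0)
  tb1 <- topBetweenness(net, n = 1)
  expect_identical(tb1$genes, "hub")
  expect_equal(tb1$n_returned, 1)
})

test_that("list overlap reports the sorted intersection", {
  ov <- overlapWithList(c("g3", "g1", "g2"), c("g2", "g3", "g9"))
  expect_identical(ov$intersection, c("g2", "g3"))
  expect_equal(ov$n_overlap, 2)
  expect_equal(ov$n_genes, 3)
  expect_equal(ov$n_reference, 3)
})

test_that("the bundled report agrees with its parts", {
  pp <- plantedPartitionGraph(c(8, 8), 0.9, 0.05, seed = 77)
  rep <- topologyReport(pp$net, hub_min_degree = 5, top_n = 4,
                        member_threshold = 4)
  expect_identical(rep$per_node$gene_id, networkNodes(pp$net))
  expect_equal(rep$per_node$betweenness,
               unname(betweennessAll(pp$net)[rep$per_node$gene_id]))
  expect_equal(rep$density, networkDensity(pp$net))
  expect_identical(rep$hubs, hubs(pp$net, 5))
  expect_equal(rep$components$n_components,
               networkComponents(pp$net, 4)$n_components)
})
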