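test_that("Kraskov pair MI matches the longhand estimator and is symmetric", {
  set.seed(31)
  n <- 120
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, sd = 0.5)
  for (k in c(1, 3, 6)) {
    expect_equal(kraskovPairMI(x, y, k), bruteKraskov(x, y, k))
    expect_equal(kraskovPairMI(x, y, k), kraskovPairMI(y, x, k))
  }
  expect_error(kraskovPairMI(x[1:3], y[1:3], k = 3), "smaller than")
})

test_that("Kraskov MI is exactly invariant under joint scaling", {
  set.seed(32)
  x <- rnorm(80); y <- rnorm(80) + 0.5 * x
  # scaling both coordinates by the same power of two preserves every
  # max-norm comparison bit-for-bit
  expect_identical(kraskovPairMI(4 * x, 4 * y, 3), kraskovPairMI(x, y, 3))
  expect_identical(kraskovPairMI(0.5 * x, 0.5 * y, 5),
                   kraskovPairMI(x, y, 5))
  # rescaling one marginal reshapes the max-norm balls, so invariance
  # is only approximate at finite N
  expect_equal(kraskovPairMI(2 * x, y, 3), kraskovPairMI(x, y, 3),
               tolerance = 0.1)
})

test_that("independent samples give near-zero MI, dependence gives more", {
  set.seed(33)
  x <- rnorm(400); y_ind <- rnorm(400); y_dep <- x + rnorm(400, sd = 0.3)
  mi_ind <- kraskovPairMI(x, y_ind, 3)
  mi_dep <- kraskovPairMI(x, y_dep, 3)
  expect_lt(abs(mi_ind), 0.1)
  expect_gt(mi_dep, 0.5)
})

test_that("all-pairs MI is deterministic, symmetric and structure-aware", {
  tr <- plantedExpressionTruth(c(6, 6), 60, flip_prob = 0.05, seed = 41)
  tem <- synthExpression(16, 60, tr, seed = 42)
  cfg <- miConfig(seed = 7)
  s1 <- kraskovMiAll(tem, cfg)
  s2 <- kraskovMiAll(tem, cfg)
  expect_identical(simWeights(s1), simWeights(s2))
  expect_identical(simKind(s1), "mi")
  w <- simWeights(s1)
  expect_equal(w, t(w))
  within <- w[1:6, 1:6][upper.tri(matrix(0, 6, 6))]
  between <- w[1:6, 13:16]
  expect_gt(mean(within), mean(between) + 0.1)
  expect_error(kraskovMiAll(TernaryExpressionMatrix(
    ternaryValues(tem)[, 1:2]), cfg), "3 conditions")
})

test_that("miConfig validates its numeric ranges", {
  expect_identical(miConfig(dpi_mode = "additive")$dpi_tolerance, 0)
  expect_identical(miConfig(dpi_mode = "multiplicative")$dpi_tolerance, 1)
  expect_error(miConfig(k_neighbors = 0), "k_neighbors")
  expect_error(miConfig(jitter_sd = 0), "jitter_sd")
  expect_error(miConfig(threshold_fraction = 0), "threshold_fraction")
  expect_error(miConfig(dpi_mode = "additive", dpi_tolerance = -1), ">= 0")
  expect_error(miConfig(dpi_mode = "multiplicative", dpi_tolerance = 1.5),
               "\\(0, 1\\]")
})

test_that("ARACNE pruning matches the brute-force triple scan", {
  for (seed in 1:5) {
    w <- randomMiMatrix(8, seed + 100)
    s <- SimilarityMatrix(w, "mi")
    for (spec in list(list("multiplicative", 1), list("multiplicative", 0.8),
                      list("additive", 0), list("additive", 0.05))) {
      got <- simWeights(aracnePrune(s, spec[[1]], spec[[2]]))
      want <- bruteDpi(w, spec[[1]], spec[[2]])
      expect_equal(got, want)
    }
  }
})

test_that("DPI pruning removes the weak edge of a known triangle", {
  ids <- c("x", "y", "z")
  w <- matrix(0, 3, 3, dimnames = list(ids, ids))
  w["x", "y"] <- w["y", "x"] <- 0.9
  w["y", "z"] <- w["z", "y"] <- 0.8
  w["x", "z"] <- w["z", "x"] <- 0.3    # indirect x-z link
  out <- simWeights(aracnePrune(SimilarityMatrix(w, "mi")))
  expect_equal(out["x", "z"], 0)
  expect_equal(out["x", "y"], 0.9)
  expect_equal(out["y", "z"], 0.8)
  # a lenient multiplicative tau keeps the indirect edge
  keep <- simWeights(aracnePrune(SimilarityMatrix(w, "mi"),
                                 "multiplicative", 0.3))
  expect_equal(keep["x", "z"], 0.3)
})

test_that("ARACNE is order-independent: permuting genes commutes", {
  w <- randomMiMatrix(7, 55)
  s <- SimilarityMatrix(w, "mi")
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  wp <- w[perm, perm]
  sp <- SimilarityMatrix(wp, "mi")
  a <- simWeights(aracnePrune(s))[perm, perm]
  b <- simWeights(aracnePrune(sp))
  expect_equal(a, b)
})

test_that("CLR matches the definitional oracle and handles flat rows", {
  for (seed in 6:9) {
    w <- randomMiMatrix(9, seed + 200)
    got <- simWeights(clrTransform(SimilarityMatrix(w, "mi")))
    expect_equal(got, bruteClr(w))
    expect_true(all(got >= 0))
  }
  flat <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(flat) <- 0
  expect_message(out <- clrTransform(SimilarityMatrix(flat, "mi")),
                 "zero MI spread")
  expect_true(all(simWeights(out) == 0))
  small <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(clrTransform(SimilarityMatrix(small, "mi")), "3 genes")
})

test_that("MRNET scores match forward MRMR selection written longhand", {
  for (seed in 10:13) {
    w <- randomMiMatrix(8, seed + 300)
    got <- simWeights(mrnetBuild(SimilarityMatrix(w, "mi")))
    expect_equal(got, bruteMrnet(w))
    expect_true(all(got >= 0))
    expect_equal(got, t(got))
  }
})

test_that("max-fraction thresholding drops isolated genes", {
  ids <- paste0("g", 1:4)
  w <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w["g1", "g2"] <- w["g2", "g1"] <- 1.0
  w["g2", "g3"] <- w["g3", "g2"] <- 0.85
  w["g3", "g4"] <- w["g4", "g3"] <- 0.5
  s <- SimilarityMatrix(w, "mi")
  net <- fractionThresholdNetwork(s, 0.8)      # threshold 0.8 x 1.0
  expect_setequal(networkNodes(net), c("g1", "g2", "g3"))  # g4 dropped
  expect_equal(nEdges(net), 2)
  net_all <- fractionThresholdNetwork(s, 0.5)
  expect_equal(nNodes(net_all), 4)
  expect_error(fractionThresholdNetwork(s, 0), "\\(0, 1\\]")
  zero <- SimilarityMatrix(matrix(0, 2, 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))),
                           "mi")
  expect_error(fractionThresholdNetwork(zero), "no edges at any threshold")
})
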