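# Graph construction, normalization and topology metrics, checked against
# exhaustive-enumeration oracles on small fixtures.

test_that("edge retention follows the ceil rule and keeps values", {
  # 12 nodes: ceil(0.10 * 66) = 7 edges survive
  set.seed(40)
  v <- runif(66, 0.1, 0.9)
  cm <- fakeConnectivity(v, sprintf("n%02d", 1:12))
  g <- buildGraph(cm, 0.10)
  expect_equal(g@meta$nRetained, 7L)
  kept <- adjacency(g)[upper.tri(adjacency(g))]
  expect_equal(sort(kept[kept > 0], decreasing = TRUE),
               sort(v, decreasing = TRUE)[1:7])
  # 4 nodes, distinct weights, retain 0.10: only the 0.9 edge survives
  cm4 <- fakeConnectivity(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), letters[1:4])
  g4 <- buildGraph(cm4, 0.10)
  expect_equal(sum(adjacency(g4) > 0) / 2, 1)
  expect_equal(max(adjacency(g4)), 0.9)
  # retain everything: identity off the diagonal
  gAll <- buildGraph(cm4, 1)
  expect_equal(adjacency(gAll)[upper.tri(diag(4))],
               c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)[c(1, 2, 4, 3, 5, 6)])
  expect_equal(diag(adjacency(gAll)), c(a = 0, b = 0, c = 0, d = 0))
})

test_that("ties at the cutoff are all kept and flagged", {
  cm <- fakeConnectivity(c(0.9, 0.8, 0.8, 0.8, 0.2, 0.1), letters[1:4])
  g <- buildGraph(cm, 1 / 6)  # m = 1 but three ties at 0.8 would be arbitrary
  expect_equal(g@meta$nRetained, 1L)
  g2 <- buildGraph(cm, 2 / 6) # m = 2, cutoff 0.8 ties -> keep all three
  expect_equal(g2@meta$nRetained, 4L)
  expect_true(g2@meta$ties)
})

test_that("retained edge sets are nested across fractions", {
  set.seed(41)
  cm <- fakeConnectivity(runif(45), sprintf("n%d", 1:10))
  e1 <- adjacency(buildGraph(cm, 0.2)) > 0
  e2 <- adjacency(buildGraph(cm, 0.6)) > 0
  expect_true(all(e2[e1]))
})

test_that("max-weight normalization is exact and idempotent", {
  cm <- fakeConnectivity(c(0.6, 0.3, 0, 0, 0, 0), letters[1:4])
  g <- normalizeWeights(buildGraph(cm, 1))
  w <- adjacency(g)[upper.tri(diag(4))]
  expect_equal(sort(w[w > 0]), c(0.5, 1.0))
  expect_equal(adjacency(normalizeWeights(g)), adjacency(g))
  zero <- new("WeightedGraph", adjacency = matrix(0, 3, 3),
              meta = list(normalized = FALSE))
  expect_error(normalizeWeights(zero), "all-zero")
})

test_that("nodal metrics match hand values on canonical fixtures", {
  full <- nodalMetrics(completeUnitGraph(4))
  expect_equal(full$degree, rep(3L, 4))
  expect_equal(full$strength, rep(3, 4))
  expect_equal(full$clustering, rep(1, 4))
  path <- nodalMetrics(pathGraph3())
  expect_equal(path$clustering, rep(0, 3))
  # unit triangle with one edge at 0.125: Onnela gives 0.5 everywhere
  tri <- nodalMetrics(unitTriangleGraph(0.125))
  expect_equal(tri$clustering, rep(0.5, 3), tolerance = 1e-12)
  expect_error(nodalMetrics(buildGraph(fakeConnectivity(rep(0.5, 3),
                                                        letters[1:3]), 1)),
               "normalized")
})

test_that("global metrics match hand values on canonical fixtures", {
  expect_equal(globalMetrics(completeUnitGraph(5))$globalEfficiency, 1)
  expect_equal(globalMetrics(pathGraph3())$globalEfficiency, 5 / 6,
               tolerance = 1e-12)
  two <- globalMetrics(twoTrianglesGraph(), seed = 1)
  expect_equal(two$modularityQ, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(two$partition)), 2)
  expect_equal(unname(two$partition[1:3]), rep(two$partition[[1]], 3))
  # brute force over all 6-node partitions confirms 0.5 is the optimum
  expect_equal(oracleBestModularity(adjacency(twoTrianglesGraph())), 0.5,
               tolerance = 1e-12)
  # equal strengths make assortativity undefined
  expect_true(is.na(globalMetrics(completeUnitGraph(4))$assortativity))
})

test_that("metrics agree with exhaustive oracles on random <= 7-node graphs", {
  for (seed in c(101, 202, 303, 404)) {
    n <- 4 + seed %% 4
    g <- randomNormalizedGraph(n, seed)
    A <- adjacency(g)
    nm <- nodalMetrics(g)
    expect_equal(nm$degree, unname(as.integer(colSums(A > 0))))
    expect_equal(nm$strength, unname(colSums(A)), tolerance = 1e-12)
    expect_equal(nm$clustering, oracleOnnela(A), tolerance = 1e-12)
    gm <- globalMetrics(g, seed = 7)
    expect_equal(gm$globalEfficiency, oracleEfficiency(A), tolerance = 1e-12)
    # the package's Q value equals the direct modularity formula applied
    # to the partition it reports
    expect_equal(gm$modularityQ, oracleModularityQ(A, gm$partition),
                 tolerance = 1e-12)
    # with normalized weights strength cannot exceed degree
    expect_true(all(nm$strength <= nm$degree + 1e-12))
  }
})

test_that("metrics are invariant to input scale after normalization", {
  set.seed(42)
  v <- runif(21, 0.05, 0.8)
  cm1 <- fakeConnectivity(v, letters[1:7])
  g1 <- normalizeWeights(buildGraph(cm1, 0.3))
  g2 <- normalizeWeights(buildGraph(msc(cm1) * 3.7 - diag(3.7 - 1, 7), 0.3))
  expect_equal(adjacency(g1), adjacency(g2), tolerance = 1e-12)
  expect_equal(nodalMetrics(g1), nodalMetrics(g2), tolerance = 1e-12)
  expect_equal(globalMetrics(g1, 3)$globalEfficiency,
               globalMetrics(g2, 3)$globalEfficiency, tolerance = 1e-12)
})

test_that("cohort metric tables have the documented shape and determinism", {
  labels <- cohortRoiLabels(24)
  set.seed(43)
  cmBySubject <- lapply(sprintf("S%d", 1:4), function(id)
    list(gamma = fakeConnectivity(runif(276, 0, 0.5), labels,
                                  bandSpec("gamma", 30, 59))))
  names(cmBySubject) <- sprintf("S%d", 1:4)
  groups <- c(S1 = "NVLD", S2 = "NVLD", S3 = "TD", S4 = "TD")
  tabs <- groupMetricTables(cmBySubject, groups, bands = "gamma", seed = 5)
  # 4 subjects x 2 networks x 2 hemispheres x 3 global measures
  expect_equal(nrow(tabs$global), 48)
  expect_equal(sum(tabs$global$measure == "global_efficiency"), 16)
  # 4 subjects x 2 networks x 12 nodes x 3 nodal measures
  expect_equal(nrow(tabs$nodal), 288)
  tabs2 <- groupMetricTables(cmBySubject, groups, bands = "gamma", seed = 5)
  expect_identical(tabs, tabs2)
  expect_error(groupMetricTables(cmBySubject, groups[1:2], bands = "gamma"),
               "missing subjects")
})
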