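test_that("the multilayer network records the documented bookkeeping", {
  a <- randomLayers(5, 3, seed = 1)
  aDiag <- a
  for (l in 1:3) diag(aDiag[, , l]) <- 1  # simulate unit-diagonal input
  net <- buildMultilayerNetwork(aDiag, gamma = 1, omega = 0.5)
  expect_equal(dim(net@layers), c(5L, 5L, 3L))
  for (l in 1:3) expect_equal(unname(diag(net@layers[, , l])), rep(0, 5))
  expect_equal(net@twom, sapply(1:3, function(l) sum(a[, , l])))
  expect_equal(net@twomu, sum(a) + 2 * 0.5 * 5 * 2)
  # single layer: 2mu = 2m_1 exactly
  net1 <- buildMultilayerNetwork(a[, , 1, drop = FALSE], omega = 0.7)
  expect_equal(net1@twomu, sum(a[, , 1]))
  expect_error(buildMultilayerNetwork(-a), "negative")
})

test_that("single-layer one-community modularity is exactly zero at gamma 1", {
  a <- randomLayers(6, 1, seed = 2)
  net <- buildMultilayerNetwork(a, gamma = 1, omega = 0)
  p <- LayerPartition(matrix(1L, 6, 1))
  expect_equal(multilayerModularity(p, net), 0, tolerance = 1e-14)
})

test_that("modularity is invariant to bijective relabeling", {
  a <- randomLayers(4, 3, seed = 3)
  net <- buildMultilayerNetwork(a, gamma = 1.2, omega = 0.4)
  lab <- matrix(sample(1:3, 12, replace = TRUE), 4, 3)
  relab <- matrix(c(7L, 5L, 9L)[lab], 4, 3)
  expect_equal(multilayerModularity(LayerPartition(lab), net),
               multilayerModularity(LayerPartition(relab), net),
               tolerance = 1e-14)
})

test_that("modularity agrees with the direct quadruple-sum oracle", {
  for (seed in 1:6) {
    a <- randomLayers(4, 2, seed = seed)
    gamma <- c(1, 1, 0.8, 1.3, 1, 0.5)[seed]
    omega <- c(0.2, 1, 0, 0.6, 2, 0.9)[seed]
    net <- buildMultilayerNetwork(a, gamma = gamma, omega = omega)
    lab <- matrix(sample(1:4, 8, replace = TRUE), 4, 2)
    expect_equal(multilayerModularity(LayerPartition(lab), net),
                 directModularity(lab, a, gamma, omega),
                 tolerance = 1e-12)
  }
})

test_that("louvain attains the enumerated maximum on 4-node 2-layer instances", {
  for (seed in 1:4) {
    a <- randomLayers(4, 2, seed = 100 + seed)
    omega <- c(0.1, 0.5, 1, 0)[seed]
    net <- buildMultilayerNetwork(a, gamma = 1, omega = omega)
    qStar <- bruteForceMaxQ(a, 1, omega)
    qBest <- max(vapply(1:100, function(s) {
      louvainMultilayer(net, seed = s)@Q
    }, numeric(1)))
    expect_equal(qBest, qStar, tolerance = 1e-10)
  }
})

test_that("louvain's reported Q matches recomputing Q from its partition", {
  a <- randomLayers(6, 4, seed = 9)
  net <- buildMultilayerNetwork(a, gamma = 1, omega = 0.3)
  for (s in 1:5) {
    part <- louvainMultilayer(net, seed = s)
    expect_equal(part@Q, multilayerModularity(part, net),
                 tolerance = 1e-12)
    # never below the all-singletons partition
    singletons <- matrix(seq_len(24), 6, 4)
    expect_gte(part@Q + 1e-12,
               multilayerModularity(LayerPartition(singletons), net))
  }
})

test_that("louvain is reproducible given a seed", {
  a <- randomLayers(7, 5, seed = 17)
  net <- buildMultilayerNetwork(a, omega = 0.2)
  p1 <- louvainMultilayer(net, seed = 42)
  p2 <- louvainMultilayer(net, seed = 42)
  expect_identical(partitionLabels(p1), partitionLabels(p2))
})

test_that("two disconnected triangles are split into their components", {
  a <- array(0, c(6, 6, 1))
  tri <- matrix(1, 3, 3) - diag(3)
  a[1:3, 1:3, 1] <- tri
  a[4:6, 4:6, 1] <- tri
  net <- buildMultilayerNetwork(a, gamma = 1, omega = 0)
  part <- louvainMultilayer(net, seed = 1)
  lab <- partitionLabels(part)
  expect_length(unique(lab[1:3]), 1L)
  expect_length(unique(lab[4:6]), 1L)
  expect_false(lab[1] == lab[4])
})

test_that("omega = 0 decouples layers; dominant omega freezes labels in time", {
  a <- randomLayers(5, 4, seed = 23)
  # omega much larger than any coherence weight: one label per node
  # across all layers -> zero flexibility downstream
  netBig <- buildMultilayerNetwork(a, omega = 50)
  part <- louvainMultilayer(netBig, seed = 3)
  lab <- partitionLabels(part)
  for (i in 1:5) expect_length(unique(lab[i, ]), 1L)
  expect_equal(networkFlexibility(flexibility(part)), 0)
  # omega = 0: supra matrix has no inter-layer terms
  net0 <- buildMultilayerNetwork(a, omega = 0)
  b <- mtlflex:::supraModularityMatrix(net0)
  for (l in 1:3) {
    expect_equal(sum(abs(b[((l - 1) * 5 + 1):(l * 5),
                           (l * 5 + 1):((l + 1) * 5)])), 0)
  }
})

test_that("flexibility counts label changes over L - 1 transitions", {
  lab <- matrix(1L, 7, 16)
  expect_equal(networkFlexibility(flexibility(LayerPartition(lab))), 0)
  # alternate every layer -> 1
  alt <- matrix(rep(c(1L, 2L), 8), 7, 16, byrow = TRUE)
  f <- flexibility(LayerPartition(alt))
  expect_equal(unname(nodeFlexibility(f)), rep(1, 7))
  # exactly 3 changes across 16 layers -> 0.2
  lab3 <- matrix(1L, 2, 16)
  lab3[1, 5:8] <- 2L
  lab3[1, 9:13] <- 3L
  lab3[1, 14:16] <- 4L
  f3 <- nodeFlexibility(flexibility(LayerPartition(lab3)))
  expect_equal(unname(f3[1]), 0.2)
  expect_equal(unname(f3[2]), 0)
  expect_error(flexibility(LayerPartition(matrix(1L, 3, 1))),
               "single-layer")
})

test_that("flexibilityPipeline with one run equals single-run flexibility", {
  a <- randomLayers(5, 6, seed = 29)
  net <- buildMultilayerNetwork(a, omega = 0.3)
  res <- flexibilityPipeline(a, omega = 0.3, nRuns = 1L, seed = 77)
  seed1 <- mtlflex:::childSeeds(77, 1L)
  single <- flexibility(louvainMultilayer(net, seed = seed1))
  expect_equal(unname(nodeFlexibility(res)),
               unname(nodeFlexibility(single)))
  expect_equal(networkFlexibility(res),
               mean(nodeFlexibility(res)))
})

test_that("mean flexibility is nonincreasing in omega on fixed synthetic input", {
  omegas <- c(0.1, 0.5, 1, 2, 5)
  nSeeds <- 20
  tensors <- lapply(seq_len(nSeeds), function(s) {
    connectivityTensor(simulateRoiTimeSeries(
      plantedDynamicsConfig(segmentMemberships = switchSchedule(),
                            seed = 9000L + s)))
  })
  meanFlex <- vapply(omegas, function(om) {
    mean(vapply(seq_len(nSeeds), function(s) {
      networkFlexibility(flexibilityPipeline(tensors[[s]], omega = om,
                                             nRuns = 3L, seed = 11L))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanFlex) <= 1e-9))
})
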