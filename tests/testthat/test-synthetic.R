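test_that("simulated ROI series have the configured shape and are seed-deterministic", {
  cfg <- plantedDynamicsConfig(seed = 11L)
  ts <- simulateRoiTimeSeries(cfg)
  expect_s4_class(ts, "SubjectTimeSeries")
  expect_identical(dim(as.matrix(ts)), c(7L, 812L))
  expect_identical(roiNames(ts), mtlRoiNames())
  ts2 <- simulateRoiTimeSeries(plantedDynamicsConfig(seed = 11L))
  expect_identical(as.matrix(ts), as.matrix(ts2))
  ts3 <- simulateRoiTimeSeries(plantedDynamicsConfig(seed = 12L))
  expect_false(identical(as.matrix(ts), as.matrix(ts3)))
})

test_that("invalid planted-dynamics configs are rejected", {
  expect_error(
    plantedDynamicsConfig(segmentMemberships = list(
      list(length = 500L, labels = rep(1L, 7)))),
    "segment lengths")
  expect_error(
    plantedDynamicsConfig(segmentMemberships = list(
      list(length = 812L, labels = c(1L, 2L)))),
    "one label per node")
  expect_error(plantedDynamicsConfig(withinCoupling = -1), "withinCoupling")
})

test_that("planted flexibility matches hand-derived label schedules", {
  # no switches -> 0 for every node
  cfg0 <- plantedDynamicsConfig()
  expect_equal(unname(plantedFlexibility(cfg0)), rep(0, 7))

  # one boundary-aligned switch over 16 windows -> 1/15 for switching nodes
  segs1 <- list(
    list(length = 406L, labels = c(1L, 1L, 1L, 2L, 2L, 2L, 2L)),
    list(length = 406L, labels = c(2L, 1L, 1L, 1L, 2L, 2L, 2L)))
  cfg1 <- plantedDynamicsConfig(segmentMemberships = segs1)
  f1 <- unname(plantedFlexibility(cfg1))
  expect_equal(f1[c(1, 4)], rep(1 / 15, 2))
  expect_equal(f1[c(2, 3, 5, 6, 7)], rep(0, 5))

  # node switching at every window boundary -> flexibility 1
  segs <- lapply(seq_len(16L), function(w) {
    lab <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L)
    lab[1] <- if (w %% 2L == 0L) 2L else 1L
    list(length = 50L + (w == 1L) * 6L + (w == 16L) * 6L, labels = lab)
  })
  cfgAll <- plantedDynamicsConfig(segmentMemberships = segs)
  expect_equal(unname(plantedFlexibility(cfgAll))[1], 1)
})

test_that("window-straddling switch ties break to the earlier segment's label", {
  # switch at the midpoint of window 1 (trim 6, window 50: points 7-56,
  # switch after point 31 -> 25 points each label): tie -> earlier label
  segs <- list(list(length = 31L, labels = rep(1L, 7)),
               list(length = 781L, labels = rep(2L, 7)))
  cfg <- plantedDynamicsConfig(segmentMemberships = segs)
  f <- plantedFlexibility(cfg)
  # window 1 majority ties 25/25 -> label 1; window 2 onward label 2:
  # exactly one change per node
  expect_equal(unname(f), rep(1 / 15, 7))
})

test_that("swap switch schedules plant the requested per-node change count", {
  segs <- switchSchedule(nNodes = 7L, nWindows = 16L, changesPerNode = 4L)
  cfg <- plantedDynamicsConfig(segmentMemberships = segs)
  expect_equal(unname(plantedFlexibility(cfg)), rep(4 / 15, 7))
  # both communities always keep at least two members
  for (s in segs) expect_true(all(table(s$labels) >= 2))
})

test_that("within-community band coherence exceeds between-community coherence", {
  # Monte-Carlo over seeds, using the coherence operation itself on the
  # no-switch two-community layout
  nSeeds <- 15
  diffs <- vapply(seq_len(nSeeds), function(s) {
    cfg <- plantedDynamicsConfig(seed = 1000L + s)
    tens <- as.array(connectivityTensor(simulateRoiTimeSeries(cfg)))
    within <- c(apply(tens[1:3, 1:3, , drop = FALSE], 3,
                      function(m) m[upper.tri(m)]),
                apply(tens[4:7, 4:7, , drop = FALSE], 3,
                      function(m) m[upper.tri(m)]))
    between <- as.vector(tens[1:3, 4:7, ])
    mean(within) - mean(between)
  }, numeric(1))
  expect_gt(mean(diffs), 0.2)
})

test_that("synthetic cohorts are deterministic and null cohorts uncorrelated", {
  c1 <- simulateCohort(cohortConfig(200, seed = 42L))
  c2 <- simulateCohort(cohortConfig(200, seed = 42L))
  expect_identical(c1, c2)

  big <- simulateCohort(cohortConfig(10000, seed = 7L))
  preds <- c("ptau231", "ptau181", "abeta_ratio", "network_flexibility")
  outs <- c("ae_accuracy", "ravlt_delayed")
  for (p in preds) for (o in outs) {
    expect_lt(abs(cor(big[[p]], big[[o]])), 0.03)
  }
  expect_true(all(big$ptau231 >= 0 & big$ptau181 >= 0 &
                  big$abeta_ratio >= 0))
  expect_true(all(big$sex %in% c(0, 1)))
})

test_that("a planted standardized effect is recovered by the adjusted fit", {
  eff <- data.frame(predictor = "network_flexibility",
                    outcome = "ae_accuracy", beta = 0.28)
  coh <- simulateCohort(cohortConfig(5000, eff, seed = 19L))
  fit <- fitAdjustedModel(coh, "ae_accuracy", "network_flexibility",
                          c("age", "sex", "education",
                            "ae_acquisition_score"))
  expect_lt(abs(fit$beta - 0.28), 0.05)
  # cross-check against the closed-form normal-equations oracle
  z <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(1, z(coh$network_flexibility), z(coh$age), coh$sex,
             z(coh$education), z(coh$ae_acquisition_score))
  oracle <- normalEquationsFit(z(coh$ae_accuracy), X)
  expect_equal(fit$beta, oracle$beta[2], tolerance = 1e-10)
})

test_that("estimated flexibility is nondecreasing in the planted switch count", {
  nSeeds <- 12
  meanFlex <- sapply(c(0L, 2L, 4L), function(nChanges) {
    segs <- if (nChanges == 0L) NULL
            else switchSchedule(changesPerNode = nChanges)
    mean(vapply(seq_len(nSeeds), function(s) {
      cfg <- plantedDynamicsConfig(segmentMemberships = segs,
                                   seed = 5000L + nChanges * 100L + s)
      tens <- connectivityTensor(simulateRoiTimeSeries(cfg))
      networkFlexibility(flexibilityPipeline(tens, nRuns = 5L,
                                             seed = 33L + s))
    }, numeric(1)))
  })
  expect_true(all(diff(meanFlex) >= 0))
})
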