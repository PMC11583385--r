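test_that("every task spec preserves the trained-association structure", {
  for (seed in c(1L, 7L, 99L, 1234L)) {
    spec <- aeTask(seed)
    expect_equal(nrow(spec$associations), 6L)
    expect_equal(nrow(spec$transfer), 48L)
    expect_equal(sum(spec$transfer$tag == "old"), 36L)
    expect_equal(sum(spec$transfer$tag == "new"), 12L)
    # stage contents per the paradigm table
    s1 <- spec$associations[spec$associations$stage == 1, ]
    expect_setequal(paste(s1$antecedent, s1$consequent),
                    c("A1 X1", "B1 Y1"))
    s2 <- spec$associations[spec$associations$stage == 2, ]
    expect_setequal(paste(s2$antecedent, s2$consequent),
                    c("A2 X1", "B2 Y1"))
    s3 <- spec$associations[spec$associations$stage == 3, ]
    expect_setequal(paste(s3$antecedent, s3$consequent),
                    c("A1 X2", "B1 Y2"))
    # new trials are exactly the equivalence-implied pairings
    nt <- unique(spec$transfer[spec$transfer$tag == "new",
                               c("antecedent", "consequent")])
    expect_setequal(paste(nt$antecedent, nt$consequent),
                    c("A2 X2", "B2 Y2"))
  }
})

test_that("seeds change stimulus assignment and order, not structure", {
  s1 <- aeTask(1L)
  s2 <- aeTask(2L)
  expect_identical(s1$associations, s2$associations)
  expect_false(identical(s1$stimuli, s2$stimuli))
  expect_false(identical(s1$transfer$tag, s2$transfer$tag) &&
               identical(s1$transfer$antecedent, s2$transfer$antecedent))
  expect_identical(aeTask(5L), aeTask(5L))
})

test_that("acquisition advances on an error-free block and is bounded", {
  spec <- aeTask(3L)
  key <- with(spec$associations,
              setNames(consequent, paste(antecedent, consequent, sep = "|")))
  # perfect responder: each stage ends after its first error-free block
  perfect <- function(a, o1, o2) {
    corr <- spec$associations$consequent[
      spec$associations$antecedent == a &
      spec$associations$consequent %in% c(o1, o2)]
    corr[1]
  }
  log <- runAcquisition(spec, perfect, seed = 1L)
  expect_equal(nrow(log), 2L + 4L + 6L)  # one block per stage
  expect_length(attr(log, "truncated"), 0L)
  expect_true(all(log$correct))
  # stage 3 blocks contain all six associations
  s3 <- log[log$phase == "stage3", ]
  expect_equal(nrow(s3), 6L)
  expect_setequal(paste(s3$antecedent, s3$consequent),
                  paste(spec$associations$antecedent,
                        spec$associations$consequent))
  # never-correct responder terminates at maxBlocks with truncation flags
  wrong <- function(a, o1, o2) {
    corr <- perfect(a, o1, o2)
    if (identical(o1, corr)) o2 else o1
  }
  logW <- runAcquisition(spec, wrong, maxBlocks = 10L, seed = 2L)
  expect_setequal(attr(logW, "truncated"),
                  c("stage1", "stage2", "stage3"))
  expect_equal(max(logW$block[logW$phase == "stage1"]), 10L)
  expect_true(all(!logW$correct))
  expect_error(runAcquisition(spec, perfect, maxBlocks = 0L), "maxBlocks")
})

test_that("scores follow their defining identities on fixture logs", {
  mkTransfer <- function(okOld, okNew) {
    data.frame(phase = "transfer",
               tag = rep(c("old", "new"), c(36, 12)),
               correct = c(okOld, okNew))
  }
  sAll <- scoreResponses(mkTransfer(rep(TRUE, 36), rep(TRUE, 12)))
  expect_equal(sAll$accuracy_percent, 100)
  expect_equal(sAll$transfer_error_proportion, 0)

  sHalf <- scoreResponses(mkTransfer(rep(c(TRUE, FALSE), 18),
                                     rep(c(TRUE, FALSE), 6)))
  expect_equal(sHalf$transfer_error_proportion, 0.5)

  # all 36 old correct, 6 of 12 new correct (hand count: 6 errors / 48)
  sMix <- scoreResponses(mkTransfer(rep(TRUE, 36),
                                    rep(c(TRUE, FALSE), 6)))
  expect_equal(sMix$generalization_accuracy, 0.5)
  expect_equal(sMix$retention_accuracy, 1)
  expect_equal(sMix$transfer_error_proportion, 6 / 48)
  expect_equal(sMix$accuracy_percent, 100 * 42 / 48)
  expect_error(scoreResponses(
    data.frame(phase = "stage1", tag = NA, correct = TRUE)), "transfer")
})

test_that("retention and generalization recombine to transfer accuracy 36:12", {
  spec <- aeTask(11L)
  for (seed in 1:5) {
    log <- simulateAgent(spec, retentionP = 0.8, generalizationP = 0.4,
                         seed = seed)
    sc <- scoreResponses(log)
    expect_equal((36 * sc$retention_accuracy +
                  12 * sc$generalization_accuracy) / 48,
                 1 - sc$transfer_error_proportion, tolerance = 1e-12)
  }
})

test_that("simulated agents hit their transfer probabilities in expectation", {
  spec <- aeTask(2L)
  # deterministic extremes
  sPerfect <- scoreResponses(simulateAgent(spec, 1, 1, seed = 1L))
  expect_equal(sPerfect$transfer_error_proportion, 0)
  # retention 1, generalization 0.5: E[error] = 12 * 0.5 / 48 = 0.125
  errs <- vapply(seq_len(2000), function(s) {
    scoreResponses(simulateAgent(spec, 1, 0.5,
                                 seed = s))$transfer_error_proportion
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.125), 0.005)
})

test_that("a non-learning agent performs at chance in acquisition", {
  spec <- aeTask(4L)
  accs <- vapply(1:300, function(s) {
    log <- simulateAgent(spec, 1, 1, learningRate = 0, seed = 1000L + s)
    mean(log$correct[log$phase != "transfer"])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("expected transfer error decreases as generalization improves", {
  spec <- aeTask(6L)
  meanErr <- vapply(c(0.2, 0.5, 0.8), function(gp) {
    mean(vapply(1:400, function(s) {
      scoreResponses(simulateAgent(spec, 0.9, gp,
                                   seed = s))$transfer_error_proportion
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanErr) < 0))
})

test_that("RAVLT scores implement percent forgetting with its edge cases", {
  s0 <- ravltScores(c(5, 7, 9, 11, 12, 11), delayedRecall = 12)
  expect_equal(s0$percent_forgetting, 0)
  s50 <- ravltScores(c(4, 6, 8, 9, 10, 8), delayedRecall = 5)
  expect_equal(s50$percent_forgetting, 50)
  expect_false(s50$percent_forgetting_missing)
  # trial 5 = 0: undefined, flagged missing, not an error
  sMiss <- ravltScores(c(0, 0, 0, 0, 0, 0), delayedRecall = 0)
  expect_true(sMiss$percent_forgetting_missing)
  expect_true(is.na(sMiss$percent_forgetting))
  expect_error(ravltScores(c(5, 7, 9, 11, 12, 11), delayedRecall = 16),
               "0, 15")
  expect_error(ravltScores(c(5, 7, 9, 11, 12, 11), delayedRecall = -1),
               "0, 15")
})
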