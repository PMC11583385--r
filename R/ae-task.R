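#' Build a Rutgers acquired equivalence task specification
#'
#' Generates the task's trial structure. Four face antecedents (roles
#' A1, A2, B1, B2) and four fish consequents (roles X1, X2, Y1, Y2) are
#' randomly assigned from the stimulus pools. Acquisition trains six
#' associations over three stages: stage 1 trains A1->X1 and B1->Y1;
#' stage 2 adds A2->X1 and B2->Y1 (different faces mapped to the same
#' fish, the equivalence training); stage 3 adds A1->X2 and B1->Y2 (new
#' fish). The transfer phase has 48 trials — 36 old (each trained
#' association six times) and 12 new (the equivalence-implied pairings
#' A2->X2 and B2->Y2, six times each) — interleaved in seeded random
#' order with randomized left/right placement. The foil on every trial
#' is the same-stage consequent of the opposite antecedent family
#' (X1 vs Y1, X2 vs Y2).
#'
#' @param assignmentSeed RNG seed for stimulus-role assignment and
#'   transfer order.
#'
#' @return A list with class `"aeTaskSpec"`: `stimuli` (role -> drawing
#'   assignment), `associations` (data.frame: stage, antecedent,
#'   consequent, foil), and `transfer` (data.frame of 48 trials: tag
#'   old/new, antecedent, consequent, foil, left/right placement).
#' @export
aeTask <- function(assignmentSeed = 1L) {
  withSeed(assignmentSeed, {
    faces <- sample(c("woman1", "woman2", "man1", "man2"))
    fish <- sample(c("red_fish", "orange_fish", "purple_fish", "pink_fish"))
    stimuli <- c(A1 = faces[1], A2 = faces[2], B1 = faces[3], B2 = faces[4],
                 X1 = fish[1], X2 = fish[2], Y1 = fish[3], Y2 = fish[4])
    associations <- data.frame(
      stage = c(1L, 1L, 2L, 2L, 3L, 3L),
      antecedent = c("A1", "B1", "A2", "B2", "A1", "B1"),
      consequent = c("X1", "Y1", "X1", "Y1", "X2", "Y2"),
      foil = c("Y1", "X1", "Y1", "X1", "Y2", "X2"),
      stringsAsFactors = FALSE)
    newPairs <- data.frame(
      antecedent = c("A2", "B2"), consequent = c("X2", "Y2"),
      foil = c("Y2", "X2"), stringsAsFactors = FALSE)
    old <- associations[rep(seq_len(6L), each = 6L),
                        c("antecedent", "consequent", "foil")]
    old$tag <- "old"
    newt <- newPairs[rep(1:2, each = 6L), ]
    newt$tag <- "new"
    transfer <- rbind(old, newt)
    transfer <- transfer[sample.int(nrow(transfer)), ]
    transfer$correct_side <- sample(c("left", "right"), nrow(transfer),
                                    replace = TRUE)
    rownames(transfer) <- NULL
    structure(list(stimuli = stimuli, associations = associations,
                   transfer = transfer, assignmentSeed = assignmentSeed),
              class = "aeTaskSpec")
  })
}

#' @export
print.aeTaskSpec <- function(x, ...) {
  cat("Rutgers acquired equivalence task\n")
  cat("  6 trained associations over 3 acquisition stages\n")
  cat(sprintf("  transfer: %d trials (%d old, %d new)\n",
              nrow(x$transfer), sum(x$transfer$tag == "old"),
              sum(x$transfer$tag == "new")))
  invisible(x)
}

#' Run the acquisition phase against a responder
#'
#' Presents criterion-based acquisition blocks. The active associations
#' at stage s are all associations trained up to and including stage s
#' (earlier pairs stay interleaved). Each block presents every active
#' association once in random order; a stage advances after
#' `criterionBlocks` consecutive error-free blocks, or terminates with a
#' truncation flag after `maxBlocks`. Corrective feedback is implied on
#' every acquisition trial; per-trial timing (1 s feedback, 1 s
#' intertrial interval) is recorded but has no computational effect.
#'
#' @param spec an [aeTask()] specification.
#' @param respond function(antecedent, option1, option2) returning the
#'   chosen consequent role; called once per trial.
#' @param criterionBlocks error-free blocks required to advance
#'   (default 1).
#' @param maxBlocks maximum blocks per stage (default 10).
#' @param seed RNG seed for block orders.
#'
#' @return A data.frame response log with one row per presented trial:
#'   `phase`, `block`, `tag` (NA for acquisition), `antecedent`,
#'   `consequent`, `foil`, `chosen`, `correct`, `feedback`,
#'   `feedback_s`, `iti_s`, plus an attribute `truncated` naming stages
#'   stopped at `maxBlocks`.
#' @export
runAcquisition <- function(spec, respond, criterionBlocks = 1L,
                           maxBlocks = 10L, seed = 1L) {
  stopifnot(inherits(spec, "aeTaskSpec"), is.function(respond))
  if (maxBlocks < 1L) stop("'maxBlocks' must be at least 1")
  withSeed(seed, {
    rows <- list()
    truncated <- character()
    for (stage in 1:3) {
      active <- spec$associations[spec$associations$stage <= stage, ,
                                  drop = FALSE]
      streak <- 0L
      for (block in seq_len(maxBlocks)) {
        ord <- sample.int(nrow(active))
        errors <- 0L
        for (i in ord) {
          a <- active$antecedent[i]
          corr <- active$consequent[i]
          foil <- active$foil[i]
          opts <- sample(c(corr, foil))
          chosen <- respond(a, opts[1], opts[2])
          ok <- identical(chosen, corr)
          if (!ok) errors <- errors + 1L
          rows[[length(rows) + 1L]] <- data.frame(
            phase = paste0("stage", stage), block = block,
            tag = NA_character_, antecedent = a, consequent = corr,
            foil = foil, chosen = chosen, correct = ok, feedback = TRUE,
            feedback_s = 1, iti_s = 1, stringsAsFactors = FALSE)
        }
        streak <- if (errors == 0L) streak + 1L else 0L
        if (streak >= criterionBlocks) break
        if (block == maxBlocks) {
          truncated <- c(truncated, paste0("stage", stage))
        }
      }
    }
    log <- do.call(rbind, rows)
    attr(log, "truncated") <- truncated
    log
  })
}

#' Simulate an agent on the acquired equivalence task
#'
#' Acquisition responses come from an incremental associative learner:
#' association strengths V(antecedent, consequent) start at zero, the
#' choice between the two displayed fish is a logistic (soft) selection
#' on the strength difference, and feedback updates the chosen
#' association by `learningRate * (reward - V)`. With
#' `learningRate = 0` the agent stays at chance. Transfer responses are
#' Bernoulli: old trials are answered correctly with probability
#' `retentionP`, new (generalization) trials with probability
#' `generalizationP` — allowing the dissociation of intact learning
#' with impaired generalization to be simulated.
#'
#' @param spec an [aeTask()] specification.
#' @param retentionP probability of a correct old-association transfer
#'   response.
#' @param generalizationP probability of a correct new-association
#'   transfer response.
#' @param learningRate acquisition learning rate in [0, 1] (default 0.3).
#' @param criterionBlocks,maxBlocks acquisition schedule controls, see
#'   [runAcquisition()].
#' @param seed RNG seed.
#'
#' @return A data.frame response log covering acquisition and transfer
#'   (transfer rows have `feedback = FALSE`).
#' @export
simulateAgent <- function(spec, retentionP, generalizationP,
                          learningRate = 0.3, criterionBlocks = 1L,
                          maxBlocks = 10L, seed = 1L) {
  stopifnot(inherits(spec, "aeTaskSpec"))
  for (p in c(retentionP, generalizationP)) {
    stopUnlessScalar(p, "probability", 0, 1)
  }
  stopUnlessScalar(learningRate, "learningRate", 0, 1)
  withSeed(seed, {
    roles <- c("A1", "A2", "B1", "B2")
    cons <- c("X1", "X2", "Y1", "Y2")
    v <- matrix(0, 4, 4, dimnames = list(roles, cons))
    respond <- function(a, opt1, opt2) {
      p1 <- stats::plogis(4 * (v[a, opt1] - v[a, opt2]))
      choice <- if (stats::runif(1) < p1) opt1 else opt2
      other <- if (identical(choice, opt1)) opt2 else opt1
      corr <- spec$associations$consequent[
        spec$associations$antecedent == a &
        spec$associations$consequent %in% c(opt1, opt2)]
      reward <- as.numeric(length(corr) && identical(choice, corr[1]))
      v[a, choice] <<- v[a, choice] +
        learningRate * (reward - v[a, choice])
      choice
    }
    acq <- runAcquisition(spec, respond, criterionBlocks, maxBlocks,
                          seed = sample.int(2147483646L, 1L))
    tr <- spec$transfer
    pCorrect <- ifelse(tr$tag == "old", retentionP, generalizationP)
    ok <- stats::runif(nrow(tr)) < pCorrect
    trans <- data.frame(
      phase = "transfer", block = NA_integer_, tag = tr$tag,
      antecedent = tr$antecedent, consequent = tr$consequent,
      foil = tr$foil, chosen = ifelse(ok, tr$consequent, tr$foil),
      correct = ok, feedback = FALSE, feedback_s = NA_real_,
      iti_s = 1, stringsAsFactors = FALSE)
    log <- rbind(acq, trans)
    attr(log, "truncated") <- attr(acq, "truncated")
    log
  })
}

#' Score an acquired equivalence response log
#'
#' Computes the task's dependent measures: the average number of errors
#' per acquisition trial, the proportion of incorrect transfer
#' responses, the transfer accuracy percentage (100 x correct / total
#' transfer trials — the headline accuracy score), the pooled
#' accuracy percentage over acquisition plus transfer, and the separate
#' retention (old trials) and generalization (new trials) accuracies.
#' Retention and generalization recombine exactly to the overall
#' transfer accuracy with 36:12 weights.
#'
#' @param log a response log from [simulateAgent()] or
#'   [runAcquisition()] plus transfer rows; columns `phase`, `tag`,
#'   `correct` are required.
#'
#' @return A list with class `"aeScores"`: `acquisition_mean_errors`,
#'   `acquisition_n_trials`, `transfer_error_proportion`,
#'   `accuracy_percent`, `accuracy_percent_pooled`,
#'   `retention_accuracy`, `generalization_accuracy`.
#' @export
scoreResponses <- function(log) {
  stopifnot(is.data.frame(log),
            all(c("phase", "tag", "correct") %in% names(log)))
  acq <- log[log$phase != "transfer", , drop = FALSE]
  trans <- log[log$phase == "transfer", , drop = FALSE]
  if (nrow(trans) == 0L) {
    stop("response log has no transfer trials; scores are undefined")
  }
  old <- trans[trans$tag == "old", , drop = FALSE]
  newt <- trans[trans$tag == "new", , drop = FALSE]
  res <- list(
    acquisition_mean_errors =
      if (nrow(acq)) mean(!acq$correct) else NA_real_,
    acquisition_n_trials = nrow(acq),
    transfer_error_proportion = mean(!trans$correct),
    accuracy_percent = 100 * mean(trans$correct),
    accuracy_percent_pooled = 100 * mean(log$correct),
    retention_accuracy =
      if (nrow(old)) mean(old$correct) else NA_real_,
    generalization_accuracy =
      if (nrow(newt)) mean(newt$correct) else NA_real_)
  structure(res, class = "aeScores")
}

#' @export
print.aeScores <- function(x, ...) {
  cat("Acquired equivalence scores\n")
  cat(sprintf("  acquisition: %.3f errors/trial over %d trials\n",
              x$acquisition_mean_errors, x$acquisition_n_trials))
  cat(sprintf("  transfer error proportion: %.3f (accuracy %.1f%%)\n",
              x$transfer_error_proportion, x$accuracy_percent))
  cat(sprintf("  retention %.3f | generalization %.3f\n",
              x$retention_accuracy, x$generalization_accuracy))
  invisible(x)
}

#' RAVLT score derivation
#'
#' Derives the Rey Auditory Verbal Learning Test summary scores from
#' the per-trial recall counts: the delayed recall (words recalled
#' after the ~20 minute delay; higher is better) and percent
#' forgetting, `100 * (trial5 - delayed) / trial5`, the relative loss
#' from the fifth learning trial to delayed recall. When trial 5 is
#' zero, percent forgetting is undefined and returned as `NA` with a
#' flag rather than an error.
#'
#' @param trialRecalls integer vector of recall counts for learning
#'   trials 1-5 and the post-interference trial 6 (each 0-15 words).
#' @param delayedRecall delayed recall count (0-15).
#'
#' @return A list with class `"ravltScores"`: `trial_recalls`,
#'   `delayed_recall`, `percent_forgetting`,
#'   `percent_forgetting_missing`.
#' @examples
#' ravltScores(c(5, 7, 9, 10, 10, 9), delayedRecall = 5)
#' @export
ravltScores <- function(trialRecalls, delayedRecall) {
  vals <- c(trialRecalls, delayedRecall)
  if (any(vals != floor(vals)) || any(vals < 0) || any(vals > 15)) {
    stop("recall counts must be integers in [0, 15]")
  }
  if (length(trialRecalls) < 5L) {
    stop("recall counts for at least trials 1-5 are required")
  }
  t5 <- trialRecalls[5L]
  missing <- t5 == 0
  pf <- if (missing) NA_real_ else 100 * (t5 - delayedRecall) / t5
  structure(list(trial_recalls = as.integer(trialRecalls),
                 delayed_recall = as.integer(delayedRecall),
                 percent_forgetting = pf,
                 percent_forgetting_missing = missing),
            class = "ravltScores")
}

#' @export
print.ravltScores <- function(x, ...) {
  cat(sprintf("RAVLT: delayed recall %d", x$delayed_recall))
  if (x$percent_forgetting_missing) {
    cat(", percent forgetting undefined (trial 5 = 0)\n")
  } else {
    cat(sprintf(", percent forgetting %.1f%%\n", x$percent_forgetting))
  }
  invisible(x)
}
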