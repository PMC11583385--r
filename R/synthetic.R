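#' Configuration for ROI time series with planted dynamic communities
#'
#' Describes a synthetic subject: band-limited ROI signals with a
#' piecewise-constant planted community structure that switches at known
#' times. Within each segment, nodes sharing a community label share a
#' common narrowband signal (Gaussian noise band-pass filtered to
#' `band`) scaled by `withinCoupling`, on top of independent unit-variance
#' broadband noise. The planted labels are the ground truth against which
#' estimated flexibility is tested.
#'
#' @param nNodes number of ROIs (default 7).
#' @param nTimepoints number of time points (default 812).
#' @param samplingInterval sampling interval in seconds (default 0.664).
#' @param band narrowband frequency interval in Hz (default
#'   `c(0.06, 0.12)`).
#' @param segmentMemberships list of segments, each a
#'   `list(length = <time points>, labels = <community label per node>)`.
#'   Segment lengths must sum to `nTimepoints`. Default: a single
#'   segment with two communities (first 3 nodes vs the rest).
#' @param withinCoupling amplitude ratio of the shared band-limited
#'   signal to the independent noise (default 2, >= 0).
#' @param seed RNG seed.
#'
#' @return A list with class `"plantedDynamicsConfig"`.
#' @seealso [simulateRoiTimeSeries()], [plantedFlexibility()],
#'   [switchSchedule()]
#' @export
plantedDynamicsConfig <- function(nNodes = 7L, nTimepoints = 812L,
                                  samplingInterval = 0.664,
                                  band = c(0.06, 0.12),
                                  segmentMemberships = NULL,
                                  withinCoupling = 2, seed = 1L) {
  stopUnlessScalar(nNodes, "nNodes", 2)
  stopUnlessScalar(nTimepoints, "nTimepoints", 2)
  stopUnlessScalar(withinCoupling, "withinCoupling", 0)
  if (is.null(segmentMemberships)) {
    half <- max(1L, nNodes %/% 2L)  # 3 vs 4 for n = 7
    labels <- rep(c(1L, 2L), c(half, nNodes - half))
    segmentMemberships <- list(list(length = as.integer(nTimepoints),
                                    labels = labels))
  }
  lens <- vapply(segmentMemberships, function(s) as.integer(s$length), 1L)
  if (sum(lens) != nTimepoints) {
    stop(sprintf("segment lengths sum to %d, not nTimepoints = %d",
                 sum(lens), nTimepoints), call. = FALSE)
  }
  for (s in segmentMemberships) {
    if (length(s$labels) != nNodes) {
      stop("every segment must assign exactly one label per node",
           call. = FALSE)
    }
  }
  structure(list(nNodes = as.integer(nNodes),
                 nTimepoints = as.integer(nTimepoints),
                 samplingInterval = samplingInterval,
                 band = as.numeric(band),
                 segmentMemberships = segmentMemberships,
                 withinCoupling = withinCoupling,
                 seed = as.integer(seed)),
            class = "plantedDynamicsConfig")
}

# Gaussian noise band-pass filtered to `band` by zeroing FFT bins outside
# it, rescaled to unit standard deviation.
bandLimitedNoise <- function(n, samplingInterval, band) {
  z <- stats::rnorm(n)
  zf <- stats::fft(z)
  f <- (0:(n - 1)) / (n * samplingInterval)
  fMirror <- pmin(f, 1 / samplingInterval - f)
  keep <- fMirror >= band[1] & fMirror <= band[2]
  if (!any(keep)) stop("band too narrow for the requested series length")
  zf[!keep] <- 0
  s <- Re(stats::fft(zf, inverse = TRUE)) / n
  s / stats::sd(s)
}

#' Planted per-timepoint community labels
#'
#' Expands the segment memberships of a [plantedDynamicsConfig()] into a
#' node x timepoint label matrix.
#'
#' @param config a [plantedDynamicsConfig()].
#' @return Integer matrix, `nNodes` x `nTimepoints`.
#' @export
plantedLabels <- function(config) {
  stopifnot(inherits(config, "plantedDynamicsConfig"))
  lab <- matrix(0L, config$nNodes, config$nTimepoints)
  at <- 0L
  for (s in config$segmentMemberships) {
    lab[, (at + 1L):(at + s$length)] <- as.integer(s$labels)
    at <- at + s$length
  }
  lab
}

#' Simulate ROI time series with planted dynamic community structure
#'
#' Within each segment, every community receives one shared narrowband
#' signal; each node's series is `withinCoupling` times its community's
#' shared signal plus independent standard Gaussian broadband noise.
#' Deterministic given the config seed.
#'
#' @param config a [plantedDynamicsConfig()].
#' @return A [SubjectTimeSeries-class] of `nNodes` x `nTimepoints`.
#' @examples
#' ts <- simulateRoiTimeSeries(plantedDynamicsConfig(seed = 7))
#' dim(as.matrix(ts))  # 7 x 812
#' @export
simulateRoiTimeSeries <- function(config) {
  stopifnot(inherits(config, "plantedDynamicsConfig"))
  withSeed(config$seed, {
    x <- matrix(0, config$nNodes, config$nTimepoints)
    at <- 0L
    for (s in config$segmentMemberships) {
      idx <- (at + 1L):(at + s$length)
      for (cl in unique(s$labels)) {
        shared <- bandLimitedNoise(s$length, config$samplingInterval,
                                   config$band)
        members <- which(s$labels == cl)
        x[members, idx] <- x[members, idx] +
          config$withinCoupling * rep(shared, each = length(members))
      }
      at <- at + s$length
    }
    x <- x + matrix(stats::rnorm(length(x)), nrow(x))
    SubjectTimeSeries(x, samplingInterval = config$samplingInterval)
  })
}

#' Planted flexibility ground truth
#'
#' Maps the planted per-timepoint labels onto the windowing used for
#' connectivity (majority label per node per window; a tie is broken to
#' the earlier segment's label, i.e. the tied label occurring first in
#' the window) and returns, for each node, the fraction of adjacent
#' window pairs whose majority label differs, out of `L - 1` possible
#' changes. This is the recovery target for the estimated flexibility.
#'
#' @param config a [plantedDynamicsConfig()].
#' @param scheme a [windowScheme()].
#' @return Named numeric vector of per-node planted flexibility in [0, 1].
#' @export
plantedFlexibility <- function(config, scheme = windowScheme()) {
  lab <- plantedLabels(config)
  usable <- config$nTimepoints - scheme$trimHead - scheme$trimTail
  if (usable < scheme$windowLen) {
    stop("windowing is not valid for this config (series too short)")
  }
  nWin <- usable %/% scheme$windowLen
  winLab <- matrix(0L, config$nNodes, nWin)
  for (w in seq_len(nWin)) {
    from <- scheme$trimHead + (w - 1L) * scheme$windowLen + 1L
    cols <- from:(from + scheme$windowLen - 1L)
    for (i in seq_len(config$nNodes)) {
      ll <- lab[i, cols]
      counts <- table(ll)
      top <- as.integer(names(counts)[counts == max(counts)])
      if (length(top) == 1L) {
        winLab[i, w] <- top
      } else {
        # tie: earlier segment's label = tied label seen first in window
        winLab[i, w] <- ll[min(match(top, ll))]
      }
    }
  }
  if (nWin < 2L) {
    f <- rep(0, config$nNodes)
  } else {
    f <- rowMeans(winLab[, -1L, drop = FALSE] !=
                  winLab[, -nWin, drop = FALSE])
  }
  names(f) <- if (config$nNodes == 7L) mtlRoiNames()
              else paste0("ROI", seq_len(config$nNodes))
  f
}

#' Window-boundary-aligned community switch schedule
#'
#' Builds segment memberships in which pairs of nodes swap between two
#' persisting communities at window boundaries, so that every node
#' accumulates `changesPerNode` community changes across the scan while
#' each community always retains a core of non-moving members (making
#' the switches recoverable by community detection). Swapping nodes are
#' chosen greedily (fewest changes so far, lowest index first), one from
#' each community per switching boundary.
#'
#' With the defaults (7 nodes, 16 windows) and `changesPerNode = 4`, the
#' planted per-node flexibility is exactly 4/15.
#'
#' @param nNodes number of nodes (default 7).
#' @param nWindows number of windows (default 16).
#' @param changesPerNode target community changes per node; must satisfy
#'   `nNodes * changesPerNode / 2 <= nWindows - 1`.
#' @param scheme a [windowScheme()]; segment lengths are derived from it.
#' @param baseMembership starting labels (default first 3 nodes vs rest
#'   for 7 nodes, halves otherwise).
#'
#' @return A `segmentMemberships` list for [plantedDynamicsConfig()].
#' @export
switchSchedule <- function(nNodes = 7L, nWindows = 16L, changesPerNode = 4L,
                           scheme = windowScheme(),
                           baseMembership = NULL) {
  if (is.null(baseMembership)) {
    half <- max(1L, nNodes %/% 2L)
    baseMembership <- rep(c(1L, 2L), c(half, nNodes - half))
  }
  nSwaps <- nNodes * changesPerNode / 2
  if (nSwaps != floor(nSwaps)) {
    stop("nNodes * changesPerNode must be even (each swap changes 2 nodes)")
  }
  if (nSwaps > nWindows - 1L) {
    stop("too many switches for the number of window boundaries")
  }
  cur <- baseMembership
  count <- rep(0L, nNodes)
  membPerWindow <- matrix(0L, nNodes, nWindows)
  membPerWindow[, 1L] <- cur
  done <- 0L
  for (w in 2:nWindows) {
    if (done < nSwaps) {
      c1 <- which(cur == 1L)
      c2 <- which(cur == 2L)
      a <- c1[order(count[c1], c1)][1L]
      b <- c2[order(count[c2], c2)][1L]
      cur[a] <- 2L
      cur[b] <- 1L
      count[a] <- count[a] + 1L
      count[b] <- count[b] + 1L
      done <- done + 1L
    }
    membPerWindow[, w] <- cur
  }
  # segments: trimHead rides with the first window, trimTail with the last
  segs <- vector("list", nWindows)
  for (w in seq_len(nWindows)) {
    len <- scheme$windowLen +
      (w == 1L) * scheme$trimHead + (w == nWindows) * scheme$trimTail
    segs[[w]] <- list(length = as.integer(len),
                      labels = membPerWindow[, w])
  }
  segs
}

## ---- synthetic cohorts ----

#' Configuration for a synthetic cohort with planted effects
#'
#' Describes a cohort table of flexibility, cognitive scores, plasma
#' biomarkers and covariates in which selected predictor-outcome pairs
#' carry planted standardized linear effects. Covariate and variable
#' scales default to the study cohort's summary statistics (n = 148,
#' 66.21 percent women, age 70.88 +/- 6.05 y, education 13.90 +/- 2.47 y).
#'
#' @param nSubjects number of subjects.
#' @param effects data.frame with columns `predictor`, `outcome`, `beta`
#'   giving planted standardized coefficients (|beta| < 1), or NULL for
#'   a null cohort.
#' @param sexProb probability of female (default 0.6621).
#' @param scales named list overriding per-variable `c(mean, sd)` on the
#'   measurement scale.
#' @param seed RNG seed.
#'
#' @return A list with class `"cohortConfig"`.
#' @seealso [simulateCohort()]
#' @export
cohortConfig <- function(nSubjects, effects = NULL, sexProb = 0.6621,
                         scales = NULL, seed = 1L) {
  defaults <- list(
    network_flexibility  = c(0.34, 0.26),
    ae_accuracy          = c(0.57, 0.24),
    ae_acquisition_score = c(0.25, 0.15),
    ravlt_delayed        = c(7.93, 3.60),
    ptau231              = c(20.39, 11.99),
    ptau181              = c(18.68, 9.49),
    abeta_ratio          = c(0.06, 0.01),
    age                  = c(70.88, 6.05),
    education            = c(13.90, 2.47)
  )
  if (!is.null(scales)) defaults[names(scales)] <- scales
  if (!is.null(effects)) {
    stopifnot(is.data.frame(effects),
              all(c("predictor", "outcome", "beta") %in% names(effects)))
    if (any(abs(effects$beta) >= 1)) {
      stop("|each planted standardized effect| must be < 1")
    }
    bad <- setdiff(c(effects$predictor, effects$outcome),
                   c(names(defaults), "sex"))
    if (length(bad)) {
      stop("unknown variable(s) in effects: ", paste(bad, collapse = ", "))
    }
    totals <- tapply(effects$beta^2, effects$outcome, sum)
    if (any(totals >= 1)) {
      stop("planted effects on an outcome imply nonpositive residual variance")
    }
  }
  nTerms <- 5L + if (is.null(effects)) 0L else max(table(effects$outcome))
  if (nSubjects < nTerms + 2L) {
    stop(sprintf("nSubjects must be at least %d for this design", nTerms + 2L))
  }
  structure(list(nSubjects = as.integer(nSubjects), effects = effects,
                 sexProb = sexProb, scales = defaults,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Simulate a cohort table with planted standardized effects
#'
#' Draws covariates (age, sex, education) and latent standard-normal
#' scores for every other variable; each outcome named in the planted
#' effects is rebuilt as the planted linear combination of its
#' standardized predictors plus Gaussian noise scaled so the outcome
#' stays standard normal. Latents are then mapped to each variable's
#' measurement scale; biomarkers and the acquisition score are truncated
#' at zero. Deterministic given the config seed.
#'
#' @param config a [cohortConfig()].
#' @return A `data.frame` (one row per subject) with columns
#'   `subject_id`, `network_flexibility`, `ae_accuracy`,
#'   `ae_acquisition_score`, `ravlt_delayed`, `ptau231`, `ptau181`,
#'   `abeta_ratio`, `age`, `sex` (1 = female, 0 = male), `education`.
#' @examples
#' eff <- data.frame(predictor = "network_flexibility",
#'                   outcome = "ae_accuracy", beta = 0.28)
#' coh <- simulateCohort(cohortConfig(200, eff, seed = 3))
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  n <- config$nSubjects
  vars <- names(config$scales)
  withSeed(config$seed, {
    z <- list()
    z$age <- stats::rnorm(n)
    z$education <- stats::rnorm(n)
    sex <- stats::rbinom(n, 1L, config$sexProb)
    z$sex <- as.numeric(scale(sex))
    if (stats::sd(sex) == 0) z$sex <- rep(0, n)
    for (v in setdiff(vars, c("age", "education"))) z[[v]] <- stats::rnorm(n)
    eff <- config$effects
    if (!is.null(eff)) {
      # resolve outcomes whose predictors are ready first (acyclic by check)
      pending <- unique(eff$outcome)
      guard <- 0L
      while (length(pending)) {
        guard <- guard + 1L
        if (guard > 100L) stop("cyclic planted effects are not supported")
        for (out in pending) {
          rows <- eff[eff$outcome == out, , drop = FALSE]
          if (any(rows$predictor %in% pending)) next
          lin <- rep(0, n)
          for (r in seq_len(nrow(rows))) {
            zp <- z[[rows$predictor[r]]]
            lin <- lin + rows$beta[r] * as.numeric(scale(zp))
          }
          resid <- sqrt(max(0, 1 - sum(rows$beta^2)))
          z[[out]] <- lin + resid * stats::rnorm(n)
          pending <- setdiff(pending, out)
        }
      }
    }
    tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)))
    truncated <- c("ptau231", "ptau181", "abeta_ratio",
                   "ae_acquisition_score")
    for (v in vars) {
      sc <- config$scales[[v]]
      x <- sc[1] + sc[2] * z[[v]]
      if (v %in% truncated) x <- pmax(x, 0)
      tab[[v]] <- x
    }
    tab$sex <- sex
    tab
  })
}
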