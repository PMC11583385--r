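#' Build a time-linked multilayer network from a coherence tensor
#'
#' Takes the windowed coherence layers, zeroes their diagonals (so
#' self-coherence does not enter node strengths), and records the
#' resolution `gamma`, the identity inter-layer coupling `omega` that
#' links each node to its own copies in the adjacent layers only, the
#' per-layer strengths `k_il`, per-layer totals `2 m_l`, and the
#' multilayer normalisation `2 mu = sum_l 2 m_l + 2 omega N (L - 1)`.
#'
#' The default `omega = 0.3` was calibrated on synthetic networks with
#' planted switches (see the package vignette): on dense 7-node
#' coherence layers the conventional `omega = 1` freezes the partition
#' across layers and yields zero flexibility even when communities
#' genuinely reorganise.
#'
#' @param tensor a [CoherenceTensor-class] or a plain N x N x L array of
#'   nonnegative symmetric layers.
#' @param gamma resolution parameter (> 0, default 1).
#' @param omega inter-layer coupling (>= 0, default 0.3).
#'
#' @return A [MultilayerNetwork-class].
#' @export
buildMultilayerNetwork <- function(tensor, gamma = 1, omega = 0.3) {
  stopUnlessScalar(gamma, "gamma", lower = 1e-12)
  stopUnlessScalar(omega, "omega", lower = 0)
  vals <- if (is(tensor, "CoherenceTensor")) tensor@values else {
    stopifnot(is.array(tensor), length(dim(tensor)) == 3L)
    tensor
  }
  if (any(vals < 0)) stop("negative coherence entries are not allowed")
  n <- dim(vals)[1]
  nWin <- dim(vals)[3]
  layers <- vals
  strengths <- matrix(0, n, nWin)
  twom <- numeric(nWin)
  for (l in seq_len(nWin)) {
    a <- layers[, , l]
    diag(a) <- 0
    layers[, , l] <- a
    strengths[, l] <- rowSums(a)
    twom[l] <- sum(a)
  }
  rn <- if (is(tensor, "CoherenceTensor")) tensor@roiNames
        else paste0("ROI", seq_len(n))
  new("MultilayerNetwork", layers = layers, gamma = gamma, omega = omega,
      strengths = strengths, twom = twom,
      twomu = sum(twom) + 2 * omega * n * max(nWin - 1L, 0L),
      roiNames = rn)
}

#' Multilayer modularity of a partition
#'
#' The quality function
#' \deqn{Q = \frac{1}{2\mu} \sum_{ijlr} \left[ \left(A_{ijl} -
#'   \gamma \frac{k_{il} k_{jl}}{2 m_l}\right) \delta_{lr} +
#'   \delta_{ij}\, \omega\, 1\{|l - r| = 1\} \right]
#'   \delta(g_{il}, g_{jr})}
#' combining per-layer Newman-Girvan terms at resolution gamma with
#' identity coupling omega between a node's copies in adjacent layers.
#' A layer with zero total weight contributes no null term.
#'
#' @param partition a [LayerPartition-class] (or a label matrix).
#' @param net a [MultilayerNetwork-class].
#'
#' @return The scalar modularity Q.
#' @export
multilayerModularity <- function(partition, net) {
  stopifnot(is(net, "MultilayerNetwork"))
  lab <- if (is(partition, "LayerPartition")) partition@labels
         else as.matrix(partition)
  n <- dim(net@layers)[1]
  nWin <- dim(net@layers)[3]
  if (nrow(lab) != n || ncol(lab) != nWin) {
    stop(sprintf("partition is %d x %d but the network is %d nodes x %d layers",
                 nrow(lab), ncol(lab), n, nWin))
  }
  total <- 0
  for (l in seq_len(nWin)) {
    same <- outer(lab[, l], lab[, l], "==")
    a <- net@layers[, , l]
    k <- net@strengths[, l]
    p <- if (net@twom[l] > 0) net@gamma * outer(k, k) / net@twom[l] else 0 * a
    total <- total + sum((a - p)[same])
  }
  if (nWin > 1L) {
    agree <- lab[, -1L, drop = FALSE] == lab[, -nWin, drop = FALSE]
    total <- total + 2 * net@omega * sum(agree)
  }
  total / net@twomu
}

# Supra-modularity matrix: dense U x U matrix over node-layer units with
# per-layer Newman-Girvan blocks on the diagonal and omega on the
# identity couplings between adjacent layers.
supraModularityMatrix <- function(net) {
  n <- dim(net@layers)[1]
  nWin <- dim(net@layers)[3]
  u <- n * nWin
  b <- matrix(0, u, u)
  for (l in seq_len(nWin)) {
    a <- net@layers[, , l]
    k <- net@strengths[, l]
    p <- if (net@twom[l] > 0) net@gamma * outer(k, k) / net@twom[l] else 0 * a
    idx <- ((l - 1L) * n + 1L):(l * n)
    b[idx, idx] <- a - p
    if (l < nWin) {
      for (i in seq_len(n)) {
        b[(l - 1L) * n + i, l * n + i] <- net@omega
        b[l * n + i, (l - 1L) * n + i] <- net@omega
      }
    }
  }
  b
}

# One Louvain level on a (possibly aggregated) modularity matrix:
# greedy node moving in seeded random sweep order until no move has
# positive gain. Among equal-gain alternatives the unit keeps its
# current community. Returns the label vector (1..k, first-appearance
# order).
greedySweep <- function(m) {
  nUnits <- nrow(m)
  lab <- seq_len(nUnits)
  repeat {
    moved <- FALSE
    for (u in sample.int(nUnits)) {
      gains <- rowsum(m[u, ], lab, reorder = FALSE)
      comms <- as.integer(rownames(gains))
      gains <- gains[, 1L]
      cur <- lab[u]
      iCur <- match(cur, comms)
      gains[iCur] <- gains[iCur] - m[u, u]
      iBest <- which.max(gains)
      if (gains[iBest] > gains[iCur] + 1e-12) {
        lab[u] <- comms[iBest]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  match(lab, unique(lab))
}

#' Louvain-like greedy multilayer modularity optimization
#'
#' Partitions a multilayer network into temporally connected modules by
#' locally greedy optimization of [multilayerModularity()]: phase 1
#' sweeps node-layer units in a seeded random order, moving each unit to
#' the community with the largest positive modularity gain until no move
#' improves; phase 2 aggregates communities into super-nodes (summing
#' intra- and inter-layer modularity terms) and repeats. Q is
#' nondecreasing across accepted moves and aggregation passes, and the
#' returned partition never scores below the all-singletons partition.
#' Stochastic in sweep order; reproducible given `seed`.
#'
#' @param net a [MultilayerNetwork-class].
#' @param seed RNG seed for the sweep order.
#'
#' @return A [LayerPartition-class]; its `Q` slot holds the achieved
#'   multilayer modularity.
#' @export
louvainMultilayer <- function(net, seed = 1L) {
  stopifnot(is(net, "MultilayerNetwork"))
  n <- dim(net@layers)[1]
  nWin <- dim(net@layers)[3]
  b <- supraModularityMatrix(net)
  withSeed(seed, {
    global <- seq_len(n * nWin)
    m <- b
    repeat {
      lab <- greedySweep(m)
      global <- lab[global]
      if (max(lab) == nrow(m)) break
      m <- rowsum(t(rowsum(m, lab, reorder = TRUE)), lab, reorder = TRUE)
    }
    labels <- matrix(global, n, nWin)
    rownames(labels) <- net@roiNames
    q <- sum(b[outer(global, global, "==")]) / net@twomu
    new("LayerPartition", labels = labels, Q = q)
  })
}

#' Node and network flexibility of a layer partition
#'
#' For each node, flexibility is the number of adjacent-layer community
#' changes divided by the `L - 1` changes that may occur; the network
#' flexibility is the arithmetic mean over nodes.
#'
#' @param partition a [LayerPartition-class] with at least 2 layers.
#'
#' @return A [FlexibilityResult-class] with `nRuns = 1`.
#' @examples
#' p <- LayerPartition(matrix(c(1, 1, 1, 2, 2, 2), nrow = 3))
#' networkFlexibility(flexibility(p))  # 1: every node changes once
#' @export
flexibility <- function(partition) {
  stopifnot(is(partition, "LayerPartition"))
  lab <- partition@labels
  nWin <- ncol(lab)
  if (nWin < 2L) {
    stop("flexibility is undefined for a single-layer partition")
  }
  f <- rowMeans(lab[, -1L, drop = FALSE] != lab[, -nWin, drop = FALSE])
  names(f) <- rownames(lab)
  new("FlexibilityResult", nodeFlexibility = f,
      networkFlexibility = mean(f), nodeSD = numeric(0),
      networkSD = NA_real_, nRuns = 1L)
}

#' Flexibility from a coherence tensor, averaged over optimizer restarts
#'
#' Runs [louvainMultilayer()] `nRuns` times with child seeds derived
#' deterministically from `seed`, computes node flexibility for each
#' run, and reports the mean node and network flexibility across runs
#' together with their dispersion. Averaging over restarts smooths the
#' optimizer's degenerate-optimum sensitivity.
#'
#' @param tensor a [CoherenceTensor-class] or plain N x N x L array.
#' @param gamma resolution (default 1).
#' @param omega inter-layer coupling (default 0.3; see
#'   [buildMultilayerNetwork()]).
#' @param nRuns optimizer restarts (default 100).
#' @param seed master seed.
#'
#' @return A [FlexibilityResult-class].
#' @export
flexibilityPipeline <- function(tensor, gamma = 1, omega = 0.3,
                                nRuns = 100L, seed = 1L) {
  stopUnlessScalar(nRuns, "nRuns", 1)
  net <- buildMultilayerNetwork(tensor, gamma = gamma, omega = omega)
  seeds <- childSeeds(seed, nRuns)
  perRun <- vapply(seeds, function(s) {
    nodeFlexibility(flexibility(louvainMultilayer(net, seed = s)))
  }, numeric(dim(net@layers)[1]))
  perRun <- matrix(perRun, ncol = nRuns)
  f <- rowMeans(perRun)
  names(f) <- net@roiNames
  netPerRun <- colMeans(perRun)
  new("FlexibilityResult", nodeFlexibility = f,
      networkFlexibility = mean(f),
      nodeSD = apply(perRun, 1L, stats::sd),
      networkSD = stats::sd(netPerRun), nRuns = as.integer(nRuns))
}
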