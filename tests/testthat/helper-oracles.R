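# Independent oracles, written deliberately differently from the
# package implementations they check.

# Direct quadruple-sum multilayer modularity:
# Q = (1/2mu) sum_{ijlr} [(A_ijl - gamma k_il k_jl / 2m_l) delta_lr
#                         + delta_ij omega 1{|l-r|=1}] delta(g_il, g_jr)
directModularity <- function(labels, layers, gamma, omega) {
  n <- dim(layers)[1]; L <- dim(layers)[3]
  k <- sapply(seq_len(L), function(l) rowSums(layers[, , l]))
  twom <- colSums(k)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (l in seq_len(L)) for (r in seq_len(L)) {
      if (labels[i, l] != labels[j, r]) next
      if (l == r) {
        null <- if (twom[l] > 0) gamma * k[i, l] * k[j, l] / twom[l] else 0
        total <- total + layers[i, j, l] - null
      }
      if (i == j && abs(l - r) == 1) total <- total + omega
    }
  }
  twomu <- sum(twom) + 2 * omega * n * (L - 1)
  total / twomu
}

# All set partitions of n items as label vectors (restricted growth
# strings).
allPartitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxLab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxLab + 1L)) {
      recurse(c(prefix, lab), max(maxLab, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive maximum of multilayer modularity over all partitions of
# the N*L node-layer units (small instances only).
bruteForceMaxQ <- function(layers, gamma, omega) {
  n <- dim(layers)[1]; L <- dim(layers)[3]
  parts <- allPartitions(n * L)
  best <- -Inf
  for (p in parts) {
    q <- directModularity(matrix(p, n, L), layers, gamma, omega)
    if (q > best) best <- q
  }
  best
}

# Random symmetric nonnegative test layers with zero diagonal.
randomLayers <- function(n, L, seed) {
  set.seed(seed)
  a <- array(0, c(n, n, L))
  for (l in seq_len(L)) {
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    a[, , l] <- m
  }
  a
}

# Naive Welch magnitude-squared coherence: explicit DFT sums, no fft().
# Mirrors the package's documented estimator settings (Hann taper,
# 50% overlap, per-segment linear detrend) via a different code path.
naiveBandCoherence <- function(x, y, dt, band = c(0.06, 0.12), seg = 25) {
  hop <- round(seg / 2)
  starts <- seq(1, length(x) - seg + 1, by = hop)
  taper <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / (seg - 1)))
  detrend <- function(z) {
    tt <- seq_along(z)
    unname(residuals(lm(z ~ tt)))
  }
  dft <- function(z, k) {
    idx <- 0:(seg - 1)
    sum(z * exp(-2i * pi * k * idx / seg))
  }
  freqs <- (0:floor(seg / 2)) / (seg * dt)
  bins <- which(freqs >= band[1] & freqs <= band[2]) - 1L
  vals <- sapply(bins, function(k) {
    sxx <- syy <- 0
    sxy <- 0 + 0i
    for (s in starts) {
      zx <- detrend(x[s:(s + seg - 1)]) * taper
      zy <- detrend(y[s:(s + seg - 1)]) * taper
      fx <- dft(zx, k); fy <- dft(zy, k)
      sxx <- sxx + Mod(fx)^2
      syy <- syy + Mod(fy)^2
      sxy <- sxy + fx * Conj(fy)
    }
    Mod(sxy)^2 / (sxx * syy)
  })
  mean(vals)
}

# Closed-form least squares via the normal equations, for checking the
# standardized regression fits.
normalEquationsFit <- function(y, X) {
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y); k <- ncol(X) - 1L
  df2 <- n - k - 1L
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  se <- sqrt(rss / df2 * diag(solve(xtx)))
  list(beta = drop(beta), se = se, t = drop(beta) / se, r2 = r2,
       f = (r2 / k) / ((1 - r2) / df2), df1 = k, df2 = df2)
}
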