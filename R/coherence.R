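#' Windowing scheme for dynamic connectivity
#'
#' Describes how a subject's time series is cut into consecutive
#' non-overlapping windows: the number of time points discarded at the
#' head and tail of the scan and the window length. With the defaults
#' (trim 6 + 6, windows of 50 points) an 812-point series yields 16
#' windows of 33 s each at a 0.664 s sampling interval.
#'
#' @param trimHead time points dropped at the start (default 6).
#' @param trimTail time points dropped at the end (default 6).
#' @param windowLen window length in time points (default 50, minimum 8).
#'
#' @return A list with class `"windowScheme"`.
#' @export
windowScheme <- function(trimHead = 6L, trimTail = 6L, windowLen = 50L) {
  stopUnlessScalar(trimHead, "trimHead", 0)
  stopUnlessScalar(trimTail, "trimTail", 0)
  stopUnlessScalar(windowLen, "windowLen", 8)
  structure(list(trimHead = as.integer(trimHead),
                 trimTail = as.integer(trimTail),
                 windowLen = as.integer(windowLen)),
            class = "windowScheme")
}

#' Cut a time series into consecutive non-overlapping windows
#'
#' Drops `trimHead` points at the start and `trimTail` at the end, then
#' returns every full `windowLen`-point window in order. A remainder
#' shorter than one window is dropped with a warning.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param scheme a [windowScheme()].
#'
#' @return A list of ROI x `windowLen` matrices, one per window.
#' @examples
#' ts <- SubjectTimeSeries(matrix(rnorm(7 * 812), nrow = 7))
#' length(windowTimeSeries(ts))  # 16
#' @export
windowTimeSeries <- function(ts, scheme = windowScheme()) {
  stopifnot(is(ts, "SubjectTimeSeries"))
  x <- ts@values
  tTotal <- ncol(x)
  usable <- tTotal - scheme$trimHead - scheme$trimTail
  if (usable < scheme$windowLen) {
    stop(sprintf(
      paste0("time series too short: %d points after trimming, but at ",
             "least %d are required (T >= %d)"),
      max(usable, 0L), scheme$windowLen,
      scheme$windowLen + scheme$trimHead + scheme$trimTail), call. = FALSE)
  }
  nWin <- usable %/% scheme$windowLen
  rem <- usable %% scheme$windowLen
  if (rem > 0L) {
    warning(sprintf("dropping %d trailing time points (not a full window)",
                    rem), call. = FALSE)
  }
  lapply(seq_len(nWin), function(w) {
    from <- scheme$trimHead + (w - 1L) * scheme$windowLen + 1L
    x[, from:(from + scheme$windowLen - 1L), drop = FALSE]
  })
}

#' Welch cross-spectral estimator settings
#'
#' Settings of the Welch estimator behind [bandCoherence()]: Hann-tapered
#' segments with 50 percent overlap and per-segment linear detrending.
#' With 25-point segments inside a 50-point window three segments are
#' averaged, which keeps the coherence estimate away from its degenerate
#' single-segment value of 1.
#'
#' @param segmentLength Welch segment length in samples (default 25).
#' @param overlap fractional segment overlap in [0, 1) (default 0.5).
#' @param detrend linearly detrend each segment before tapering
#'   (default TRUE).
#'
#' @return A list with class `"welchSettings"`.
#' @export
welchSettings <- function(segmentLength = 25L, overlap = 0.5,
                          detrend = TRUE) {
  stopUnlessScalar(segmentLength, "segmentLength", 4)
  stopUnlessScalar(overlap, "overlap", 0, 0.99)
  structure(list(segmentLength = as.integer(segmentLength),
                 overlap = overlap, detrend = isTRUE(detrend)),
            class = "welchSettings")
}

# Hann taper of length n.
hannTaper <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

# Welch-averaged auto/cross spectra of two equal-length series.
# Returns one-sided bin frequencies and the magnitude-squared coherence
# per bin.
welchCoherenceSpectrum <- function(x, y, samplingInterval, settings) {
  n <- length(x)
  seg <- settings$segmentLength
  if (seg > n) seg <- n
  hop <- max(1L, as.integer(round(seg * (1 - settings$overlap))))
  starts <- seq.int(1L, n - seg + 1L, by = hop)
  w <- hannTaper(seg)
  tt <- seq_len(seg)
  design <- cbind(1, tt)
  sxx <- syy <- numeric(seg)
  sxy <- complex(real = numeric(seg), imaginary = numeric(seg))
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)]
    ys <- y[s:(s + seg - 1L)]
    if (settings$detrend) {
      xs <- stats::lm.fit(design, xs)$residuals
      ys <- stats::lm.fit(design, ys)$residuals
    }
    xf <- stats::fft(xs * w)
    yf <- stats::fft(ys * w)
    sxx <- sxx + Mod(xf)^2
    syy <- syy + Mod(yf)^2
    sxy <- sxy + xf * Conj(yf)
  }
  freq <- (0:(seg - 1)) / (seg * samplingInterval)
  oneSided <- 0:(seg - 1) <= seg / 2
  coh <- rep(NA_real_, seg)
  ok <- sxx > 0 & syy > 0
  coh[ok] <- Mod(sxy[ok])^2 / (sxx[ok] * syy[ok])
  list(freq = freq[oneSided], coherence = coh[oneSided])
}

#' Band-averaged magnitude-squared coherence of two series
#'
#' Welch-estimated magnitude-squared coherence |Sxy|^2 / (Sxx Syy),
#' averaged over the one-sided frequency bins whose center frequency f
#' lies in the closed band. The result lies in [0, 1]; identical or
#' affinely related series give exactly 1.
#'
#' Note that with few Welch segments the estimator carries a substantial
#' positive small-sample bias on independent inputs; comparisons should
#' always be within-estimator (e.g. within- vs between-community), never
#' against zero.
#'
#' @param x,y numeric series of equal length with no missing values.
#' @param samplingInterval sampling interval in seconds.
#' @param band closed frequency band in Hz (default `c(0.06, 0.12)`).
#' @param settings a [welchSettings()].
#'
#' @return Band-averaged coherence in [0, 1].
#' @examples
#' x <- rnorm(50)
#' bandCoherence(x, 3 * x + 7, 0.664)  # 1
#' @export
bandCoherence <- function(x, y, samplingInterval, band = c(0.06, 0.12),
                          settings = welchSettings()) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("input series must be finite with no missing values")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("coherence is undefined for a zero-variance series")
  }
  nyquist <- 1 / (2 * samplingInterval)
  if (band[1] < 0 || band[2] > nyquist + 1e-12) {
    stop(sprintf("band [%g, %g] Hz must lie within [0, %g] (Nyquist)",
                 band[1], band[2], nyquist))
  }
  sp <- welchCoherenceSpectrum(x, y, samplingInterval, settings)
  inBand <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(inBand)) {
    stop(sprintf(
      "no spectral bin center falls inside [%g, %g] Hz (resolution %g Hz)",
      band[1], band[2], sp$freq[2]))
  }
  val <- mean(sp$coherence[inBand])
  min(max(val, 0), 1)
}

#' Windowed coherence tensor of a subject
#'
#' Cuts the ROI time series into windows, demeans each window, and
#' computes the band-averaged magnitude-squared coherence for every
#' unordered ROI pair in every window. The result is an N x N x L
#' symmetric tensor with unit diagonal — the layers of the multilayer
#' network.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param scheme a [windowScheme()].
#' @param band closed frequency band in Hz.
#' @param settings a [welchSettings()].
#'
#' @return A [CoherenceTensor-class].
#' @examples
#' cfg <- plantedDynamicsConfig(seed = 1)
#' ts <- simulateRoiTimeSeries(cfg)
#' tensor <- connectivityTensor(ts)
#' dim(as.array(tensor))  # 7 7 16
#' @export
connectivityTensor <- function(ts, scheme = windowScheme(),
                               band = c(0.06, 0.12),
                               settings = welchSettings()) {
  wins <- windowTimeSeries(ts, scheme)
  n <- nNodes(ts)
  nWin <- length(wins)
  vals <- array(1, dim = c(n, n, nWin),
                dimnames = list(ts@roiNames, ts@roiNames, NULL))
  for (l in seq_len(nWin)) {
    xw <- wins[[l]] - rowMeans(wins[[l]])
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        c_ij <- tryCatch(
          bandCoherence(xw[i, ], xw[j, ], ts@samplingInterval, band,
                        settings),
          error = function(e) {
            stop(sprintf("window %d, pair (%s, %s): %s", l,
                         ts@roiNames[i], ts@roiNames[j],
                         conditionMessage(e)), call. = FALSE)
          })
        vals[i, j, l] <- vals[j, i, l] <- c_ij
      }
    }
  }
  new("CoherenceTensor", values = vals, band = as.numeric(band),
      roiNames = ts@roiNames, samplingInterval = ts@samplingInterval,
      windowScheme = unclass(scheme))
}
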