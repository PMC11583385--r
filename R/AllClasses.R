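#' @import methods
NULL

#' SubjectTimeSeries: ROI-averaged time series for one subject
#'
#' Container for a single subject's ROI-by-time matrix of ROI-averaged
#' signal values together with the ROI labels and the sampling interval
#' (the repetition time for fMRI data). This is the raw input to the
#' dynamic connectivity pipeline.
#'
#' @slot values numeric matrix, ROIs in rows, time points in columns.
#' @slot roiNames character vector of ROI labels, one per row.
#' @slot samplingInterval sampling interval in seconds (> 0).
#'
#' @seealso [SubjectTimeSeries()] for the constructor,
#'   [connectivityTensor()] for the next pipeline stage.
#' @exportClass SubjectTimeSeries
setClass("SubjectTimeSeries",
  representation(
    values = "matrix",
    roiNames = "character",
    samplingInterval = "numeric"
  )
)

setValidity("SubjectTimeSeries", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "'values' must be a numeric matrix")
  if (anyNA(v) || any(!is.finite(v))) {
    msgs <- c(msgs, "'values' must not contain missing or non-finite entries")
  }
  if (nrow(v) < 2L) msgs <- c(msgs, "at least 2 ROIs are required")
  if (length(object@roiNames) != nrow(v)) {
    msgs <- c(msgs, "'roiNames' must have one entry per ROI (row)")
  }
  if (anyDuplicated(object@roiNames)) {
    msgs <- c(msgs, "'roiNames' must be unique")
  }
  si <- object@samplingInterval
  if (length(si) != 1L || !is.finite(si) || si <= 0) {
    msgs <- c(msgs, "'samplingInterval' must be a single positive number")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SubjectTimeSeries
#'
#' @param values numeric matrix with ROIs in rows and time points in
#'   columns.
#' @param roiNames character vector of ROI labels. Defaults to the
#'   rownames of `values`, or the seven MTL ROI names when the matrix has
#'   seven unnamed rows, or `ROI1, ROI2, ...` otherwise.
#' @param samplingInterval sampling interval in seconds (default 0.664,
#'   the study's fMRI repetition time).
#'
#' @return A [SubjectTimeSeries-class] object.
#' @examples
#' ts <- SubjectTimeSeries(matrix(rnorm(7 * 100), nrow = 7))
#' nNodes(ts)
#' @export
SubjectTimeSeries <- function(values, roiNames = NULL,
                              samplingInterval = 0.664) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(roiNames)) {
    roiNames <- rownames(values)
    if (is.null(roiNames)) {
      roiNames <- if (nrow(values) == 7L) mtlRoiNames()
      else paste0("ROI", seq_len(nrow(values)))
    }
  }
  rownames(values) <- roiNames
  new("SubjectTimeSeries", values = values, roiNames = roiNames,
      samplingInterval = samplingInterval)
}

#' The seven MTL regions of interest
#'
#' Default ROI labels of the medial temporal lobe network: perirhinal
#' cortex, parahippocampal cortex, posteromedial and anterolateral
#' entorhinal cortex, and the hippocampal subfields subiculum, CA1 and
#' DG/CA3.
#'
#' @return Character vector of length 7.
#' @export
mtlRoiNames <- function() {
  c("PRC", "PHC", "pMEC", "aLEC", "subiculum", "CA1", "DG/CA3")
}

#' CoherenceTensor: windowed band-averaged coherence networks
#'
#' An N x N x L stack of band-averaged magnitude-squared coherence
#' matrices, one symmetric layer per time window, with values in [0, 1]
#' and unit diagonal. These are the layers of the multilayer network.
#'
#' @slot values numeric array, ROI x ROI x window.
#' @slot band numeric length-2 frequency band in Hz.
#' @slot roiNames character ROI labels.
#' @slot samplingInterval sampling interval of the source series (s).
#' @slot windowScheme the [windowScheme()] used to cut the series.
#'
#' @seealso [connectivityTensor()], [buildMultilayerNetwork()]
#' @exportClass CoherenceTensor
setClass("CoherenceTensor",
  representation(
    values = "array",
    band = "numeric",
    roiNames = "character",
    samplingInterval = "numeric",
    windowScheme = "list"
  )
)

setValidity("CoherenceTensor", function(object) {
  v <- object@values
  msgs <- character()
  if (length(dim(v)) != 3L || dim(v)[1] != dim(v)[2]) {
    msgs <- c(msgs, "'values' must be an N x N x L array")
  } else {
    if (anyNA(v) || any(v < -1e-12) || any(v > 1 + 1e-12)) {
      msgs <- c(msgs, "coherence values must lie in [0, 1]")
    }
    for (l in seq_len(dim(v)[3])) {
      if (max(abs(v[, , l] - t(v[, , l]))) > 1e-12) {
        msgs <- c(msgs, sprintf("layer %d is not symmetric", l))
        break
      }
    }
  }
  if (length(object@band) != 2L || object@band[1] > object@band[2]) {
    msgs <- c(msgs, "'band' must be an increasing length-2 Hz interval")
  }
  if (length(object@roiNames) != dim(v)[1]) {
    msgs <- c(msgs, "'roiNames' must match the tensor dimension")
  }
  if (length(msgs)) msgs else TRUE
})

#' MultilayerNetwork: time-linked coherence layers
#'
#' The multilayer network assembled from a [CoherenceTensor-class]:
#' the coherence layers with zeroed diagonals, identity inter-layer
#' coupling `omega` between each node and its copies in the adjacent
#' layers, resolution `gamma`, and the derived strength bookkeeping used
#' by multilayer modularity.
#'
#' @slot layers numeric N x N x L array with zero diagonals.
#' @slot gamma resolution parameter (> 0).
#' @slot omega inter-layer coupling (>= 0).
#' @slot strengths N x L matrix of per-layer node strengths.
#' @slot twom per-layer total edge weight (2 m_l).
#' @slot twomu multilayer normalisation 2 mu = sum_l 2 m_l + 2 omega N (L - 1).
#' @slot roiNames character ROI labels.
#'
#' @exportClass MultilayerNetwork
setClass("MultilayerNetwork",
  representation(
    layers = "array",
    gamma = "numeric",
    omega = "numeric",
    strengths = "matrix",
    twom = "numeric",
    twomu = "numeric",
    roiNames = "character"
  )
)

setValidity("MultilayerNetwork", function(object) {
  msgs <- character()
  d <- dim(object@layers)
  if (length(d) != 3L || d[1] != d[2]) {
    msgs <- c(msgs, "'layers' must be an N x N x L array")
  } else {
    for (l in seq_len(d[3])) {
      if (any(diag(object@layers[, , l]) != 0)) {
        msgs <- c(msgs, "layer diagonals must be zero")
        break
      }
    }
    if (any(object@layers < 0)) {
      msgs <- c(msgs, "layer weights must be nonnegative")
    }
  }
  if (object@gamma <= 0 || !is.finite(object@gamma)) {
    msgs <- c(msgs, "'gamma' must be positive and finite")
  }
  if (object@omega < 0 || !is.finite(object@omega)) {
    msgs <- c(msgs, "'omega' must be nonnegative and finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' LayerPartition: community labels per node and layer
#'
#' A community assignment for each (node, layer) pair — the module
#' allegiance of every node in every time window. Labels are opaque:
#' only equality matters. Produced by [louvainMultilayer()]; the input
#' to [flexibility()].
#'
#' @slot labels integer matrix, nodes in rows, layers in columns.
#' @slot Q achieved multilayer modularity (NA when not applicable).
#'
#' @exportClass LayerPartition
setClass("LayerPartition",
  representation(labels = "matrix", Q = "numeric")
)

setValidity("LayerPartition", function(object) {
  msgs <- character()
  if (anyNA(object@labels)) msgs <- c(msgs, "every (node, layer) must be labeled")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LayerPartition from a label matrix
#'
#' @param labels matrix of community labels, nodes in rows, layers in
#'   columns. Any atomic label type is accepted; labels are compared by
#'   equality only.
#' @param Q optional achieved multilayer modularity.
#' @return A [LayerPartition-class] object.
#' @export
LayerPartition <- function(labels, Q = NA_real_) {
  labels <- as.matrix(labels)
  lab <- matrix(match(labels, unique(as.vector(labels))),
                nrow(labels), ncol(labels), dimnames = dimnames(labels))
  new("LayerPartition", labels = lab, Q = as.numeric(Q))
}

#' FlexibilityResult: node and network flexibility
#'
#' Per-node flexibility (fraction of adjacent-window transitions at
#' which the node changes community) and the network flexibility (mean
#' over nodes), optionally aggregated over optimizer restarts.
#'
#' @slot nodeFlexibility named numeric vector of per-node values in [0, 1].
#' @slot networkFlexibility mean of the node values.
#' @slot nodeSD per-node standard deviation across optimizer runs
#'   (zero-length for a single run).
#' @slot networkSD standard deviation of the network value across runs.
#' @slot nRuns number of optimizer restarts aggregated.
#'
#' @exportClass FlexibilityResult
setClass("FlexibilityResult",
  representation(
    nodeFlexibility = "numeric",
    networkFlexibility = "numeric",
    nodeSD = "numeric",
    networkSD = "numeric",
    nRuns = "integer"
  )
)

setValidity("FlexibilityResult", function(object) {
  f <- object@nodeFlexibility
  msgs <- character()
  if (any(f < 0 | f > 1)) msgs <- c(msgs, "node flexibility must lie in [0, 1]")
  if (abs(object@networkFlexibility - mean(f)) > 1e-12) {
    msgs <- c(msgs, "network flexibility must equal the mean node flexibility")
  }
  if (length(msgs)) msgs else TRUE
})

## ---- generics ----

#' Number of nodes (ROIs)
#' @param x a pipeline object.
#' @return integer count of nodes.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of layers (time windows)
#' @param x a pipeline object.
#' @return integer count of layers.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' ROI labels
#' @param x a pipeline object.
#' @return character vector of ROI names.
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' Sampling interval in seconds
#' @param x a pipeline object.
#' @return numeric sampling interval.
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' Community label matrix of a partition
#' @param x a [LayerPartition-class].
#' @return integer matrix, nodes in rows, layers in columns.
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))

#' Per-node flexibility values
#' @param x a [FlexibilityResult-class].
#' @return named numeric vector.
#' @export
setGeneric("nodeFlexibility", function(x) standardGeneric("nodeFlexibility"))

#' Network (mean) flexibility
#' @param x a [FlexibilityResult-class].
#' @return numeric scalar.
#' @export
setGeneric("networkFlexibility",
           function(x) standardGeneric("networkFlexibility"))

#' @describeIn nNodes nodes of a subject time series
#' @export
setMethod("nNodes", "SubjectTimeSeries", function(x) nrow(x@values))
#' @describeIn nNodes nodes of a coherence tensor
#' @export
setMethod("nNodes", "CoherenceTensor", function(x) dim(x@values)[1])
#' @describeIn nNodes nodes of a multilayer network
#' @export
setMethod("nNodes", "MultilayerNetwork", function(x) dim(x@layers)[1])
#' @describeIn nNodes nodes of a partition
#' @export
setMethod("nNodes", "LayerPartition", function(x) nrow(x@labels))

#' @describeIn nLayers layers of a coherence tensor
#' @export
setMethod("nLayers", "CoherenceTensor", function(x) dim(x@values)[3])
#' @describeIn nLayers layers of a multilayer network
#' @export
setMethod("nLayers", "MultilayerNetwork", function(x) dim(x@layers)[3])
#' @describeIn nLayers layers of a partition
#' @export
setMethod("nLayers", "LayerPartition", function(x) ncol(x@labels))

#' @describeIn roiNames ROI labels of a time series
#' @export
setMethod("roiNames", "SubjectTimeSeries", function(x) x@roiNames)
#' @describeIn roiNames ROI labels of a coherence tensor
#' @export
setMethod("roiNames", "CoherenceTensor", function(x) x@roiNames)
#' @describeIn roiNames ROI labels of a multilayer network
#' @export
setMethod("roiNames", "MultilayerNetwork", function(x) x@roiNames)

#' @describeIn samplingInterval of a time series
#' @export
setMethod("samplingInterval", "SubjectTimeSeries",
          function(x) x@samplingInterval)
#' @describeIn samplingInterval of a coherence tensor
#' @export
setMethod("samplingInterval", "CoherenceTensor",
          function(x) x@samplingInterval)

#' @describeIn partitionLabels label matrix accessor
#' @export
setMethod("partitionLabels", "LayerPartition", function(x) x@labels)

#' @describeIn nodeFlexibility accessor
#' @export
setMethod("nodeFlexibility", "FlexibilityResult",
          function(x) x@nodeFlexibility)
#' @describeIn networkFlexibility accessor
#' @export
setMethod("networkFlexibility", "FlexibilityResult",
          function(x) x@networkFlexibility)

#' @describeIn SubjectTimeSeries-class coerce to the ROI x time matrix
#' @param x a SubjectTimeSeries.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "SubjectTimeSeries", function(x, ...) x@values)

#' Coerce a CoherenceTensor to a plain array
#' @param x a [CoherenceTensor-class].
#' @param ... ignored
#' @return the N x N x L numeric array.
#' @export
setMethod("as.array", "CoherenceTensor", function(x, ...) x@values)

setMethod("show", "SubjectTimeSeries", function(object) {
  cat(sprintf("SubjectTimeSeries: %d ROIs x %d time points (TR = %g s)\n",
              nrow(object@values), ncol(object@values),
              object@samplingInterval))
  cat("ROIs:", paste(object@roiNames, collapse = ", "), "\n")
})

setMethod("show", "CoherenceTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("CoherenceTensor: %d x %d x %d (band %g-%g Hz)\n",
              d[1], d[2], d[3], object@band[1], object@band[2]))
})

setMethod("show", "MultilayerNetwork", function(object) {
  d <- dim(object@layers)
  cat(sprintf(
    "MultilayerNetwork: %d nodes x %d layers (gamma = %g, omega = %g)\n",
    d[1], d[3], object@gamma, object@omega))
  cat(sprintf("  2mu = %.4f\n", object@twomu))
})

setMethod("show", "LayerPartition", function(object) {
  cat(sprintf("LayerPartition: %d nodes x %d layers, %d communities",
              nrow(object@labels), ncol(object@labels),
              length(unique(as.vector(object@labels)))))
  if (!is.na(object@Q)) cat(sprintf(" (Q = %.6f)", object@Q))
  cat("\n")
})

setMethod("show", "FlexibilityResult", function(object) {
  cat(sprintf("FlexibilityResult (%d run%s)\n", object@nRuns,
              if (object@nRuns > 1L) "s" else ""))
  cat(sprintf("  network flexibility: %.4f\n", object@networkFlexibility))
  f <- object@nodeFlexibility
  cat("  node flexibility:\n")
  for (i in seq_along(f)) {
    cat(sprintf("    %-10s %.4f\n",
                if (!is.null(names(f))) names(f)[i] else i, f[i]))
  }
})
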