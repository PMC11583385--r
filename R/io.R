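#' Write a subject time series as TSV
#'
#' Writes the series as time points x ROIs with a header row of ROI
#' names — the plain-text interchange format read back by
#' [readTimeSeries()].
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTimeSeries <- function(ts, path) {
  stopifnot(is(ts, "SubjectTimeSeries"))
  m <- t(ts@values)
  colnames(m) <- ts@roiNames
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a subject time series from TSV/CSV
#'
#' Reads a time points x ROIs table with a header row of ROI names.
#' The delimiter (tab or comma) is auto-detected from the header line.
#' Ragged rows and non-numeric cells raise errors naming the offending
#' row and column.
#'
#' @param path input file path.
#' @param samplingInterval sampling interval in seconds (default 0.664).
#' @return A [SubjectTimeSeries-class].
#' @export
readTimeSeries <- function(path, samplingInterval = 0.664) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (!nzchar(header)) stop("empty file or missing header")
  sep <- if (grepl("\t", header)) "\t" else ","
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character")
  if (ncol(dat) < 2L) stop("expected at least 2 ROI columns")
  if (any(grepl("^V[0-9]+$", names(dat))) &&
      suppressWarnings(!anyNA(as.numeric(names(dat))))) {
    stop("missing header row of ROI names")
  }
  m <- matrix(NA_real_, nrow(dat), ncol(dat))
  for (j in seq_len(ncol(dat))) {
    v <- suppressWarnings(as.numeric(dat[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   dat[[j]][bad], bad, names(dat)[j]))
    }
    m[, j] <- v
  }
  SubjectTimeSeries(t(m), roiNames = names(dat),
                    samplingInterval = samplingInterval)
}

#' Write / read a cohort table as CSV
#'
#' The cohort CSV carries one row per subject with the column
#' dictionary of [simulateCohort()].
#'
#' @param table cohort data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeCohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a flexibility result as a tidy CSV
#'
#' One row per ROI (mean and SD across optimizer runs) plus a
#' network-level summary row.
#'
#' @param result a [FlexibilityResult-class].
#' @param path output file path.
#' @param subjectId optional subject identifier column value.
#' @return `path`, invisibly.
#' @export
writeFlexibility <- function(result, path, subjectId = NA_character_) {
  stopifnot(is(result, "FlexibilityResult"))
  f <- result@nodeFlexibility
  sdv <- if (length(result@nodeSD)) result@nodeSD else rep(NA_real_,
                                                           length(f))
  df <- data.frame(
    subject_id = subjectId,
    unit = c(names(f), "network"),
    flexibility = c(unname(f), result@networkFlexibility),
    sd_across_runs = c(sdv, result@networkSD),
    n_runs = result@nRuns, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
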