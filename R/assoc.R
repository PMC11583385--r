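#' Flag potential outliers by the 2 x IQR rule
#'
#' For each screened variable, computes the quartiles (type-7, linear
#' interpolation), the interquartile range, and flags values below
#' `Q1 - k * IQR` or above `Q3 + k * IQR` with `k = 2`. Flags are
#' reported only — no rows are dropped. A constant variable has zero
#' IQR, so any deviation from the constant is flagged.
#'
#' @param table cohort data.frame.
#' @param variables character vector of columns to screen (default: all
#'   numeric columns).
#' @param k IQR multiplier (default 2).
#'
#' @return A list with class `"screeningReport"`: one entry per
#'   variable with `q1`, `q3`, `iqr`, `lower`, `upper`, `flagged`
#'   (row indices), `n_missing`.
#' @examples
#' rep <- screenOutliers(data.frame(x = c(1:100, 500)))
#' rep$x$flagged  # 101
#' @export
screenOutliers <- function(table, variables = NULL, k = 2) {
  stopifnot(is.data.frame(table))
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  out <- lapply(variables, function(v) {
    if (!v %in% names(table)) stop(sprintf("no column '%s'", v))
    x <- table[[v]]
    ok <- !is.na(x)
    if (sum(ok) == 0L) stop(sprintf("variable '%s' is entirely missing", v))
    if (sum(ok) < 4L) {
      stop(sprintf("variable '%s' has fewer than 4 non-missing values", v))
    }
    q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lower <- q[1] - k * iqr
    upper <- q[2] + k * iqr
    list(q1 = q[1], q3 = q[2], iqr = iqr, lower = lower, upper = upper,
         flagged = which(ok & (x < lower | x > upper)),
         n_missing = sum(!ok))
  })
  names(out) <- variables
  structure(out, class = "screeningReport")
}

#' @export
print.screeningReport <- function(x, ...) {
  cat("Outlier screening (2 x IQR rule; flags reported, rows retained)\n")
  for (v in names(x)) {
    e <- x[[v]]
    cat(sprintf("  %-22s [%g, %g] flagged: %s\n", v, e$lower, e$upper,
                if (length(e$flagged)) paste(e$flagged, collapse = ", ")
                else "none"))
  }
  invisible(x)
}

# z-score ignoring nothing (input already complete-case)
zScore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance variable cannot be standardized")
  (x - mean(x)) / s
}

#' Covariate-adjusted standardized linear model
#'
#' Ordinary least squares of a z-scored outcome on a z-scored focal
#' predictor plus covariates. Continuous covariates are z-scored;
#' binary covariates (by default `sex`) enter 0/1 unscaled, so the
#' focal coefficient is the standardized beta in the reporting
#' convention of covariate-adjusted association studies. Rows with
#' missing values in any model variable are dropped listwise and the n
#' used is reported. Standardized residuals (residual / residual SD)
#' beyond +/- 2 are flagged, never dropped.
#'
#' @param table cohort data.frame.
#' @param outcome outcome column name.
#' @param focal focal predictor column name.
#' @param covariates covariate column names (default age, sex,
#'   education).
#' @param binaryCovariates covariates entered unscaled (default "sex").
#'
#' @return A list with class `"adjustedModelFit"`: `beta`, `se`, `t`,
#'   `p`, `r_squared`, `r`, `f`, `df1`, `df2`, `n`, `outcome`, `focal`,
#'   `covariates`, `flagged_residuals`, `coefficients`.
#' @examples
#' coh <- simulateCohort(cohortConfig(100, seed = 1))
#' fitAdjustedModel(coh, "ae_accuracy", "ptau231")
#' @export
fitAdjustedModel <- function(table, outcome, focal,
                             covariates = c("age", "sex", "education"),
                             binaryCovariates = "sex") {
  varsNeeded <- c(outcome, focal, covariates)
  missingCols <- setdiff(varsNeeded, names(table))
  if (length(missingCols)) {
    stop("missing required column(s): ", paste(missingCols, collapse = ", "))
  }
  dat <- table[, varsNeeded, drop = FALSE]
  keep <- stats::complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]
  n <- nrow(dat)
  kTerms <- 1L + length(covariates)
  if (n <= kTerms + 1L) {
    stop(sprintf("n = %d is too small for %d model terms", n, kTerms))
  }
  if (stats::sd(dat[[focal]]) == 0) {
    stop(sprintf("focal predictor '%s' is constant", focal))
  }
  y <- zScore(dat[[outcome]])
  xCols <- lapply(c(focal, covariates), function(v) {
    if (v %in% binaryCovariates) dat[[v]] else zScore(dat[[v]])
  })
  x <- cbind(1, do.call(cbind, xCols))
  colnames(x) <- c("(Intercept)", focal, covariates)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) stop("singular design matrix")
  fit <- stats::lm.fit(x, y)
  res <- fit$residuals
  df2 <- n - kTerms - 1L
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  sigma2 <- rss / df2
  xtxInv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(xtxInv))[2L]
  beta <- fit$coefficients[2L]
  tval <- beta / se
  fstat <- (r2 / kTerms) / ((1 - r2) / df2)
  stdRes <- res / sqrt(sigma2)
  structure(list(
    beta = unname(beta), se = unname(se), t = unname(tval),
    p = 2 * stats::pt(-abs(tval), df2),
    r_squared = r2, r = sqrt(r2), f = fstat,
    df1 = kTerms, df2 = df2, n = n,
    outcome = outcome, focal = focal, covariates = covariates,
    flagged_residuals = which(abs(stdRes) > 2),
    coefficients = stats::setNames(fit$coefficients, colnames(x))),
    class = "adjustedModelFit")
}

#' @export
print.adjustedModelFit <- function(x, ...) {
  cat(sprintf("%s ~ %s (+ %s), n = %d\n", x$outcome, x$focal,
              paste(x$covariates, collapse = ", "), x$n))
  cat(sprintf("  beta = %.3f, t = %.3f, p = %.4g\n", x$beta, x$t, x$p))
  cat(sprintf("  R2 = %.3f (R = %.3f), F(%d, %d) = %.3f\n",
              x$r_squared, x$r, x$df1, x$df2, x$f))
  invisible(x)
}

#' The study's focal association models
#'
#' Fits the full suite of covariate-adjusted focal models linking
#' cognition, flexibility and plasma biomarkers: AE accuracy and RAVLT
#' delayed recall against MTL network flexibility, and each biomarker
#' (p-tau231, p-tau181, Abeta42/40) against AE accuracy, RAVLT delayed
#' recall and flexibility. Age, sex and education are covariates in
#' every model; the AE acquisition score is an additional covariate in
#' every model whose outcome or focal predictor is AE accuracy. No
#' multiple-testing adjustment is applied (p values are reported at
#' nominal alpha).
#'
#' @param table cohort data.frame with the [simulateCohort()] column
#'   dictionary.
#'
#' @return A tidy data.frame, one row per model: `outcome`, `focal`,
#'   `beta`, `t`, `p`, `r_squared`, `r`, `f`, `df1`, `df2`, `n`,
#'   `covariates`.
#' @export
runModelSuite <- function(table) {
  required <- c("network_flexibility", "ae_accuracy",
                "ae_acquisition_score", "ravlt_delayed", "ptau231",
                "ptau181", "abeta_ratio", "age", "sex", "education")
  missingCols <- setdiff(required, names(table))
  if (length(missingCols)) {
    stop("missing required column(s): ", paste(missingCols, collapse = ", "))
  }
  base <- c("age", "sex", "education")
  withAcq <- c(base, "ae_acquisition_score")
  models <- list(
    list(outcome = "network_flexibility", focal = "ae_accuracy",
         covariates = withAcq),
    list(outcome = "network_flexibility", focal = "ravlt_delayed",
         covariates = base),
    list(outcome = "ae_accuracy", focal = "ptau231", covariates = withAcq),
    list(outcome = "ae_accuracy", focal = "ptau181", covariates = withAcq),
    list(outcome = "ae_accuracy", focal = "abeta_ratio",
         covariates = withAcq),
    list(outcome = "ravlt_delayed", focal = "ptau231", covariates = base),
    list(outcome = "ravlt_delayed", focal = "ptau181", covariates = base),
    list(outcome = "ravlt_delayed", focal = "abeta_ratio",
         covariates = base),
    list(outcome = "network_flexibility", focal = "ptau231",
         covariates = base),
    list(outcome = "network_flexibility", focal = "ptau181",
         covariates = base),
    list(outcome = "network_flexibility", focal = "abeta_ratio",
         covariates = base))
  rows <- lapply(models, function(m) {
    fit <- fitAdjustedModel(table, m$outcome, m$focal, m$covariates)
    data.frame(outcome = m$outcome, focal = m$focal, beta = fit$beta,
               t = fit$t, p = fit$p, r_squared = fit$r_squared, r = fit$r,
               f = fit$f, df1 = fit$df1, df2 = fit$df2, n = fit$n,
               covariates = paste(m$covariates, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact power of the two-tailed point-biserial correlation test
#'
#' Power of the two-sided t test of a correlation of magnitude `rho` at
#' sample size `n`, using the noncentral t distribution with
#' noncentrality `sqrt(n) * rho / sqrt(1 - rho^2)` and `n - 2` degrees
#' of freedom.
#'
#' @param n sample size (>= 4).
#' @param rho effect size, 0 < rho < 1.
#' @param alpha two-tailed significance level.
#'
#' @return A list: `power`, `critical_t`, `df`, `ncp`.
#' @export
pointBiserialPower <- function(n, rho, alpha = 0.05) {
  stopUnlessScalar(rho, "rho", 1e-12, 1 - 1e-12)
  stopUnlessScalar(alpha, "alpha", 1e-12, 1 - 1e-12)
  df <- n - 2
  crit <- stats::qt(1 - alpha / 2, df)
  ncp <- sqrt(n) * rho / sqrt(1 - rho^2)
  pw <- stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
  list(power = pw, critical_t = crit, df = df, ncp = ncp)
}

#' Minimal sample size for the point-biserial correlation test
#'
#' Smallest integer n whose exact noncentral-t power (see
#' [pointBiserialPower()]) reaches `targetPower` for a two-tailed test
#' of effect size `rho` at level `alpha`. For rho = 0.40, alpha = 0.05
#' and power 0.95 the answer is 71 subjects.
#'
#' @param rho effect size, 0 < rho < 1.
#' @param alpha two-tailed significance level (default 0.05).
#' @param targetPower required power (default 0.95).
#' @param nMax search bound (default 1e6).
#'
#' @return A list: `n`, `critical_t` and `achieved_power` at the
#'   returned n.
#' @examples
#' sampleSizePointBiserial(0.40)$n  # 71
#' @export
sampleSizePointBiserial <- function(rho, alpha = 0.05, targetPower = 0.95,
                                    nMax = 1e6) {
  stopUnlessScalar(targetPower, "targetPower", 1e-12, 1 - 1e-12)
  for (n in 4:nMax) {
    pw <- pointBiserialPower(n, rho, alpha)
    if (pw$power >= targetPower) {
      return(list(n = as.integer(n), critical_t = pw$critical_t,
                  achieved_power = pw$power))
    }
  }
  stop(sprintf("power %g unattainable with n <= %g", targetPower, nMax))
}
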