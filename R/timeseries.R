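# Descriptors of incubation curves: maximum cumulative product, windowed
# production rate, tangent-intercept lag time, replicate aggregation.
#
# Incubation series are long-format data.frames with columns
#   treatment, analyte, replicate, day, conc
# (concentrations in mmol/L, time in days). Headspace-to-liquid
# normalisation is assumed already applied upstream.

.seriesColumns <- c("treatment", "analyte", "replicate", "day", "conc")

.checkSeries <- function(series) {
  if (!is.data.frame(series) || !all(.seriesColumns %in% names(series)))
    stop(sprintf("incubation series must have columns %s",
                 paste(.seriesColumns, collapse = ", ")))
  if (nrow(series) == 0L) stop("incubation series is empty")
  for (key in split(series, list(series$treatment, series$analyte,
                                 series$replicate), drop = TRUE)) {
    if (anyDuplicated(key$day))
      stop(sprintf(
        "duplicated sampling times within a replicate (treatment '%s', analyte '%s', replicate '%s')",
        key$treatment[1], key$analyte[1], key$replicate[1]))
  }
  if (any(series$conc < 0))
    stop("negative concentrations; clamp (and flag) before analysis")
  invisible(series)
}

# stored series are additionally required to be time-ordered
.checkSeriesOrdered <- function(series) {
  .checkSeries(series)
  for (key in split(series, list(series$treatment, series$analyte,
                                 series$replicate), drop = TRUE)) {
    if (is.unsorted(key$day, strictly = TRUE))
      stop(sprintf(
        "times must be strictly increasing within a replicate (treatment '%s', analyte '%s', replicate '%s')",
        key$treatment[1], key$analyte[1], key$replicate[1]))
  }
  invisible(series)
}

#' Read / write incubation time series as TSV
#'
#' The TSV format has columns `treatment`, `analyte`, `replicate`, `day`,
#' `conc` (mmol/L) and optionally `clamped`. The reader validates that
#' times are strictly increasing within each replicate series and that
#' concentrations are nonnegative.
#'
#' @param file Path to the TSV file.
#' @return `readIncubationTSV`: a validated data.frame.
#' @export
readIncubationTSV <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  .checkSeriesOrdered(df)
  df
}

#' @rdname readIncubationTSV
#' @param series Long-format incubation data.frame.
#' @export
writeIncubationTSV <- function(series, file) {
  .checkSeriesOrdered(series)
  utils::write.table(series, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# replicate-mean curve of one treatment x analyte slice
.meanCurve <- function(series) {
  agg <- stats::aggregate(conc ~ day, data = series, FUN = mean)
  agg[order(agg$day), ]
}

.oneSeries <- function(series, treatment = NULL, analyte = NULL) {
  if (!is.null(treatment)) series <- series[series$treatment == treatment, ]
  if (!is.null(analyte)) series <- series[series$analyte == analyte, ]
  if (nrow(series) == 0L) stop("no observations after filtering")
  if (length(unique(series$treatment)) > 1L ||
      length(unique(series$analyte)) > 1L)
    stop("series spans several treatments/analytes; filter first")
  series
}

#' Maximum cumulative product of an incubation series
#'
#' The maximum over sampling times of the replicate-mean concentration.
#' Invariant to sample reordering; adding a later, larger observation can
#' only increase it.
#'
#' @param series Long-format incubation data.frame (one treatment/analyte,
#'   or use the filters).
#' @param treatment,analyte Optional filters.
#' @return Concentration (mmol/L).
#' @export
maxCumulative <- function(series, treatment = NULL, analyte = NULL) {
  .checkSeries(series)
  series <- .oneSeries(series, treatment, analyte)
  max(.meanCurve(series)$conc)
}

#' Windowed production rate
#'
#' Per-replicate least-squares slope of concentration against time over
#' `[startDay, endDay]`, aggregated as mean and sample SD across
#' replicates. Every replicate must contribute at least two samples in the
#' window.
#'
#' @inheritParams maxCumulative
#' @param startDay,endDay Window bounds in days (inclusive).
#' @return List with `window`, `slopes` (per replicate), `mean`, `sd`
#'   (mmol/L/day; `sd` is `NA` for a single replicate).
#' @examples
#' d <- data.frame(treatment = "M", analyte = "CH4", replicate = 1,
#'                 day = 28:35, conc = 1.4 * (28:35 - 28))
#' windowRate(d, 28, 35)$mean  # 1.4
#' @export
windowRate <- function(series, startDay, endDay,
                       treatment = NULL, analyte = NULL) {
  .checkSeries(series)
  stopifnot(startDay < endDay)
  series <- .oneSeries(series, treatment, analyte)
  win <- series[series$day >= startDay & series$day <= endDay, ]
  if (nrow(win) == 0L) stop("no samples fall inside the window")
  slopes <- vapply(split(win, win$replicate), function(d) {
    if (nrow(d) < 2L)
      stop(sprintf("replicate '%s' has fewer than 2 samples in the window",
                   d$replicate[1]))
    unname(stats::coef(stats::lm(conc ~ day, data = d))["day"])
  }, numeric(1))
  list(window = c(start = startDay, end = endDay),
       slopes = slopes,
       mean = mean(slopes),
       sd = if (length(slopes) > 1L) stats::sd(slopes) else NA_real_)
}

#' Fit a modified-Gompertz curve to an incubation series
#'
#' Least-squares fit of [gompertzCurve()] plus a fixed baseline to the
#' replicate-mean curve, parameterised directly in asymptote `A`
#' (mmol/L), maximum rate `Rmax` (mmol/L/day) and lag `lag` (days; the
#' intercept of the maximum-slope tangent with the baseline). Starting
#' values come from the empirical maximum-slope tangent.
#'
#' @inheritParams maxCumulative
#' @param baseline Baseline concentration. By default the baseline is a
#'   free nonnegative parameter bounded above by the smallest
#'   replicate-mean value (a curve already rising at the first sample must
#'   not inflate the baseline); pass a number to fix it.
#' @return List with `A`, `Rmax`, `lag`, `baseline`, `fitted` values and
#'   `converged`.
#' @export
fitGompertz <- function(series, treatment = NULL, analyte = NULL,
                        baseline = NULL) {
  .checkSeries(series)
  series <- .oneSeries(series, treatment, analyte)
  mc <- .meanCurve(series)
  t <- mc$day; y <- mc$conc
  if (length(t) < 4L) stop("need at least 4 time points to fit a curve")
  freeBase <- is.null(baseline)
  b0 <- if (freeBase) min(y) else baseline
  emp <- .tangentEstimate(t, y, b0)
  dat <- data.frame(t = t, y = y)
  start <- list(A = max(emp$A, 1e-3), Rmax = max(emp$Rmax, 1e-3),
                lag = emp$lag)
  lower <- c(A = 0, Rmax = 0, lag = -max(t))
  upper <- c(A = Inf, Rmax = Inf, lag = max(t))
  if (freeBase && b0 > 0) {
    form <- y ~ b + gompertzCurve(t, A, Rmax, lag)
    start$b <- b0 / 2
    lower <- c(lower, b = 0); upper <- c(upper, b = b0)
  } else {
    if (freeBase) baseline <- 0
    b <- baseline
    form <- y ~ b + gompertzCurve(t, A, Rmax, lag)
    dat$b <- b
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(A = emp$A, Rmax = emp$Rmax, lag = emp$lag,
                baseline = b0, fitted = NULL, converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(A = unname(cf["A"]), Rmax = unname(cf["Rmax"]),
       lag = unname(cf["lag"]),
       baseline = if ("b" %in% names(cf)) unname(cf["b"]) else baseline,
       fitted = stats::fitted(fit), converged = TRUE)
}

# empirical maximum-slope tangent from local 3-point slopes
.tangentEstimate <- function(t, y, baseline) {
  n <- length(t)
  slopes <- numeric(n - 1L)
  mid <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 2L)
    fit <- stats::lm.fit(cbind(1, t[lo:hi]), y[lo:hi])
    slopes[i] <- fit$coefficients[2]
    mid[i] <- mean(t[c(i, i + 1L)])
  }
  k <- which.max(slopes)
  s <- slopes[k]
  yk <- stats::approx(t, y, xout = mid[k])$y
  lag <- if (s > 0) mid[k] - (yk - baseline) / s else 0
  list(A = max(y) - baseline, Rmax = max(s, 0),
       lag = min(max(lag, 0), max(t)))
}

#' Lag time of a cumulative production curve
#'
#' Tangent-intercept lag: the intersection of the maximum-slope tangent
#' with the baseline, the standard operational definition for anaerobic
#' biodegradability curves. Estimated by fitting a modified-Gompertz curve
#' (whose lag parameter is exactly this intercept); if the fit fails, the
#' empirical tangent through the steepest local slope is used instead, and
#' the `method` tag records which path produced the estimate.
#'
#' A series that never rises above the baseline by more than `noiseFloor`
#' has no defined lag (`defined = FALSE`).
#'
#' @inheritParams maxCumulative
#' @param noiseFloor Minimum amplitude (mmol/L) above baseline for a lag to
#'   be defined. Default 0.5, about twice the replicate noise of headspace
#'   methane measurements.
#' @return List with `lag` (days), `defined`, `method` (`"gompertz-tangent"`
#'   or `"empirical-tangent"`), and the `A`, `Rmax`, `baseline` used.
#' @examples
#' d <- expand.grid(replicate = 1, day = seq(0, 60, 2))
#' d$treatment <- "M"; d$analyte <- "CH4"
#' d$conc <- gompertzCurve(d$day, A = 28, Rmax = 1.4, lag = 13)
#' lagTime(d)$lag  # about 13
#' @export
lagTime <- function(series, treatment = NULL, analyte = NULL,
                    noiseFloor = 0.5) {
  .checkSeries(series)
  series <- .oneSeries(series, treatment, analyte)
  mc <- .meanCurve(series)
  amplitude <- max(mc$conc) - min(mc$conc)
  if (amplitude <= noiseFloor) {
    return(list(lag = NA_real_, defined = FALSE, method = "none",
                A = amplitude, Rmax = NA_real_, baseline = mc$conc[1]))
  }
  fit <- fitGompertz(series)
  lag <- min(max(fit$lag, 0), max(mc$day))
  list(lag = lag, defined = TRUE,
       method = if (fit$converged) "gompertz-tangent" else "empirical-tangent",
       A = fit$A, Rmax = fit$Rmax, baseline = fit$baseline)
}

#' Replicate mean and sample standard deviation
#'
#' Arithmetic mean and sample SD (n - 1 denominator) across replicate
#' values, with the conventional `"m ± s"` formatting at one decimal.
#' The SD is omitted for a single value.
#'
#' @param values Numeric vector of per-replicate values.
#' @param digits Decimals for the formatted string (default 1).
#' @return List with `mean`, `sd` (`NA` for n = 1), `n`, `formatted`.
#' @examples
#' replicateStats(c(6.0, 6.6, 7.2))$formatted  # "6.6 +/- 0.6"
#' @export
replicateStats <- function(values, digits = 1) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("need at least one value")
  m <- mean(values)
  s <- if (length(values) > 1L) stats::sd(values) else NA_real_
  fmt <- if (is.na(s)) {
    sprintf("%.*f", digits, m)
  } else {
    sprintf("%.*f ± %.*f", digits, m, digits, s)
  }
  list(mean = m, sd = s, n = length(values), formatted = fmt)
}
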