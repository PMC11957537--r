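#' Doubling time from an exponential growth rate
#'
#' `t_d = ln(2) / k`.
#'
#' @param k exponential growth rate (1/min), positive.
#' @return doubling time (min).
#' @export
doublingTime <- function(k) {
  if (any(!is.finite(k) | k <= 0))
    stop("domain error: k must be positive")
  log(2) / k
}

#' Generations elapsed during regrowth
#'
#' `log2(nf / n0)`: the number of doublings taking an initial population
#' `n0` to a final population `nf`. Additive over serial transfers. A daily
#' 1000-fold dilution-regrowth cycle corresponds to about 10 generations.
#'
#' @param n0 initial population size, positive.
#' @param nf final population size, positive.
#' @return number of generations (dimensionless).
#' @export
generationsElapsed <- function(n0, nf) {
  if (any(!is.finite(n0) | n0 <= 0) || any(!is.finite(nf) | nf <= 0))
    stop("domain error: populations must be positive")
  log(nf / n0) / log(2)
}

#' Selection coefficient from a pairwise competition assay
#'
#' With `R = countA / countB` the ratio of the focal strain to the reference
#' at the start and end of the competition, the selection coefficient is the
#' per-unit-time log ratio change
#' \deqn{s = \ln( R(t) / R(0) ) / t.}
#' Swapping the strains flips the sign of `s`. When `t` is measured in
#' generations the conventional relative fitness `1 + s` is also reported;
#' for clock-time units relative fitness is left `NA` and the time unit is
#' flagged in the output.
#'
#' @param countA0,countB0 strain counts at time 0, positive.
#' @param countAt,countBt strain counts at time `t`, positive.
#' @param t elapsed competition time, positive.
#' @param timeUnit `"generation"` (default) or `"hour"`; only a flag carried
#'   into the output and used to decide whether `1 + s` is meaningful.
#' @return list of class `"selectionCoefficient"`: `s` (per `timeUnit`),
#'   `relative_fitness` (`1 + s` for generation time, else `NA`),
#'   `R0`, `Rt`, `t`, `time_unit`.
#' @examples
#' # neutral marker: equal ratios, s = 0, relative fitness 1
#' selectionCoefficient(100, 100, 500, 500, t = 10)
#' @export
selectionCoefficient <- function(countA0, countB0, countAt, countBt, t,
                                 timeUnit = c("generation", "hour")) {
  timeUnit <- match.arg(timeUnit)
  counts <- c(countA0, countB0, countAt, countBt)
  if (any(!is.finite(counts) | counts <= 0))
    stop("domain error: all counts must be positive")
  if (!is.finite(t) || t <= 0) stop("domain error: t must be positive")
  R0 <- countA0 / countB0
  Rt <- countAt / countBt
  s <- log(Rt / R0) / t
  structure(list(s = s,
                 relative_fitness = if (timeUnit == "generation") 1 + s
                                    else NA_real_,
                 R0 = R0, Rt = Rt, t = t, time_unit = timeUnit),
            class = "selectionCoefficient")
}

#' @export
print.selectionCoefficient <- function(x, ...) {
  cat(sprintf("s = %.4g per %s", x$s, x$time_unit))
  if (is.finite(x$relative_fitness))
    cat(sprintf(", relative fitness = %.3f", x$relative_fitness))
  cat("\n")
  invisible(x)
}

#' Identify lag and exponential phase of a growth curve
#'
#' Processes an optical-density time series as a semi-log plot: the maximal
#' growth rate `k` is the largest slope of `ln(OD)` over a sliding window of
#' `window` points, and the lag time is found by extrapolating the max-slope
#' line back to the initial OD. Both `k` and the lag are invariant under
#' multiplying the whole curve by a positive constant (blank subtraction is
#' the caller's responsibility; non-positive ODs are excluded from the log
#' fit with a warning).
#'
#' @param times observation times (min), strictly increasing.
#' @param od optical density (absorbance at 600 nm), same length as `times`.
#' @param window number of points per sliding window (default 5, i.e. 25 min
#'   at the usual 5-min plate-reader interval).
#' @return list of class `"growthPhases"`: `lag` (min), `k` (1/min),
#'   `max_od`, `window`, plus `lag_definition` flagging the back-extrapolation
#'   convention.
#' @export
identifyPhases <- function(times, od, window = 5) {
  if (length(times) != length(od)) stop("times and od differ in length")
  if (any(diff(times) <= 0))
    stop("domain error: times must be strictly increasing")
  keep <- is.finite(od) & od > 0
  if (!all(keep)) {
    warning(sum(!keep), " non-positive/missing OD value(s) excluded from ",
            "the log fit")
    times <- times[keep]; od <- od[keep]
  }
  if (length(times) < 2 * window)
    stop("insufficient data: need at least 2 * window points")
  y <- log(od)
  n <- length(times)
  nW <- n - window + 1L
  slope <- numeric(nW); intercept <- numeric(nW)
  for (i in seq_len(nW)) {
    idx <- i:(i + window - 1L)
    f <- lm.fit(cbind(1, times[idx]), y[idx])
    intercept[i] <- f$coefficients[1]
    slope[i] <- f$coefficients[2]
  }
  best <- which.max(slope)
  k <- slope[best]
  if (!is.finite(k) || k < 1e-8)
    stop("insufficient data: no exponential region detected (max slope <= 0)")
  lag <- (y[1] - intercept[best]) / k
  lag <- max(lag, 0)
  structure(list(lag = lag, k = k, max_od = max(od), window = window,
                 lag_definition = "back-extrapolation of max-slope line to initial OD"),
            class = "growthPhases")
}

#' @export
print.growthPhases <- function(x, ...) {
  cat(sprintf("lag = %.4g min, k = %.4g /min (doubling %.4g min), max OD = %.3g\n",
              x$lag, x$k, log(2) / x$k, x$max_od))
  invisible(x)
}
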