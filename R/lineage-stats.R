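#' Single-cell elongation rate from a volume trajectory
#'
#' Fits the exponential growth model `V(t) = V0 * exp(r * t)` by ordinary
#' least squares on `log(V)` versus time (time is taken relative to the first
#' observation, i.e. the cell's own cycle clock).
#'
#' @param time observation times (min), strictly increasing, length >= 3.
#' @param volume volumes (um^3), strictly positive.
#' @return object of class `"rateFit"`: list with `r` (1/min), `V0` (um^3,
#'   volume at the first observation time), `n_points`, and `rss` (residual
#'   sum of squares on the log scale).
#' @examples
#' t <- seq(0, 30, 5)
#' fitElongationRate(t, 2 * exp(0.01 * t))$r   # 0.01
#' @export
fitElongationRate <- function(time, volume) {
  if (length(time) < 3)
    stop("insufficient data: need at least 3 points to fit a rate")
  if (length(volume) != length(time))
    stop("time and volume must have equal length")
  if (any(!is.finite(volume) | volume <= 0))
    stop("domain error: volumes must be strictly positive")
  if (any(diff(time) <= 0))
    stop("domain error: times must be strictly increasing")
  tt <- time - time[1]
  fit <- lm.fit(cbind(1, tt), log(volume))
  structure(list(r = unname(fit$coefficients[2]),
                 V0 = exp(unname(fit$coefficients[1])),
                 n_points = length(time),
                 rss = sum(fit$residuals^2)),
            class = "rateFit")
}

#' @export
print.rateFit <- function(x, ...) {
  cat(sprintf("rateFit: r = %.5g /min, V0 = %.4g um^3 (n = %d, rss = %.3g)\n",
              x$r, x$V0, x$n_points, x$rss))
  invisible(x)
}

#' Septation rate
#'
#' `ln(2) / tau`, where `tau` is the mean division time (birth to septation)
#' pooled over the divided cells of the analysis set. Balanced against the
#' elongation rate, this sets whether mean cell volume is stable across
#' generations (see [homeostasisCheck()]).
#'
#' @param x a [LineageTable-class] (divided cells are used) or a numeric
#'   vector of division times (min).
#' @return septation rate (1/min).
#' @export
septationRate <- function(x) {
  tau <- if (is(x, "LineageTable")) {
    cc <- x@cells
    d <- cc$fate == "divided"
    cc$division_time[d] - cc$birth_time[d]
  } else as.numeric(x)
  tau <- tau[is.finite(tau)]
  if (length(tau) < 1)
    stop("insufficient data: no divided cells")
  if (any(tau <= 0)) stop("domain error: division times must be positive")
  log(2) / mean(tau)
}

#' Sister-cell asymmetry statistics Cg, CT and Cs
#'
#' Mean relative sister differences over a set of pairs: elongation rate
#' `Cg = <|r1 - r2| / (r1 + r2)>`, division time
#' `CT = <|T1 - T2| / (T1 + T2)>`, and birth volume (septum-placement
#' precision) `Cs = <|V1 - V2| / (V1 + V2)>`. Cg and CT are averaged over
#' pairs in which both sisters proliferate (both divided), which removes the
#' trivial bias from proliferation arrest of one sister; Cs is averaged over
#' all pairs with both birth volumes measured (the mother divided by
#' construction). Each statistic lies in \[0, 1\], is invariant under sister
#' relabelling, and is zero iff all eligible pairs are identical.
#'
#' @param pairs pair table from [extractSisterPairs()].
#' @param strict if `TRUE`, a statistic with no eligible pairs is an error;
#'   the default returns `NA` for it with a warning naming the statistic.
#' @return list of class `"asymmetrySummary"`: `Cg`, `CT`, `Cs` and the
#'   per-statistic pair counts `n_Cg`, `n_CT`, `n_Cs`.
#' @export
asymmetrySummary <- function(pairs, strict = FALSE) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L)
    stop("insufficient data: no sister pairs")
  relDiff <- function(a, b) abs(a - b) / (a + b)
  bothDiv <- pairs$fate_a == "divided" & pairs$fate_b == "divided"
  gOK <- bothDiv & is.finite(pairs$r_a) & is.finite(pairs$r_b) &
    (pairs$r_a + pairs$r_b) > 0
  tOK <- bothDiv & is.finite(pairs$T_a) & is.finite(pairs$T_b)
  sOK <- is.finite(pairs$Vb_a) & is.finite(pairs$Vb_b)
  one <- function(ok, a, b, nm) {
    if (!any(ok)) {
      if (strict)
        stop("insufficient data: no eligible pairs for ", nm)
      warning("no eligible pairs for ", nm, "; returning NA")
      return(NA_real_)
    }
    mean(relDiff(a[ok], b[ok]))
  }
  structure(list(Cg = one(gOK, pairs$r_a, pairs$r_b, "Cg"),
                 CT = one(tOK, pairs$T_a, pairs$T_b, "CT"),
                 Cs = one(sOK, pairs$Vb_a, pairs$Vb_b, "Cs"),
                 n_Cg = sum(gOK), n_CT = sum(tOK), n_Cs = sum(sOK)),
            class = "asymmetrySummary")
}

#' @export
print.asymmetrySummary <- function(x, ...) {
  cat(sprintf("Cg = %.4g (n = %d), CT = %.4g (n = %d), Cs = %.4g (n = %d)\n",
              x$Cg, x$n_Cg, x$CT, x$n_CT, x$Cs, x$n_Cs))
  invisible(x)
}

#' Wald 95% half-width for a binomial proportion
#'
#' `1.96 * sqrt(p * (1 - p) / n)`, the normal-approximation confidence
#' half-width used for the survival probability.
#'
#' @param p estimated proportion(s).
#' @param n count(s).
#' @return half-width(s) on the probability scale.
#' @export
waldHalfwidth <- function(p, n) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("domain error: p must be in [0, 1]")
  if (any(n < 1, na.rm = TRUE)) stop("domain error: n must be >= 1")
  1.96 * sqrt(p * (1 - p) / n)
}

#' Probability of passing to the next generation
#'
#' The fraction of observed cells at a generation that successfully divide:
#' `p = n_divided / (n_divided + n_arrested)`. Censored cells (still under
#' observation at the end of the experiment) are excluded from the
#' denominator, so an observation window never counts as a death. The 95%
#' confidence half-width is the Wald interval `1.96 * sqrt(p(1-p)/N)`.
#'
#' @param x a [LineageTable-class].
#' @param generation integer generation to score, or `"all"`.
#' @return list of class `"survivalEstimate"`: `p`, `N` (non-censored cells
#'   counted) and `ci_halfwidth`.
#' @export
survivalProbability <- function(x, generation = "all") {
  stopifnot(is(x, "LineageTable"))
  cc <- x@cells
  if (!identical(generation, "all"))
    cc <- cc[cc$generation == as.integer(generation), , drop = FALSE]
  cc <- cc[cc$fate != "censored", , drop = FALSE]
  if (nrow(cc) == 0L)
    stop("insufficient data: no non-censored cells at this generation")
  p <- mean(cc$fate == "divided")
  structure(list(p = p, N = nrow(cc), ci_halfwidth = waldHalfwidth(p, nrow(cc))),
            class = "survivalEstimate")
}

#' @export
print.survivalEstimate <- function(x, ...) {
  cat(sprintf("p = %.3f +/- %.3f (95%% CI, N = %d)\n",
              x$p, x$ci_halfwidth, x$N))
  invisible(x)
}

#' Survival probability as a function of birth volume
#'
#' Bins non-censored cells on birth volume and estimates the probability of
#' passing to the next generation per bin. Bins whose count falls below
#' `minCount` are flagged rather than dropped; empty bins are reported with
#' `N = 0` and `p = NA`.
#'
#' @param x a [LineageTable-class].
#' @param bins strictly increasing volume bin edges (um^3); default: deciles
#'   of the pooled birth-volume distribution of the scored cells.
#' @param generation generation filter as in [survivalProbability()].
#' @param minCount minimum per-bin count below which the bin is flagged
#'   (default 5).
#' @return `data.frame` with `bin_lo`, `bin_hi`, `N`, `p`, `ci_halfwidth`,
#'   `flagged`.
#' @export
survivalVsVolume <- function(x, bins = NULL, generation = "all",
                             minCount = 5) {
  stopifnot(is(x, "LineageTable"))
  cc <- x@cells
  if (!identical(generation, "all"))
    cc <- cc[cc$generation == as.integer(generation), , drop = FALSE]
  cc <- cc[cc$fate != "censored", , drop = FALSE]
  if (nrow(cc) == 0L) stop("insufficient data: no non-censored cells")
  if (is.null(bins))
    bins <- unique(quantile(cc$birth_volume, probs = seq(0, 1, 0.1),
                            names = FALSE))
  if (length(bins) < 2 || any(diff(bins) <= 0))
    stop("domain error: bins must be strictly increasing edges")
  grp <- cut(cc$birth_volume, breaks = bins, include.lowest = TRUE)
  out <- data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1])
  out$N <- as.integer(table(grp))
  div <- tapply(cc$fate == "divided", grp, sum)
  div[is.na(div)] <- 0
  out$p <- ifelse(out$N > 0, as.numeric(div) / out$N, NA_real_)
  out$ci_halfwidth <- ifelse(out$N > 0, waldHalfwidth(out$p, pmax(out$N, 1)),
                             NA_real_)
  out$flagged <- out$N < minCount
  out
}

#' Added volume per division cycle
#'
#' For each divided cell, the adder increment
#' `dV = division_volume - birth_volume`. Under adder-type division control,
#' the mean birth volume converges within a few generations to the mean added
#' volume.
#'
#' @param x a [LineageTable-class].
#' @param generation generation filter, or `"all"`.
#' @return list of class `"addedVolume"`: `perCell` data.frame (`cell_id`,
#'   `generation`, `birth_volume`, `division_volume`, `dV`), `mean`, `se`
#'   (standard error of the mean) and `n`.
#' @export
addedVolume <- function(x, generation = "all") {
  stopifnot(is(x, "LineageTable"))
  cc <- x@cells
  if (!identical(generation, "all"))
    cc <- cc[cc$generation == as.integer(generation), , drop = FALSE]
  cc <- cc[cc$fate == "divided" & !is.na(cc$division_volume), , drop = FALSE]
  if (nrow(cc) == 0L) stop("insufficient data: no divided cells")
  dV <- cc$division_volume - cc$birth_volume
  per <- data.frame(cell_id = cc$cell_id, generation = cc$generation,
                    birth_volume = cc$birth_volume,
                    division_volume = cc$division_volume, dV = dV,
                    stringsAsFactors = FALSE)
  structure(list(perCell = per, mean = mean(dV),
                 se = sd(dV) / sqrt(length(dV)), n = length(dV)),
            class = "addedVolume")
}

#' @export
print.addedVolume <- function(x, ...) {
  cat(sprintf("added volume: %.4g +/- %.3g um^3 (mean +/- SE, n = %d)\n",
              x$mean, x$se, x$n))
  invisible(x)
}

#' Elongation/septation balance
#'
#' Classifies a strain's size-homeostasis regime from its elongation rate and
#' septation rate: when septation outpaces elongation, progeny volume shrinks
#' across generations; in the opposite case it grows; near equality volume is
#' stable.
#'
#' @param elongationRate single-cell elongation rate (1/min), positive.
#' @param septation septation rate `ln 2 / mean(tau)` (1/min), positive.
#' @param tol relative tolerance around equality defining "balanced"
#'   (default 0.05).
#' @return list of class `"homeostasisPoint"`: `elongation_rate`,
#'   `septation_rate`, `regime` (`"balanced"`, `"shrinking"` or `"growing"`),
#'   `tol`.
#' @export
homeostasisCheck <- function(elongationRate, septation, tol = 0.05) {
  if (!is.finite(elongationRate) || elongationRate <= 0 ||
      !is.finite(septation) || septation <= 0)
    stop("domain error: rates must be positive and finite")
  regime <- if (septation > elongationRate * (1 + tol)) "shrinking"
  else if (septation < elongationRate * (1 - tol)) "growing"
  else "balanced"
  structure(list(elongation_rate = elongationRate,
                 septation_rate = septation, regime = regime, tol = tol),
            class = "homeostasisPoint")
}

#' @export
print.homeostasisPoint <- function(x, ...) {
  cat(sprintf("elongation %.4g /min vs septation %.4g /min: %s (tol %.2g)\n",
              x$elongation_rate, x$septation_rate, x$regime, x$tol))
  invisible(x)
}

#' Effective population growth rate
#'
#' When only a fraction `p` of daughters passes to the next generation, the
#' population model `dN = p * r * N * dt` gives the effective growth rate
#' `p * r`: viability scales the single-cell elongation rate.
#'
#' @param p probability of passing to the next generation, in \[0, 1\].
#' @param r single-cell elongation rate (1/min), positive.
#' @return `p * r` (1/min).
#' @export
effectiveGrowthRate <- function(p, r) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("domain error: p must be in [0, 1]")
  if (any(!is.finite(r) | r <= 0))
    stop("domain error: r must be positive")
  p * r
}

#' Number of proliferating cells alive over time
#'
#' Counts, at each requested time, the cells that have been born and have not
#' yet divided. By default only proliferating cells (fate divided or
#' censored) are counted; arrested cells can be included for bookkeeping.
#'
#' @param x a [LineageTable-class].
#' @param times numeric vector of times (min).
#' @param includeArrested count arrested cells while they are under
#'   observation (default `FALSE`).
#' @return integer vector, same length as `times`.
#' @export
countCells <- function(x, times, includeArrested = FALSE) {
  stopifnot(is(x, "LineageTable"))
  cc <- x@cells
  if (!includeArrested)
    cc <- cc[cc$fate != "arrested", , drop = FALSE]
  lastObs <- tapply(x@series$time, x@series$cell_id, max)
  endOf <- ifelse(is.na(cc$division_time),
                  as.numeric(lastObs[cc$cell_id]), cc$division_time)
  vapply(times, function(t)
    sum(cc$birth_time <= t & endOf > t), integer(1))
}
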