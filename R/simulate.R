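#' Expected sister asymmetry implied by the noise scales
#'
#' Under the antisymmetric pair construction, sisters receive elongation
#' rates `r0*(1+eps)` and `r0*(1-eps)` with `eps = tanh(Z)`,
#' `Z ~ Normal(0, sigma_g)`, so the pairwise statistic is exactly
#' `|r1 - r2|/(r1 + r2) = |eps|` and `Cg = E|tanh(Z)|`. Similarly the septum
#' offset `delta ~ Normal(0, sigma_s)` truncated to (-0.45, 0.45) gives
#' `Cs = E|2 delta|`. These helpers evaluate the two expectations;
#' [calibrateSigmaG()] and [calibrateSigmaS()] invert them.
#'
#' @param sigma_g,sigma_s noise scales (>= 0).
#' @return the expected Cg / Cs (dimensionless).
#' @export
expectedCg <- function(sigma_g) {
  stopifnot(sigma_g >= 0)
  if (sigma_g == 0) return(0)
  2 * integrate(function(z) tanh(z) * dnorm(z, 0, sigma_g),
                0, Inf, rel.tol = 1e-10)$value
}

#' @rdname expectedCg
#' @export
expectedCs <- function(sigma_s) {
  stopifnot(sigma_s >= 0)
  if (sigma_s == 0) return(0)
  b <- 0.45
  mass <- 2 * pnorm(b / sigma_s) - 1
  foldedMean <- sigma_s * sqrt(2 / pi) * (1 - exp(-b^2 / (2 * sigma_s^2)))
  2 * foldedMean / mass
}

#' Calibrate the sister-rate asymmetry scale to a target Cg
#'
#' Numerically inverts `Cg = E|tanh(Normal(0, sigma_g))|` so that lineages
#' simulated with the returned scale reproduce the requested mean relative
#' sister elongation-rate difference. The `tanh` link keeps both sister rates
#' strictly positive while letting Cg span the whole interval (0, 1) (a hard
#' truncation of a mean-zero Gaussian to (-1, 1) caps the achievable Cg at
#' 0.5, below asymmetries observed in strongly perturbed strains).
#'
#' @param targetCg desired Cg, in \[0, 1).
#' @return `sigma_g` such that `expectedCg(sigma_g) == targetCg`.
#' @examples
#' calibrateSigmaG(0)      # 0
#' expectedCg(calibrateSigmaG(0.55))   # 0.55
#' @export
calibrateSigmaG <- function(targetCg) {
  if (!is.finite(targetCg) || targetCg < 0 || targetCg >= 1)
    stop("domain error: targetCg must be in [0, 1)")
  if (targetCg == 0) return(0)
  upper <- 1
  while (expectedCg(upper) < targetCg && upper < 1e3) upper <- upper * 2
  if (expectedCg(upper) < targetCg)
    stop("domain error: targetCg unreachable")
  uniroot(function(s) expectedCg(s) - targetCg, c(1e-9, upper),
          tol = 1e-10)$root
}

#' Calibrate the septum-placement noise to a target Cs
#'
#' Inverts `Cs = E|2 delta|` for the truncated-Gaussian septum offset; the
#' truncation of the daughter volume fraction to (0.05, 0.95) bounds the
#' achievable Cs below 0.45.
#'
#' @param targetCs desired Cs, in \[0, 0.45).
#' @return `sigma_s` such that `expectedCs(sigma_s) == targetCs`.
#' @export
calibrateSigmaS <- function(targetCs) {
  if (!is.finite(targetCs) || targetCs < 0 || targetCs >= 0.45)
    stop("domain error: targetCs must be in [0, 0.45)")
  if (targetCs == 0) return(0)
  uniroot(function(s) expectedCs(s) - targetCs, c(1e-9, 1e3),
          tol = 1e-10)$root
}

#' U-tailed survival-vs-volume curve
#'
#' Probability that a newborn cell of birth volume `V` proliferates: a
#' plateau `p_mid` between `V_lo` and `V_hi` with logistic drops into both
#' volume tails,
#' `p(V) = p_mid * plogis(k*(V - V_lo)) * plogis(k*(V_hi - V))`,
#' so that both very small and very large newborns are unlikely to produce
#' viable offspring.
#'
#' @param V birth volume(s) (um^3).
#' @param V_lo,V_hi plateau edges (um^3), `V_lo < V_hi`.
#' @param p_mid plateau survival probability in \[0, 1\].
#' @param steepness logistic steepness `k` (1/um^3), positive.
#' @return survival probabilities, same length as `V`.
#' @export
survivalCurve <- function(V, V_lo, V_hi, p_mid, steepness) {
  stopifnot(V_lo < V_hi, p_mid >= 0, p_mid <= 1, steepness > 0)
  p_mid * stats::plogis(steepness * (V - V_lo)) *
    stats::plogis(steepness * (V_hi - V))
}

.rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(mean)
  repeat {
    x <- rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
}

#' Simulate time-lapse lineage trees
#'
#' Agent-based generator reproducing the statistical structure the lineage
#' analyses assume: exponential single-cell volume growth sampled at the
#' frame interval, adder-triggered division (a cell divides at the first
#' frame at which it has added its per-cycle volume target
#' `dV0 * (1 + Normal(0, cv_dV))`), antisymmetric sister elongation-rate
#' noise with controlled Cg, septum-placement noise with controlled Cs, and
#' volume-dependent survival drawn at birth from the U-tailed
#' [survivalCurve()] (a newborn either proliferates for its whole cycle or is
#' scored arrested). Cells reaching `n_generations` are censored. Division
#' conserves volume exactly: the daughters' birth volumes sum to the mother's
#' division volume.
#'
#' All randomness derives from `cfg@seed`; each founder lineage runs on its
#' own sub-seed drawn from the master stream, so identical configurations
#' yield identical tables.
#'
#' @param cfg a [SimulationConfig-class].
#' @return a validated [LineageTable-class]; `metadata(x)$config` echoes the
#'   resolved configuration.
#' @examples
#' lt <- simulateLineages(SimulationConfig(n_founders = 5, seed = 42))
#' survivalProbability(lt, generation = 1)
#' @export
simulateLineages <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  dt <- cfg@frame_dt
  sv <- cfg@survival
  set.seed(cfg@seed)
  founderSeeds <- sample.int(.Machine$integer.max - 1L, cfg@n_founders)

  cellRows <- list()
  serId <- list(); serT <- list(); serV <- list()
  ci <- 0L

  drawEps <- function() tanh(rnorm(1, 0, cfg@sigma_g))
  drawFrac <- function() .rtruncnorm1(0.5, cfg@sigma_s, 0.05, 0.95)
  drawTarget <- function() {
    if (cfg@cv_dV == 0) return(cfg@dV0)
    cfg@dV0 * .rtruncnorm1(1, cfg@cv_dV, 0.05, Inf)
  }

  for (f in seq_len(cfg@n_founders)) {
    set.seed(founderSeeds[f])
    Vb0 <- if (cfg@founder_cv == 0) cfg@founder_volume else {
      sdlog <- sqrt(log(1 + cfg@founder_cv^2))
      exp(rnorm(1, log(cfg@founder_volume) - sdlog^2 / 2, sdlog))
    }
    queue <- list(list(id = sprintf("F%04d", f), parent = NA_character_,
                       gen = 0L, birth = 0, Vb = Vb0,
                       r = cfg@r0 * (1 + drawEps()), alive = TRUE))
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      ci <- ci + 1L
      if (cell$gen >= cfg@n_generations) {
        # end of tracking window: censored at birth
        cellRows[[ci]] <- data.frame(
          cell_id = cell$id, parent_id = cell$parent, generation = cell$gen,
          birth_time = cell$birth, division_time = NA_real_,
          fate = "censored", birth_volume = cell$Vb,
          division_volume = NA_real_, stringsAsFactors = FALSE)
        serId[[ci]] <- cell$id; serT[[ci]] <- cell$birth
        serV[[ci]] <- cell$Vb
        next
      }
      if (!cell$alive) {
        # proliferation arrest: observed, never elongates again
        tt <- cell$birth + dt * 0:2
        cellRows[[ci]] <- data.frame(
          cell_id = cell$id, parent_id = cell$parent, generation = cell$gen,
          birth_time = cell$birth, division_time = NA_real_,
          fate = "arrested", birth_volume = cell$Vb,
          division_volume = NA_real_, stringsAsFactors = FALSE)
        serId[[ci]] <- rep(cell$id, length(tt)); serT[[ci]] <- tt
        serV[[ci]] <- rep(cell$Vb, length(tt))
        next
      }
      target <- drawTarget()
      k <- ceiling(log1p(target / cell$Vb) / (cell$r * dt))
      if (!is.finite(k) || k > cfg@max_frames) {
        tt <- cell$birth + dt * 0:2
        cellRows[[ci]] <- data.frame(
          cell_id = cell$id, parent_id = cell$parent, generation = cell$gen,
          birth_time = cell$birth, division_time = NA_real_,
          fate = "arrested", birth_volume = cell$Vb,
          division_volume = NA_real_, stringsAsFactors = FALSE)
        serId[[ci]] <- rep(cell$id, length(tt)); serT[[ci]] <- tt
        serV[[ci]] <- rep(cell$Vb, length(tt))
        next
      }
      k <- max(k, 1L)
      frames <- 0:k
      tt <- cell$birth + dt * frames
      vv <- cell$Vb * exp(cell$r * dt * frames)
      Vd <- vv[length(vv)]
      cellRows[[ci]] <- data.frame(
        cell_id = cell$id, parent_id = cell$parent, generation = cell$gen,
        birth_time = cell$birth, division_time = tt[length(tt)],
        fate = "divided", birth_volume = cell$Vb, division_volume = Vd,
        stringsAsFactors = FALSE)
      serId[[ci]] <- rep(cell$id, length(tt)); serT[[ci]] <- tt
      serV[[ci]] <- vv
      # daughters: antisymmetric rate noise, noisy septum, survival at birth
      eps <- drawEps()
      frac <- drawFrac()
      vb <- c(frac * Vd, (1 - frac) * Vd)
      rr <- cfg@r0 * c(1 + eps, 1 - eps)
      for (j in 1:2) {
        pSurv <- survivalCurve(vb[j], sv["V_lo"], sv["V_hi"], sv["p_mid"],
                               sv["steepness"])
        queue[[length(queue) + 1L]] <- list(
          id = paste0(cell$id, ".", j), parent = cell$id,
          gen = cell$gen + 1L, birth = tt[length(tt)], Vb = vb[j],
          r = rr[j], alive = runif(1) < pSurv)
      }
    }
  }

  cellsDf <- do.call(rbind, cellRows)
  seriesDf <- data.frame(cell_id = unlist(serId), time = unlist(serT),
                         volume = unlist(serV), stringsAsFactors = FALSE)
  md <- list(source = "LineageHomeo::simulateLineages",
             units = list(time = "min", volume = "um^3"),
             frame_dt = dt, seed = cfg@seed,
             config = .configAsList(cfg),
             truncation = list(septum_fraction = c(0.05, 0.95),
                               rate_noise = "eps = tanh(N(0, sigma_g))"))
  new("LineageTable", cells = cellsDf, series = seriesDf, metadata = md)
}

.configAsList <- function(cfg) {
  list(r0 = cfg@r0, sigma_g = cfg@sigma_g, sigma_s = cfg@sigma_s,
       dV0 = cfg@dV0, cv_dV = cfg@cv_dV, survival = as.list(cfg@survival),
       n_founders = cfg@n_founders, n_generations = cfg@n_generations,
       founder_volume = cfg@founder_volume, founder_cv = cfg@founder_cv,
       frame_dt = cfg@frame_dt, max_frames = cfg@max_frames,
       seed = cfg@seed)
}

#' Read / write a simulator configuration as JSON
#'
#' @param cfg a [SimulationConfig-class].
#' @param path JSON file path.
#' @return `readSimulationConfig` returns a validated
#'   [SimulationConfig-class]; `writeSimulationConfig` returns `path`
#'   invisibly.
#' @export
writeSimulationConfig <- function(cfg, path) {
  stopifnot(is(cfg, "SimulationConfig"))
  jsonlite::write_json(.configAsList(cfg), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::fromJSON(path)
  if (!is.null(x$survival)) {
    sv <- unlist(x$survival)
    miss <- setdiff(c("V_lo", "V_hi", "p_mid", "steepness"), names(sv))
    if (length(miss))
      stop("config error: survival is missing ",
           paste(miss, collapse = ", "))
    x$survival <- sv[c("V_lo", "V_hi", "p_mid", "steepness")]
  }
  known <- names(formals(SimulationConfig))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("config error: unknown field(s) ", paste(unknown, collapse = ", "))
  do.call(SimulationConfig, x)
}

#' Simulate a plate-reader growth curve
#'
#' Lag-then-logistic optical-density trace with multiplicative log-normal
#' noise, sampled at a fixed interval; a fixture generator for
#' [identifyPhases()]. The OD stays at `od0` during the lag, then follows
#' logistic growth at rate `r` towards carrying capacity `K`.
#'
#' @param r exponential growth rate (1/min); 0 yields a flat curve.
#' @param lag lag duration (min).
#' @param K carrying capacity (OD units).
#' @param noiseSd standard deviation of multiplicative log-normal noise.
#' @param seed RNG seed.
#' @param od0 inoculation OD (default 0.01).
#' @param dt sampling interval (min, default 5).
#' @param tMax duration (min, default 1440).
#' @return `data.frame` with columns `time` (min) and `od`.
#' @export
simulateGrowthCurve <- function(r, lag = 0, K = 1, noiseSd = 0, seed = 1,
                                od0 = 0.01, dt = 5, tMax = 1440) {
  if (r < 0 || lag < 0 || K <= 0 || noiseSd < 0 || od0 <= 0 || dt <= 0 ||
      tMax <= 0)
    stop("config error: parameters must be non-negative (K, od0, dt, tMax positive)")
  times <- seq(0, tMax, by = dt)
  te <- pmax(times - lag, 0)
  g <- exp(r * te)
  od <- K * od0 * g / (K + od0 * (g - 1))
  if (noiseSd > 0) {
    set.seed(seed)
    od <- od * exp(rnorm(length(od), 0, noiseSd))
  }
  data.frame(time = times, od = od)
}
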