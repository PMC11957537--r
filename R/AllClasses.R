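#' @import methods
#' @importFrom stats lm coef dnorm integrate lm.fit pnorm qnorm quantile
#'   rbinom rnorm runif sd setNames uniroot complete.cases
#' @importFrom utils head read.csv tail write.table packageVersion
#' @importFrom S4Vectors metadata
NULL

REQUIRED_CELL_COLS <- c("cell_id", "parent_id", "generation", "birth_time",
                        "division_time", "fate", "birth_volume",
                        "division_volume")
REQUIRED_SERIES_COLS <- c("cell_id", "time", "volume")
CELL_FATES <- c("divided", "arrested", "censored")

#' Tracked single-cell lineage forest
#'
#' `LineageTable` is the central container of the package: a rooted forest of
#' tracked cells, each carrying a time--volume trajectory and a fate. It is the
#' in-memory form of the per-frame tables exported by segmentation/tracking
#' tools (one row per cell per frame), split into a per-cell summary and the
#' long observation table.
#'
#' @slot cells `data.frame` with one row per cell and columns `cell_id`,
#'   `parent_id` (`NA` for founders), `generation` (0 for founders),
#'   `birth_time`, `division_time` (`NA` unless divided), `fate` (one of
#'   `"divided"`, `"arrested"`, `"censored"`), `birth_volume`,
#'   `division_volume`. Times in minutes, volumes in cubic micrometres.
#' @slot series `data.frame` with one row per (cell, frame): `cell_id`,
#'   `time` (min), `volume` (um^3). Times are strictly increasing within a
#'   cell and volumes strictly positive.
#' @slot metadata free-form provenance list (source, units, seed, frame
#'   interval `frame_dt` in minutes, ...).
#'
#' @details Validity enforces the lineage invariants: unique cell ids, parent
#' references that resolve, at most two daughters per mother, daughter
#' generation = mother generation + 1, daughter birth time within one frame
#' interval (`metadata$frame_dt`, default 5 min) of the mother's division
#' time, per-cell monotone observation times, positive volumes, and agreement
#' of `birth_volume`/`division_volume` with the first/last observed volumes.
#'
#' @seealso [makeLineageTable()], [readLineageTable()], [simulateLineages()]
#' @export
setClass("LineageTable",
         slots = c(cells = "data.frame",
                   series = "data.frame",
                   metadata = "list"))

.frameInterval <- function(object) {
  dt <- object@metadata$frame_dt
  if (is.null(dt) || !is.numeric(dt) || !is.finite(dt) || dt <= 0) 5 else dt
}

setValidity("LineageTable", function(object) {
  cells <- object@cells
  series <- object@series
  msgs <- character()
  miss <- setdiff(REQUIRED_CELL_COLS, names(cells))
  if (length(miss))
    return(paste("cells is missing columns:", paste(miss, collapse = ", ")))
  miss <- setdiff(REQUIRED_SERIES_COLS, names(series))
  if (length(miss))
    return(paste("series is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(cells) == 0L) {
    if (nrow(series) > 0L) msgs <- c(msgs, "series refers to no known cell")
    return(if (length(msgs)) msgs else TRUE)
  }
  id <- as.character(cells$cell_id)
  if (anyDuplicated(id))
    msgs <- c(msgs, paste("duplicated cell_id:",
                          paste(unique(id[duplicated(id)]), collapse = ", ")))
  parent <- as.character(cells$parent_id)
  known <- !is.na(parent)
  if (any(known & !(parent %in% id)))
    msgs <- c(msgs, paste("parent_id does not resolve:",
                          paste(unique(parent[known & !(parent %in% id)]),
                                collapse = ", ")))
  if (!all(cells$fate %in% CELL_FATES))
    msgs <- c(msgs, "fate must be one of divided/arrested/censored")
  if (any(cells$generation < 0))
    msgs <- c(msgs, "generation must be >= 0")
  sid <- as.character(series$cell_id)
  if (!all(sid %in% id))
    msgs <- c(msgs, "series contains observations for unknown cells")
  if (any(series$volume <= 0, na.rm = TRUE))
    msgs <- c(msgs, "series volumes must be strictly positive")
  ord <- order(match(sid, id), series$time)
  st <- series$time[ord]
  sg <- sid[ord]
  same <- sg[-1] == sg[-length(sg)]
  if (length(st) > 1 && any(diff(st)[same] <= 0))
    msgs <- c(msgs, "series times must be strictly increasing within a cell")
  # per-cell first/last observation
  first <- !duplicated(sg)
  last <- !duplicated(sg, fromLast = TRUE)
  firstVol <- setNames(series$volume[ord][first], sg[first])
  lastVol <- setNames(series$volume[ord][last], sg[last])
  firstT <- setNames(st[first], sg[first])
  if (!all(id %in% sg))
    msgs <- c(msgs, "every cell needs at least one observation")
  obs <- id[id %in% sg]
  if (any(abs(cells$birth_volume[match(obs, id)] - firstVol[obs]) >
          1e-6 * firstVol[obs]))
    msgs <- c(msgs, "birth_volume must equal the first observed volume")
  div <- cells$fate == "divided"
  if (any(div & is.na(cells$division_time)))
    msgs <- c(msgs, "divided cells need a division_time")
  if (any(div & !is.na(cells$division_time) &
          cells$birth_time >= cells$division_time))
    msgs <- c(msgs, "birth_time must precede division_time for divided cells")
  dobs <- id[div & id %in% names(lastVol)]
  if (length(dobs) &&
      any(abs(cells$division_volume[match(dobs, id)] - lastVol[dobs]) >
          1e-6 * lastVol[dobs], na.rm = TRUE))
    msgs <- c(msgs, "division_volume must equal the last observed volume")
  # parent/child consistency
  kid <- which(known & parent %in% id)
  if (length(kid)) {
    pidx <- match(parent[kid], id)
    nkids <- table(parent[kid])
    if (any(nkids > 2))
      msgs <- c(msgs, paste("mothers with more than 2 daughters:",
                            paste(names(nkids)[nkids > 2], collapse = ", ")))
    if (any(cells$generation[kid] != cells$generation[pidx] + 1))
      msgs <- c(msgs, "generation(child) must equal generation(parent) + 1")
    dtol <- .frameInterval(object)
    pdiv <- cells$division_time[pidx]
    bt <- cells$birth_time[kid]
    bad <- !is.na(pdiv) & abs(bt - pdiv) > dtol + 1e-9
    if (any(bad))
      msgs <- c(msgs, paste("daughter birth_time further than one frame",
                            "interval from mother division_time:",
                            paste(id[kid][bad], collapse = ", ")))
    if (anyNA(pdiv))
      msgs <- c(msgs, "daughters recorded for a mother without division_time")
  }
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the agent-based lineage simulator
#'
#' Full parameterisation of [simulateLineages()]; all randomness derives from
#' `seed`. Defaults emulate an ancestral rod-like strain growing on an agarose
#' pad: doubling time about 69 min (`r0` = 0.01/min), 5-min frames, symmetric
#' division and near-identical sister growth (target sister asymmetries of 5%
#' in both rate and birth volume), and full viability.
#'
#' @slot r0 base single-cell volume elongation rate (1/min); volume grows as
#'   `V(t) = Vb * exp(r t)`.
#' @slot sigma_g sister elongation-rate asymmetry scale: sisters receive rates
#'   `r0*(1+eps)` and `r0*(1-eps)` with `eps = tanh(Normal(0, sigma_g))`, so
#'   the pairwise statistic Cg equals `E|eps|`. Use [calibrateSigmaG()] to hit
#'   a target Cg.
#' @slot sigma_s septum-placement noise: daughter volume fraction
#'   `f = 0.5 + Normal(0, sigma_s)` truncated to (0.05, 0.95); Cs = `E|2f-1|`.
#' @slot dV0 target added volume per cycle (um^3), the adder increment.
#' @slot cv_dV coefficient of variation of the per-cycle added-volume target.
#' @slot survival numeric vector `c(V_lo, V_hi, p_mid, steepness)` defining a
#'   U-tailed survival-vs-birth-volume curve (see [survivalCurve()]); death is
#'   enriched in both volume tails.
#' @slot n_founders,n_generations forest size: founders are generation 0;
#'   cells reaching `n_generations` are censored.
#' @slot founder_volume mean founder birth volume (um^3).
#' @slot founder_cv coefficient of variation of founder volumes (log-normal);
#'   0 gives identical founders.
#' @slot frame_dt imaging frame interval (min).
#' @slot max_frames per-cycle frame cap: a cell not reaching its division
#'   threshold within `max_frames` frames is scored arrested.
#' @slot seed integer RNG seed (mandatory).
#'
#' @seealso [simulateLineages()], [calibrateSigmaG()], [calibrateSigmaS()]
#' @export
setClass("SimulationConfig",
         slots = c(r0 = "numeric", sigma_g = "numeric", sigma_s = "numeric",
                   dV0 = "numeric", cv_dV = "numeric", survival = "numeric",
                   n_founders = "integer", n_generations = "integer",
                   founder_volume = "numeric", founder_cv = "numeric",
                   frame_dt = "numeric", max_frames = "integer",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  pos <- function(x, nm) if (!is.numeric(x) || length(x) != 1 ||
                             !is.finite(x) || x <= 0)
    paste(nm, "must be a single positive finite number") else NULL
  msgs <- c(msgs,
            pos(object@r0, "r0"), pos(object@dV0, "dV0"),
            pos(object@founder_volume, "founder_volume"),
            pos(object@frame_dt, "frame_dt"))
  if (object@sigma_g < 0) msgs <- c(msgs, "sigma_g must be >= 0")
  if (object@sigma_s < 0 || object@sigma_s >= 0.5)
    msgs <- c(msgs, "sigma_s must be in [0, 0.5)")
  if (object@cv_dV < 0) msgs <- c(msgs, "cv_dV must be >= 0")
  if (object@founder_cv < 0) msgs <- c(msgs, "founder_cv must be >= 0")
  sv <- object@survival
  if (length(sv) != 4 || is.null(names(sv)) ||
      !all(c("V_lo", "V_hi", "p_mid", "steepness") %in% names(sv)))
    msgs <- c(msgs, "survival must be named c(V_lo, V_hi, p_mid, steepness)")
  else {
    if (sv["V_lo"] >= sv["V_hi"]) msgs <- c(msgs, "V_lo must be < V_hi")
    if (sv["p_mid"] < 0 || sv["p_mid"] > 1)
      msgs <- c(msgs, "p_mid must be in [0, 1]")
    if (sv["steepness"] <= 0) msgs <- c(msgs, "steepness must be > 0")
  }
  if (length(object@n_founders) != 1 || object@n_founders < 1)
    msgs <- c(msgs, "n_founders must be >= 1")
  if (length(object@n_generations) != 1 || object@n_generations < 1)
    msgs <- c(msgs, "n_generations must be >= 1")
  if (length(object@max_frames) != 1 || object@max_frames < 3)
    msgs <- c(msgs, "max_frames must be >= 3")
  if (length(object@seed) != 1 || is.na(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SimulationConfig-class Constructor with study-condition
#'   defaults (ancestral-like: balanced adder, 5% sister asymmetries, full
#'   viability over the occupied volume range).
#' @param r0,sigma_g,sigma_s,dV0,cv_dV,survival,n_founders,n_generations
#'   see slots.
#' @param founder_volume,founder_cv,frame_dt,max_frames,seed see slots.
#' @export
SimulationConfig <- function(r0 = 0.01,
                             sigma_g = calibrateSigmaG(0.05),
                             sigma_s = calibrateSigmaS(0.05),
                             dV0 = 3.3,
                             cv_dV = 0.2,
                             survival = c(V_lo = 0.3, V_hi = 30,
                                          p_mid = 1, steepness = 4),
                             n_founders = 50L,
                             n_generations = 3L,
                             founder_volume = 3.3,
                             founder_cv = 0.25,
                             frame_dt = 5,
                             max_frames = 10000L,
                             seed = 1L) {
  new("SimulationConfig", r0 = r0, sigma_g = sigma_g, sigma_s = sigma_s,
      dV0 = dV0, cv_dV = cv_dV, survival = survival,
      n_founders = as.integer(n_founders),
      n_generations = as.integer(n_generations),
      founder_volume = founder_volume, founder_cv = founder_cv,
      frame_dt = frame_dt, max_frames = as.integer(max_frames),
      seed = as.integer(seed))
}
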